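# Translated similarity search: six-frame seed-and-extend with BLOSUM62 local
# alignment and Karlin-Altschul E-values; merging of hits into candidate
# genome regions; and functionality triage of each region.

#' Default search settings for the translated scan
#'
#' @param word_size exact-match seed word size in amino acids (default 4).
#' @param gap_open,gap_ext affine gap penalties (default 11/1, BLOSUM62
#'   gapped regime).
#' @param lambda,K Karlin-Altschul parameters for the gapped BLOSUM62 11/1
#'   regime (0.267 and 0.041).
#' @param max_evalue discovery E-value cutoff; hits above it are dropped
#'   (default 1e-3).
#' @param band diagonal bandwidth for clustering seed hits (default 8).
#' @param max_seed_dist maximum along-diagonal distance between seed hits of
#'   one cluster (default 100 residues).
#' @return a list of search settings.
#' @export
scan_params <- function(word_size = 4L, gap_open = 11, gap_ext = 1,
                        lambda = 0.267, K = 0.041, max_evalue = 1e-3,
                        band = 8L, max_seed_dist = 100L) {
  list(word_size = as.integer(word_size), gap_open = gap_open,
       gap_ext = gap_ext, lambda = lambda, K = K, max_evalue = max_evalue,
       band = as.integer(band), max_seed_dist = as.integer(max_seed_dist))
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` for raw alignment score `S`, query
#' length `m` and searched residues `n`.
#'
#' @param S raw alignment score.
#' @param m query length (residues).
#' @param n searched residues.
#' @param lambda,K Karlin-Altschul parameters.
#' @return the expected number of chance alignments scoring `>= S`.
#' @export
karlin_altschul_evalue <- function(S, m, n, lambda = 0.267, K = 0.041) {
  K * m * n * exp(-lambda * S)
}

# Translate all six frames of one chromosome. Returns a list of entries with
# the translated string, frame (0/1/2), strand and chromosome length.
six_frame_translate <- function(chrom_seq) {
  len <- length(chrom_seq)
  rc <- Biostrings::reverseComplement(chrom_seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") chrom_seq else rc
    for (f in 0:2) {
      keep <- 3L * ((len - f) %/% 3L)
      if (keep < 3L) next
      aa <- Biostrings::translate(
        Biostrings::subseq(s, f + 1L, f + keep), if.fuzzy.codon = "solve")
      out[[length(out) + 1L]] <- list(aa = as.character(aa), frame = f,
                                      strand = strand, chrom_len = len)
    }
  }
  out
}

# Map 1-based inclusive aa positions in a frame translation to 0-based
# half-open genomic coordinates.
aa_to_genomic <- function(aa_start, aa_end, frame, strand, chrom_len) {
  if (strand == "+") {
    c(frame + 3L * (aa_start - 1L), frame + 3L * aa_end)
  } else {
    c(chrom_len - frame - 3L * aa_end, chrom_len - frame - 3L * (aa_start - 1L))
  }
}

# Integer 4-mer word codes of a protein string (27-letter alphabet covering
# the 20 standard residues plus X/* etc.).
word_codes <- function(aa_string, w) {
  code <- utf8ToInt(aa_string) - 64L  # 'A' -> 1
  n <- length(code) - w + 1L
  if (n < 1L) return(integer(0))
  out <- code[seq_len(n)]
  for (k in seq_len(w - 1L)) {
    out <- out * 27L + code[seq_len(n) + k]
  }
  out
}

#' Six-frame translated similarity search
#'
#' Finds high-scoring segment pairs (HSPs) between seed protein queries and
#' all six reading frames of a genome, BLAST-style: exact `word_size`-mer
#' seeding, diagonal clustering (two seeds on nearby diagonals are required),
#' and Smith-Waterman extension of the candidate window with BLOSUM62 and
#' affine gaps. Each HSP carries the raw score `S`, a bit score and the
#' Karlin-Altschul E-value `K * m * n * exp(-lambda * S)` where `m` is the
#' query length and `n` the total number of translated residues searched.
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @param profile optional [build_profile()] object; validated and carried
#'   along for downstream triage, not used for seeding.
#' @param queries seed proteins ([Biostrings::AAStringSet] or named character
#'   vector).
#' @param params a [scan_params()] list.
#' @return data.frame of HSPs: `query_id`, `chromosome`, `start`, `end`
#'   (0-based half-open genomic), `strand`, `frame`, `score`, `bitscore`,
#'   `evalue`, `identity_pct`.
#' @export
scan_translated <- function(genome, profile = NULL, queries,
                            params = scan_params()) {
  if (length(queries) == 0L) stop("usage error: empty query set")
  if (length(genome) == 0L) stop("usage error: empty genome")
  if (!is.null(profile)) stopifnot(inherits(profile, "domain_profile"))
  qchr <- as.character(queries)
  if (is.null(names(qchr))) names(qchr) <- sprintf("query%d", seq_along(qchr))
  w <- params$word_size

  # query word lookup: word code -> (query index, query position)
  qwords <- lapply(qchr, word_codes, w = w)
  qtab <- data.frame(
    code = unlist(qwords, use.names = FALSE),
    qi = rep(seq_along(qchr), lengths(qwords)),
    qpos = unlist(lapply(qwords, seq_along), use.names = FALSE)
  )

  frames <- list()
  for (ci in seq_along(genome)) {
    fr <- six_frame_translate(genome[[ci]])
    for (f in fr) {
      f$chrom <- names(genome)[ci]
      frames[[length(frames) + 1L]] <- f
    }
  }
  n_total <- sum(vapply(frames, function(f) nchar(f$aa), 0))

  hsps <- list()
  for (f in frames) {
    codes <- word_codes(f$aa, w)
    if (!length(codes)) next
    hit <- which(codes %in% qtab$code)
    if (!length(hit)) next
    # expand: one subject position may seed several queries/positions
    mt <- qtab[qtab$code %in% codes[hit], , drop = FALSE]
    exp_idx <- lapply(split(hit, codes[hit]), identity)
    sub_aa <- Biostrings::AAString(f$aa)
    for (qi in unique(mt$qi)) {
      qrows <- mt[mt$qi == qi, , drop = FALSE]
      spos <- integer(0); qpos <- integer(0)
      codes_q <- split(qrows$qpos, qrows$code)
      for (cd in names(codes_q)) {
        sp <- exp_idx[[cd]]
        if (is.null(sp)) next
        for (qp in codes_q[[cd]]) {
          spos <- c(spos, sp)
          qpos <- c(qpos, rep(qp, length(sp)))
        }
      }
      if (length(spos) < 2L) next
      diag <- spos - qpos
      ord <- order(diag, spos)
      diag <- diag[ord]; sp <- spos[ord]; qp <- qpos[ord]
      grp <- cumsum(c(TRUE, diff(diag) > params$band |
                        diff(sp) > params$max_seed_dist))
      qlen <- nchar(qchr[qi])
      windows <- list()
      for (g in unique(grp)) {
        sel <- grp == g
        if (sum(sel) < 2L || length(unique(qp[sel])) < 2L) next
        windows[[length(windows) + 1L]] <-
          c(max(1L, min(sp[sel]) - qlen - 10L),
            min(nchar(f$aa), max(sp[sel]) + qlen + 10L))
      }
      if (!length(windows)) next
      # merge overlapping windows so each locus is aligned once
      wm <- do.call(rbind, windows)
      wm <- wm[order(wm[, 1]), , drop = FALSE]
      merged <- list(wm[1, ])
      for (i in seq_len(nrow(wm))[-1]) {
        last <- merged[[length(merged)]]
        if (wm[i, 1] <= last[2]) {
          merged[[length(merged)]] <- c(last[1], max(last[2], wm[i, 2]))
        } else merged[[length(merged) + 1L]] <- wm[i, ]
      }
      for (win in merged) {
        subj <- Biostrings::subseq(sub_aa, win[1], win[2])
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(qchr[qi]), subj,
          type = "local", substitutionMatrix = blosum62(),
          gapOpening = params$gap_open, gapExtension = params$gap_ext
        )
        S <- Biostrings::score(aln)
        if (S <= 0) next
        ev <- karlin_altschul_evalue(S, qlen, n_total,
                                     params$lambda, params$K)
        if (ev > params$max_evalue) next
        aa_s <- win[1] + Biostrings::start(Biostrings::subject(aln)) - 1L
        aa_e <- win[1] + Biostrings::end(Biostrings::subject(aln)) - 1L
        gc <- aa_to_genomic(aa_s, aa_e, f$frame, f$strand, f$chrom_len)
        hsps[[length(hsps) + 1L]] <- data.frame(
          query_id = names(qchr)[qi], chromosome = f$chrom,
          start = gc[1], end = gc[2], strand = f$strand, frame = f$frame,
          score = S,
          bitscore = (params$lambda * S - log(params$K)) / log(2),
          evalue = ev,
          identity_pct = Biostrings::pid(aln, type = "PID1"),
          m = qlen, n_searched = n_total,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(hsps)) {
    return(data.frame(query_id = character(0), chromosome = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      score = numeric(0), bitscore = numeric(0),
                      evalue = numeric(0), identity_pct = numeric(0),
                      m = integer(0), n_searched = numeric(0)))
  }
  out <- do.call(rbind, hsps)
  out[order(out$chromosome, out$start, out$evalue), , drop = FALSE]
}

#' Merge HSPs into candidate genome regions
#'
#' HSPs on the same chromosome and strand whose genomic intervals lie within
#' `max_gap` of each other are merged into one region (connected components
#' of the interval-proximity graph). Regions are disjoint per
#' (chromosome, strand) and sorted by coordinate.
#'
#' @param hsps data.frame from [scan_translated()].
#' @param max_gap maximum genomic gap bridged within a region (default
#'   10000 bp).
#' @return data.frame of regions (`region_id`, `chromosome`, `start`, `end`,
#'   `strand`, `n_hsps`, `best_evalue`, `triage_class` = NA) with the
#'   supporting HSP rows attached as a list column `hsps`.
#' @export
merge_regions <- function(hsps, max_gap = 10000L) {
  stopifnot(max_gap >= 0)
  empty <- data.frame(region_id = character(0), chromosome = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_hsps = integer(0),
                      best_evalue = numeric(0), triage_class = character(0))
  if (nrow(hsps) == 0L) {
    empty$hsps <- list()
    return(empty)
  }
  out <- list()
  for (key in unique(paste(hsps$chromosome, hsps$strand))) {
    sel <- hsps[paste(hsps$chromosome, hsps$strand) == key, , drop = FALSE]
    sel <- sel[order(sel$start), , drop = FALSE]
    grp <- cumsum(c(TRUE, sel$start[-1] > cummax(sel$end[-nrow(sel)]) + max_gap))
    for (g in unique(grp)) {
      rs <- sel[grp == g, , drop = FALSE]
      out[[length(out) + 1L]] <- list(
        chromosome = rs$chromosome[1], start = min(rs$start),
        end = max(rs$end), strand = rs$strand[1], n_hsps = nrow(rs),
        best_evalue = min(rs$evalue), hsps = rs
      )
    }
  }
  df <- data.frame(
    chromosome = vapply(out, `[[`, "", "chromosome"),
    start = vapply(out, `[[`, 0, "start"),
    end = vapply(out, `[[`, 0, "end"),
    strand = vapply(out, `[[`, "", "strand"),
    n_hsps = vapply(out, `[[`, 0L, "n_hsps"),
    best_evalue = vapply(out, `[[`, 0, "best_evalue"),
    stringsAsFactors = FALSE
  )
  ord <- order(df$chromosome, df$start, df$strand)
  df <- df[ord, , drop = FALSE]
  df$region_id <- sprintf("region%03d", seq_len(nrow(df)))
  df$triage_class <- NA_character_
  df$hsps <- lapply(out, `[[`, "hsps")[ord]
  rownames(df) <- NULL
  df[, c("region_id", "chromosome", "start", "end", "strand", "n_hsps",
         "best_evalue", "triage_class", "hsps")]
}

#' Triage one candidate region
#'
#' Classifies a region exactly one way: `no_domain` when no gapless local
#' PSSM match reaches the profile threshold in any frame; otherwise
#' `nonfunctional` when the domain match covers less than 80 percent of the
#' profile (truncation) or the translated HSP span in the domain frame
#' contains an internal stop or an ambiguity run; `possibly_assembly` (a
#' refinement of nonfunctional) when the disruption interval overlaps a run
#' of at least 20 `N`; else `functional`.
#'
#' @param region one row of the [merge_regions()] data.frame (with its `hsps`
#'   list column).
#' @param genome the [Biostrings::DNAStringSet] that was scanned.
#' @param profile the family [build_profile()] object.
#' @param min_coverage minimum profile coverage of the domain match below
#'   which the region counts as truncated (default 0.8).
#' @param min_n_run minimum `N`-run length treated as an assembly gap
#'   (default 20).
#' @return the region row with `triage_class` set and two extra columns:
#'   `disruption_evidence` (`internal_stop`, `truncation`, `gap_overlap` or
#'   NA) and `domain_score`.
#' @export
triage_region <- function(region, genome, profile, min_coverage = 0.8,
                          min_n_run = 20L) {
  if (!region$chromosome %in% names(genome)) {
    stop("coordinate error: region chromosome not in genome")
  }
  chrom <- genome[[region$chromosome]]
  if (region$start < 0 || region$end > length(chrom)) {
    stop("coordinate error: region outside genome bounds")
  }
  hsps <- region$hsps[[1]]
  if (is.null(hsps) || nrow(hsps) == 0L) stop("region has no supporting HSPs")

  pad <- 30L
  rs <- max(0L, region$start - pad)
  re <- min(length(chrom), region$end + pad)
  seq_str <- as.character(Biostrings::subseq(chrom, rs + 1L, re))
  runs <- n_runs(seq_str, min_n_run)
  if (nrow(runs)) runs <- runs + rs  # lift to genomic coordinates

  frames <- six_frame_translate(Biostrings::DNAString(seq_str))
  best <- NULL
  for (f in frames) {
    hit <- scan_profile(profile, f$aa)
    if (is.null(best) || hit$score > best$hit$score) best <- list(f = f, hit = hit)
  }
  set <- function(class, evidence = NA_character_) {
    region$triage_class <- class
    region$disruption_evidence <- evidence
    region$domain_score <- if (is.null(best)) NA_real_ else best$hit$score
    region
  }
  if (is.null(best) || best$hit$score < profile$threshold) {
    return(set("no_domain"))
  }

  f <- best$f
  hit <- best$hit
  # genomic interval of the domain match
  dom_g <- aa_to_genomic(hit$seq_start, hit$seq_end, f$frame, f$strand,
                         f$chrom_len) + rs

  if (hit$coverage < min_coverage) {
    # the unmatched profile extent flanks the matched interval; an assembly
    # gap there explains the truncation
    miss_aa <- 3L * (profile$length - (hit$col_end - hit$col_start + 1L))
    flank <- if (f$strand == "+") c(dom_g[2], dom_g[2] + miss_aa)
             else c(dom_g[1] - miss_aa, dom_g[1])
    gap <- nrow(runs) > 0 &&
      any(overlaps(flank[1], flank[2], runs[, 1], runs[, 2]))
    return(set(if (gap) "possibly_assembly" else "nonfunctional",
               if (gap) "gap_overlap" else "truncation"))
  }

  # examine the translated HSP span in the domain's frame/strand for internal
  # stops and ambiguity runs
  span <- hsps[hsps$strand == f$strand, , drop = FALSE]
  if (nrow(span) == 0L) span <- hsps
  gs <- max(min(span$start), rs)
  ge <- min(max(span$end), re)
  # aa positions of the span within this frame translation
  if (f$strand == "+") {
    aa_lo <- max(1L, ((gs - rs - f$frame) %/% 3L) + 1L)
    aa_hi <- min(nchar(f$aa), ((ge - rs - f$frame - 1L) %/% 3L) + 1L)
  } else {
    len <- f$chrom_len
    aa_lo <- max(1L, ((len - (ge - rs) - f$frame) %/% 3L) + 1L)
    aa_hi <- min(nchar(f$aa), ((len - (gs - rs) - f$frame - 1L) %/% 3L) + 1L)
  }
  if (aa_hi <= aa_lo) return(set("functional"))
  aa_span <- substr(f$aa, aa_lo, aa_hi)
  chars <- strsplit(aa_span, "", fixed = TRUE)[[1]]
  inner <- seq_along(chars) > 2L & seq_along(chars) < length(chars) - 1L
  stops <- which(chars == "*" & inner)
  xs <- which(chars == "X" & inner)
  if (length(stops) == 0L && length(xs) == 0L) return(set("functional"))

  interval_of <- function(aa_pos) {
    g <- aa_to_genomic(aa_lo + min(aa_pos) - 1L, aa_lo + max(aa_pos) - 1L,
                       f$frame, f$strand, f$chrom_len) + rs
    g
  }
  if (length(xs)) {
    iv <- interval_of(xs)
    if (nrow(runs) > 0 && any(overlaps(iv[1], iv[2], runs[, 1], runs[, 2]))) {
      return(set("possibly_assembly", "gap_overlap"))
    }
  }
  if (length(stops)) {
    iv <- interval_of(stops)
    gap <- nrow(runs) > 0 && any(overlaps(iv[1], iv[2], runs[, 1], runs[, 2]))
    return(set(if (gap) "possibly_assembly" else "nonfunctional",
               "internal_stop"))
  }
  set("nonfunctional", "gap_overlap")
}

#' Triage every region of a scan
#'
#' @param regions data.frame from [merge_regions()].
#' @param genome,profile as in [triage_region()].
#' @param ... passed to [triage_region()].
#' @return the regions data.frame with `triage_class`,
#'   `disruption_evidence` and `domain_score` filled in.
#' @export
triage_regions <- function(regions, genome, profile, ...) {
  if (nrow(regions) == 0L) {
    regions$disruption_evidence <- character(0)
    regions$domain_score <- numeric(0)
    return(regions)
  }
  rows <- lapply(seq_len(nrow(regions)), function(i)
    triage_region(regions[i, , drop = FALSE], genome, profile, ...))
  do.call(rbind, rows)
}
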