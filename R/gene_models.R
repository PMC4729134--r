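# Gene models: exon/CDS structures, GFF3 round-trip, translation and
# functionality flags, structure comparison and coverage-based exon validation.
# Internal coordinates are 0-based half-open; GFF3 on disk is 1-based
# inclusive.

#' Construct a gene model
#'
#' @param locus_id character locus identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons 2-column matrix (`start`, `end`) of exon intervals, 0-based
#'   half-open, in transcript 5'->3' order (descending genomic coordinates on
#'   the minus strand).
#' @param cds like `exons`, the coding intervals (subset of the exon union);
#'   may have zero rows for non-coding models.
#' @param phase integer vector of CDS phases (one per CDS part); defaults to
#'   the phases implied by cumulative CDS length.
#' @param status one of `"gene"`, `"putative"`, `"hypothetical"`.
#' @param class optional free-text class attribute (used by the synthetic
#'   generator to carry the planted class).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(locus_id, chrom, strand, exons,
                       cds = exons, phase = NULL,
                       status = "gene", class = NA_character_) {
  stopifnot(strand %in% c("+", "-"),
            status %in% c("gene", "putative", "hypothetical"))
  exons <- interval_matrix(exons, strand, "exons")
  cds <- interval_matrix(cds, strand, "cds")
  if (nrow(exons) > 1L) {
    gs <- exons[order(exons[, 1]), , drop = FALSE]
    if (any(gs[-1, 1] < gs[-nrow(gs), 2])) stop("exons overlap")
  }
  if (nrow(cds) > 0 && !all(apply(cds, 1, function(iv)
    any(exons[, 1] <= iv[1] & iv[2] <= exons[, 2])))) {
    stop("CDS intervals must lie within exons")
  }
  if (is.null(phase)) {
    lens <- cds[, 2] - cds[, 1]
    phase <- if (length(lens)) (3L - (cumsum(c(0L, lens[-length(lens)])) %% 3L)) %% 3L
             else integer(0)
  }
  structure(list(locus_id = locus_id, chrom = chrom, strand = strand,
                 exons = exons, cds = cds, phase = as.integer(phase),
                 status = status, class = class),
            class = "gene_model")
}

# Normalize an interval matrix into transcript order for the given strand.
interval_matrix <- function(m, strand, what) {
  m <- matrix(as.numeric(m), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  if (any(m[, 1] >= m[, 2])) stop(sprintf("%s: start must be < end", what))
  ord <- order(m[, 1], decreasing = (strand == "-"))
  m[ord, , drop = FALSE]
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d (%s), %d exon(s), %d CDS part(s), status=%s\n",
              x$locus_id, x$chrom, min(x$exons[, 1]), max(x$exons[, 2]),
              x$strand, nrow(x$exons), nrow(x$cds), x$status))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Expects `gene` features with child `exon` and `CDS` features (directly or
#' via an `mRNA` level). Coordinates are converted from the 1-based inclusive
#' file convention to the package's 0-based half-open internal convention.
#'
#' @param path path to a GFF3 file.
#' @return a named list of [gene_model()] objects.
#' @export
read_gff <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    stop(sprintf("GFF parse error: expected 9 tab-separated fields at line %d",
                 body[which(nf != 9L)[1]]))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$ID <- as.character(df$ID)
  df$Parent <- vapply(as.list(df$Parent), function(p)
    if (length(p)) as.character(p)[1] else NA_character_, "")

  genes <- df[df$type == "gene", , drop = FALSE]
  # resolve transcript-level features down to their gene
  parent_gene <- function(pid) {
    while (!is.na(pid) && !(pid %in% genes$ID)) {
      pid <- df$Parent[match(pid, df$ID)]
    }
    pid
  }
  out <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    kids <- df[!is.na(df$Parent) &
                 vapply(df$Parent, parent_gene, "") == gid, , drop = FALSE]
    ex <- kids[kids$type == "exon", , drop = FALSE]
    cd <- kids[kids$type == "CDS", , drop = FALSE]
    strand <- as.character(genes$strand[i])
    to0 <- function(d) cbind(start = d$start - 1L, end = d$end)
    status <- if ("status" %in% names(genes) && !is.na(genes$status[i]))
      as.character(genes$status[i]) else "gene"
    cls <- if ("class" %in% names(genes)) as.character(genes$class[i]) else NA_character_
    phase <- if (nrow(cd)) {
      ph <- suppressWarnings(as.integer(as.character(cd$phase)))
      ord <- order(cd$start, decreasing = (strand == "-"))
      ph[ord]
    } else NULL
    out[[gid]] <- gene_model(
      locus_id = gid, chrom = as.character(genes$seqnames[i]), strand = strand,
      exons = if (nrow(ex)) to0(ex) else to0(genes[i, , drop = FALSE]),
      cds = if (nrow(cd)) to0(cd) else
        matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))),
      phase = phase, status = status, class = cls
    )
  }
  out
}

#' Write gene models to a GFF3 file
#'
#' Emits `gene`, `mRNA`, `exon` and `CDS` rows, 1-based inclusive, with a
#' `##gff-version 3` header. `write_gff` and [read_gff()] are inverse on the
#' modelled fields.
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gff <- function(models, path) {
  rows <- list()
  for (m in models) {
    span <- c(min(m$exons[, 1]), max(m$exons[, 2]))
    tid <- paste0(m$locus_id, ".t1")
    add <- function(type, s, e, id = NA, parent = NA, phase = NA) {
      data.frame(seqnames = m$chrom, start = s + 1L, end = e,
                 strand = m$strand, type = type, ID = id, Parent = parent,
                 phase = phase, status = m$status, class = m$class,
                 stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- add("gene", span[1], span[2], id = m$locus_id)
    rows[[length(rows) + 1L]] <- add("mRNA", span[1], span[2], id = tid,
                                     parent = m$locus_id)
    for (i in seq_len(nrow(m$exons))) {
      rows[[length(rows) + 1L]] <- add("exon", m$exons[i, 1], m$exons[i, 2],
                                       parent = tid)
    }
    for (i in seq_len(nrow(m$cds))) {
      rows[[length(rows) + 1L]] <- add("CDS", m$cds[i, 1], m$cds[i, 2],
                                       parent = tid, phase = m$phase[i])
    }
  }
  if (!length(rows)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand
  )
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(df$Parent, function(p) if (is.na(p)) character(0) else p))
  S4Vectors::mcols(gr)$phase <- df$phase
  S4Vectors::mcols(gr)$status <- df$status
  S4Vectors::mcols(gr)$class <- df$class
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Translate a gene model against its genome
#'
#' Splices the CDS in transcript orientation, translates with the standard
#' genetic code (ambiguous codons become `X`) and reports functionality flags.
#' The terminal stop, when present, is removed from the returned protein.
#'
#' @param model a [gene_model()].
#' @param genome a [Biostrings::DNAStringSet] containing the model's
#'   chromosome.
#' @return list with `protein` (character), and flags `internal_stop`,
#'   `no_start`, `length` (protein length), `incomplete` (CDS length not a
#'   multiple of 3).
#' @export
translate_model <- function(model, genome) {
  if (!model$chrom %in% names(genome)) {
    stop(sprintf("coordinate error: chromosome %s not in genome", model$chrom))
  }
  chrom <- genome[[model$chrom]]
  if (nrow(model$cds) == 0L) stop("model has no CDS")
  if (min(model$cds[, 1]) < 0 || max(model$cds[, 2]) > length(chrom)) {
    stop("coordinate error: CDS outside chromosome bounds")
  }
  parts <- lapply(seq_len(nrow(model$cds)), function(i) {
    s <- Biostrings::subseq(chrom, model$cds[i, 1] + 1L, model$cds[i, 2])
    if (model$strand == "-") Biostrings::reverseComplement(s) else s
  })
  cds <- do.call(Biostrings::xscat, parts)
  incomplete <- (length(cds) %% 3L) != 0L
  if (incomplete) cds <- Biostrings::subseq(cds, 1L, 3L * (length(cds) %/% 3L))
  prot <- as.character(Biostrings::translate(cds, if.fuzzy.codon = "solve"))
  had_stop <- grepl("\\*$", prot)
  prot <- sub("\\*$", "", prot)
  list(
    protein = prot,
    internal_stop = grepl("*", prot, fixed = TRUE),
    no_start = substr(prot, 1, 1) != "M",
    length = nchar(prot),
    incomplete = incomplete,
    terminal_stop = had_stop
  )
}

#' Compare two gene models for curation
#'
#' @param model_a,model_b [gene_model()] objects on the same chromosome and
#'   strand, with overlapping spans.
#' @return a one-row data.frame (`locus_id`, `verdict`, `changed_exons`,
#'   `reason`): `confirmed` when exon and CDS interval sets are identical,
#'   otherwise `curated` with `changed_exons` equal to the size of the
#'   symmetric difference of the exon interval sets.
#' @export
compare_structures <- function(model_a, model_b) {
  if (model_a$chrom != model_b$chrom || model_a$strand != model_b$strand) {
    stop("not comparable: different chromosome or strand")
  }
  span_a <- range(model_a$exons)
  span_b <- range(model_b$exons)
  if (!overlaps(span_a[1], span_a[2], span_b[1], span_b[2])) {
    stop("not comparable: models do not overlap")
  }
  key <- function(m) apply(m, 1, paste, collapse = "-")
  ea <- key(model_a$exons); eb <- key(model_b$exons)
  ca <- key(model_a$cds); cb <- key(model_b$cds)
  same <- setequal(ea, eb) && setequal(ca, cb)
  # a modified exon (present in one model, replaced in the other) counts once
  changed <- max(length(setdiff(ea, eb)), length(setdiff(eb, ea)))
  data.frame(
    locus_id = model_a$locus_id,
    verdict = if (same) "confirmed" else "curated",
    changed_exons = if (same) 0L else changed,
    reason = if (same) "" else "exon/CDS intervals differ",
    stringsAsFactors = FALSE
  )
}

#' Read a BedGraph coverage track
#'
#' @param path BedGraph file (0-based half-open intervals with a depth score).
#' @return data.frame `chrom`, `start`, `end`, `depth`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             depth = as.numeric(gr$score), stringsAsFactors = FALSE)
}

#' Validate exon structure against an expression coverage track
#'
#' An exon is supported when the median per-base depth over the exon reaches
#' `min_depth`. Bases absent from the track count as depth 0 (with a warning).
#'
#' @param model a [gene_model()].
#' @param coverage data.frame `chrom`,`start`,`end`,`depth` (0-based
#'   half-open), e.g. from [read_bedgraph()].
#' @param min_depth minimum median depth for support (default 5).
#' @return list with `exons` (data.frame exon/median_depth/supported, in
#'   transcript order) and `flagged` (TRUE when any exon is unsupported).
#' @export
validate_exons_with_coverage <- function(model, coverage, min_depth = 5) {
  cov <- coverage[coverage$chrom == model$chrom, , drop = FALSE]
  res <- lapply(seq_len(nrow(model$exons)), function(i) {
    s <- model$exons[i, 1]; e <- model$exons[i, 2]
    depth <- numeric(e - s)
    hit <- cov[cov$start < e & cov$end > s, , drop = FALSE]
    if (nrow(hit)) {
      for (j in seq_len(nrow(hit))) {
        a <- max(s, hit$start[j]); b <- min(e, hit$end[j])
        depth[(a - s + 1L):(b - s)] <- hit$depth[j]
      }
    }
    covered <- sum(pmin(pmax(cov$end, s), e) - pmin(pmax(cov$start, s), e))
    if (covered < (e - s)) {
      warning(sprintf("exon %d of %s only partially covered by track; missing bases treated as depth 0",
                      i, model$locus_id))
    }
    data.frame(exon = i, median_depth = stats::median(depth),
               supported = stats::median(depth) >= min_depth)
  })
  exons <- do.call(rbind, res)
  list(exons = exons, flagged = any(!exons$supported))
}
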