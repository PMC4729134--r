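# Family-domain position-specific scoring matrix: construction from a seed
# alignment and gapless local scanning of translated sequence.

#' Build a family-domain PSSM from a seed alignment
#'
#' Alignment columns with at least 50 percent occupancy define the profile
#' span. Per-column log-odds scores (bits) are
#' `log2((freq + pseudocount * bg) / ((1 + pseudocount) * bg))` with uniform
#' background `bg = 1/20`, where `freq` is the residue frequency among
#' non-gap characters of the column. The default acceptance threshold is
#' 0.6 times the consensus self-score (the sum of per-column maxima).
#'
#' @param seed_alignment aligned seed proteins: an [Biostrings::AAStringSet]
#'   or character vector of equal-length rows (gap `-`). At least 3 rows.
#' @param pseudocount pseudocount weight (default 1).
#' @param threshold_frac fraction of the consensus self-score used as the
#'   window-score threshold (default 0.6).
#' @param min_length minimum profile length; family domains are expected to
#'   span at least 50 columns (default 50).
#' @return an object of class `domain_profile` with components `scores`
#'   (20 x L matrix, bits), `length`, `threshold`, `consensus`,
#'   `self_score` and `source_ids`.
#' @export
build_profile <- function(seed_alignment, pseudocount = 1,
                          threshold_frac = 0.6, min_length = 50L) {
  rows <- as.character(seed_alignment)
  if (length(rows) < 3L) {
    stop("insufficient data: at least 3 seed sequences are required")
  }
  if (length(unique(nchar(rows))) != 1L) {
    stop("seed alignment rows must have equal length")
  }
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  occupancy <- colMeans(m != "-")
  keep <- which(occupancy >= 0.5)
  if (length(keep) < min_length) {
    stop(sprintf("profile span (%d columns) shorter than minimum length %d",
                 length(keep), min_length))
  }
  m <- m[, keep, drop = FALSE]
  bg <- 1 / 20
  scores <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col != "-"]
    freq <- table(factor(col, levels = AA20)) / length(col)
    log2((as.numeric(freq) + pseudocount * bg) / ((1 + pseudocount) * bg))
  }, numeric(20))
  rownames(scores) <- AA20
  self_score <- sum(apply(scores, 2, max))
  consensus <- paste(AA20[apply(scores, 2, which.max)], collapse = "")
  structure(
    list(scores = scores, length = ncol(scores),
         threshold = threshold_frac * self_score,
         self_score = self_score, consensus = consensus,
         source_ids = names(rows) %||% names(seed_alignment) %||%
           sprintf("seed%d", seq_along(rows)),
         pseudocount = pseudocount),
    class = "domain_profile"
  )
}

#' @export
print.domain_profile <- function(x, ...) {
  cat(sprintf("<domain_profile> %d columns, self-score %.1f bits, threshold %.1f bits\n",
              x$length, x$self_score, x$threshold))
  invisible(x)
}

# Score of each residue character against one profile column, with penalties
# for stops ('*', translated pseudogene codons) and ambiguity ('X', codons
# overlapping assembly gaps).
PROFILE_STOP_SCORE <- -4
PROFILE_X_SCORE <- -1

#' Gapless local alignment of a profile against a protein sequence
#'
#' Finds the best-scoring contiguous run of (profile column, residue) pairs
#' over all diagonals: a local, gap-free profile match that may use any
#' contiguous subset of profile columns. Stops score `-4`, ambiguous residues
#' `-1`.
#'
#' @param profile a [build_profile()] object.
#' @param aa_seq character; the protein sequence to scan.
#' @return list with `score`, `seq_start`, `seq_end` (1-based inclusive
#'   residue positions), `col_start`, `col_end` (profile columns) and
#'   `coverage` (matched columns / profile length). Score is `-Inf` for an
#'   empty sequence.
#' @export
scan_profile <- function(profile, aa_seq) {
  aa <- strsplit(aa_seq, "", fixed = TRUE)[[1]]
  n <- length(aa)
  L <- profile$length
  if (n == 0L) {
    return(list(score = -Inf, seq_start = NA, seq_end = NA,
                col_start = NA, col_end = NA, coverage = 0))
  }
  idx <- match(aa, AA20)
  # residue x column score matrix with fallbacks for non-standard letters
  M <- matrix(PROFILE_X_SCORE, nrow = n, ncol = L)
  known <- !is.na(idx)
  if (any(known)) M[known, ] <- profile$scores[idx[known], , drop = FALSE]
  M[aa == "*", ] <- PROFILE_STOP_SCORE

  best <- list(score = -Inf, seq_start = NA, seq_end = NA,
               col_start = NA, col_end = NA, coverage = 0)
  # diagonal d: residue i aligns to column i - d
  for (d in (1 - L):(n - 1)) {
    i0 <- max(1L, d + 1L)
    i1 <- min(n, d + L)
    if (i0 > i1) next
    i_seq <- i0:i1
    v <- M[cbind(i_seq, i_seq - d)]
    s <- cumsum(v)
    lo <- cummin(c(0, s[-length(s)]))
    gain <- s - lo
    k <- which.max(gain)
    if (gain[k] > best$score) {
      j <- if (lo[k] == 0 && k == 1) 1L else {
        w <- which(s[seq_len(k - 1)] == lo[k])
        if (length(w)) w[length(w)] + 1L else 1L
      }
      best <- list(score = gain[k],
                   seq_start = i_seq[j], seq_end = i_seq[k],
                   col_start = i_seq[j] - d, col_end = i_seq[k] - d,
                   coverage = (k - j + 1) / L)
    }
  }
  best
}
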