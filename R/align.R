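# Built-in progressive multiple aligner: k-mer distance guide tree plus
# profile-profile Needleman-Wunsch with BLOSUM62 expected scores and affine
# gaps. Exposed behind a provider interface so an external aligner can be
# substituted.

#' Construct an MSA object
#'
#' @param rows named character vector of equal-length aligned rows (gap `-`).
#' @return object of class `msa` with fields `ids`, `rows` and per-column
#'   non-gap `coverage`.
#' @export
msa <- function(rows) {
  if (length(unique(nchar(rows))) > 1L) stop("aligned rows must have equal length")
  m <- do.call(rbind, strsplit(unname(rows), "", fixed = TRUE))
  structure(list(ids = names(rows), rows = unname(rows),
                 coverage = colMeans(m != "-")),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns (mean coverage %.2f)\n",
              length(x$ids), nchar(x$rows[1]), mean(x$coverage)))
  invisible(x)
}

#' @export
as.matrix.msa <- function(x, ...) {
  m <- do.call(rbind, strsplit(x$rows, "", fixed = TRUE))
  rownames(m) <- x$ids
  m
}

# 3-mer count distance between unaligned sequences: 1 - shared/min fraction.
kmer_distance <- function(seqs, k = 3L) {
  counts <- lapply(seqs, function(s) table(word_codes(s, k)))
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- counts[[i]]; b <- counts[[j]]
      common <- intersect(names(a), names(b))
      shared <- sum(pmin(as.integer(a[common]), as.integer(b[common])))
      d[i, j] <- d[j, i] <- 1 - shared / min(sum(a), sum(b))
    }
  }
  d
}

# Column frequency profile (20 x L) of an aligned block; gaps contribute
# nothing (frequencies are over all rows, so gappy columns have mass < 1).
block_profile <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  L <- ncol(m)
  p <- matrix(0, nrow = 20, ncol = L, dimnames = list(AA20, NULL))
  for (a in AA20) p[a, ] <- colMeans(m == a)
  p
}

# Profile-profile global alignment (affine gaps); returns index vectors that
# thread the two blocks' columns (0 = gap).
profile_nw <- function(pa, pb, gap_open = 10, gap_ext = 0.5) {
  B <- blosum62()[AA20, AA20]
  S <- t(pa) %*% B %*% pb  # expected substitution score for each column pair
  la <- ncol(pa); lb <- ncol(pb)
  NEG <- -1e9
  M <- matrix(NEG, la + 1, lb + 1)  # match state
  X <- matrix(NEG, la + 1, lb + 1)  # gap in b (consume a)
  Y <- matrix(NEG, la + 1, lb + 1)  # gap in a (consume b)
  M[1, 1] <- 0
  if (la >= 1) X[2:(la + 1), 1] <- -gap_open - gap_ext * (0:(la - 1))
  if (lb >= 1) Y[1, 2:(lb + 1)] <- -gap_open - gap_ext * (0:(lb - 1))
  ptrM <- matrix(0L, la + 1, lb + 1)
  ptrX <- matrix(0L, la + 1, lb + 1)
  ptrY <- matrix(0L, la + 1, lb + 1)
  for (i in seq_len(la)) {
    Mi <- M[i, ]; Xi <- X[i, ]; Yi <- Y[i, ]
    Mrow <- M[i + 1, ]; Xrow <- X[i + 1, ]; Yrow <- Y[i + 1, ]
    # X (gap in b) transitions depend only on the previous row: vectorizable
    fromM <- Mi - gap_open
    fromX <- Xi - gap_ext
    Xrow <- pmax(fromM, fromX)
    ptrX[i + 1, ] <- ifelse(fromM >= fromX, 1L, 2L)
    for (j in seq_len(lb)) {
      sc <- S[i, j]
      cand <- c(Mi[j], Xi[j], Yi[j])
      w <- which.max(cand)
      Mrow[j + 1] <- cand[w] + sc
      ptrM[i + 1, j + 1] <- w
      candY <- c(Mrow[j] - gap_open, Yrow[j] - gap_ext)
      wy <- which.max(candY)
      Yrow[j + 1] <- candY[wy]
      ptrY[i + 1, j + 1] <- c(1L, 3L)[wy]
    }
    M[i + 1, ] <- Mrow; X[i + 1, ] <- Xrow; Y[i + 1, ] <- Yrow
  }
  ends <- c(M[la + 1, lb + 1], X[la + 1, lb + 1], Y[la + 1, lb + 1])
  state <- which.max(ends)
  i <- la; j <- lb
  ia <- integer(0); ib <- integer(0)
  while (i > 0 || j > 0) {
    if (state == 1L) {
      ia <- c(i, ia); ib <- c(j, ib)
      state <- ptrM[i + 1, j + 1]
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      ia <- c(i, ia); ib <- c(0L, ib)
      state <- if (i > 0) ptrX[i + 1, j + 1] else 2L
      i <- i - 1
      if (state == 0L) state <- 2L
    } else {
      ia <- c(0L, ia); ib <- c(j, ib)
      state <- ptrY[i + 1, j + 1]
      j <- j - 1
      if (state == 0L) state <- 3L
    }
    if (i == 0 && j > 0 && state == 1L) state <- 3L
    if (j == 0 && i > 0 && state == 1L) state <- 2L
  }
  list(ia = ia, ib = ib, score = ends[which.max(ends)])
}

# Thread aligned blocks through a profile alignment path.
apply_path <- function(rows, idx) {
  chars <- strsplit(rows, "", fixed = TRUE)
  vapply(chars, function(ch) {
    out <- ifelse(idx == 0L, "-", NA)
    out[idx != 0L] <- ch[idx[idx != 0L]]
    paste(out, collapse = "")
  }, "")
}

#' Multiple sequence alignment (provider interface)
#'
#' Default provider is the built-in progressive aligner: a 3-mer count
#' distance matrix feeds an average-linkage guide tree; profiles are merged
#' by profile-profile Needleman-Wunsch with BLOSUM62 expected scores and
#' affine gaps. A custom provider function `(named character vector) ->
#' named character vector of aligned rows` may be supplied instead.
#'
#' @param sequences named [Biostrings::AAStringSet] or character vector;
#'   at least 2 sequences with unique ids.
#' @param provider `"builtin"` or a function (see above).
#' @param gap_open,gap_ext affine gap penalties of the built-in aligner.
#' @return an [msa()] object.
#' @export
align_sequences <- function(sequences, provider = "builtin",
                            gap_open = 10, gap_ext = 0.5) {
  seqs <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("sequences must have unique ids")
  }
  if (length(seqs) < 2L) stop("at least 2 sequences are required")
  if (is.function(provider)) {
    return(msa(provider(seqs)))
  }
  if (length(seqs) == 2L) {
    blocks <- list(seqs[1], seqs[2])
    merge_order <- matrix(c(-1L, -2L), 1, 2)
  } else {
    d <- kmer_distance(seqs)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    merge_order <- hc$merge
    blocks <- as.list(seqs)
  }
  grown <- vector("list", nrow(merge_order))
  fetch <- function(k) if (k < 0) stats::setNames(seqs[-k], names(seqs)[-k])
                       else grown[[k]]
  for (r in seq_len(nrow(merge_order))) {
    ra <- fetch(merge_order[r, 1])
    rb <- fetch(merge_order[r, 2])
    path <- profile_nw(block_profile(unname(ra)), block_profile(unname(rb)),
                       gap_open, gap_ext)
    merged <- c(apply_path(unname(ra), path$ia),
                apply_path(unname(rb), path$ib))
    names(merged) <- c(names(ra), names(rb))
    grown[[r]] <- merged
  }
  final <- grown[[nrow(merge_order)]]
  msa(final[names(seqs)[names(seqs) %in% names(final)]])
}

#' Pairwise alignment score induced by an MSA
#'
#' Sum-of-pairs score of the two rows (BLOSUM62, affine gap penalties),
#' used to compare the progressive aligner against exact pairwise dynamic
#' programming.
#'
#' @param aln an [msa()] object.
#' @param id_a,id_b row ids.
#' @param gap_open,gap_ext affine gap penalties.
#' @return numeric score.
#' @export
msa_pair_score <- function(aln, id_a, id_b, gap_open = 10, gap_ext = 0.5) {
  a <- strsplit(aln$rows[match(id_a, aln$ids)], "")[[1]]
  b <- strsplit(aln$rows[match(id_b, aln$ids)], "")[[1]]
  keep <- !(a == "-" & b == "-")
  a <- a[keep]; b <- b[keep]
  B <- blosum62()
  sc <- 0
  in_gap <- 0L
  for (k in seq_along(a)) {
    if (a[k] == "-" || b[k] == "-") {
      which_gap <- if (a[k] == "-") 1L else 2L
      sc <- sc - (if (in_gap == which_gap) gap_ext else gap_open)
      in_gap <- which_gap
    } else {
      sc <- sc + B[a[k], b[k]]
      in_gap <- 0L
    }
  }
  sc
}
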