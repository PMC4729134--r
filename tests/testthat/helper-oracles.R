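# Independent brute-force oracles used by the tests. These deliberately share
# no code with the implementation paths they check.

# Smith-Waterman local alignment score, affine gaps costing
# gap_open + L * gap_ext for a gap of length L (plain O(mn) dynamic program).
sw_local_score_oracle <- function(a, b, gap_open = 11, gap_ext = 1) {
  B <- get_blosum62()
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)
  Y <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                             X[i, j + 1] - gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                             Y[i + 1, j] - gap_ext)
      M[i + 1, j + 1] <- max(0,
                             max(M[i, j], X[i, j], Y[i, j]) + B[x[i], y[j]])
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

get_blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# Connected components of the interval-proximity graph: intervals (start,end)
# are linked when their gap is <= max_gap. Returns component count.
interval_components_oracle <- function(start, end, max_gap) {
  n <- length(start)
  if (n == 0) return(0L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      gap <- max(start[i], start[j]) - min(end[i], end[j])
      if (gap <= max_gap) {
        parent[find(i)] <- find(j)
      }
    }
  }
  length(unique(vapply(seq_len(n), find, 0L)))
}

# Rand index between two partitions given as named membership vectors.
rand_index <- function(a, b) {
  ids <- intersect(names(a), names(b))
  a <- a[ids]; b <- b[ids]
  n <- length(ids)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  unname(agree / choose(n, 2))
}

# Partition (as a membership vector) from a list of groups.
membership <- function(groups) {
  out <- character(0)
  for (k in seq_along(groups)) {
    out[groups[[k]]] <- sprintf("grp%03d", k)
  }
  out
}

# Brute-force unweighted average-linkage agglomeration with a strict merge
# threshold: repeatedly merge the closest pair of clusters while the average
# of the original pairwise distances between their members is < threshold.
average_linkage_oracle <- function(d, threshold) {
  items <- rownames(d)
  clusters <- as.list(items)
  repeat {
    if (length(clusters) < 2) break
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1):length(clusters)) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < bestd) { bestd <- dd; best <- c(i, j) }
      }
    }
    if (bestd >= threshold) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  clusters
}

# Reciprocal-best-hit enumeration over a retained score table, applying the
# bitscore -> evalue -> id tie-break explicitly.
rbh_oracle <- function(scores) {
  best_of <- function(tab, from, to) {
    out <- character(0)
    for (g in unique(tab[[from]])) {
      rows <- tab[tab[[from]] == g, , drop = FALSE]
      rows <- rows[order(-rows$bitscore, rows$evalue, rows[[to]]), ,
                   drop = FALSE]
      out[g] <- rows[[to]][1]
    }
    out
  }
  fa <- best_of(scores, "gene_a", "gene_b")
  fb <- best_of(scores, "gene_b", "gene_a")
  pairs <- list()
  for (g in names(fa)) {
    if (!is.na(fb[fa[g]]) && fb[fa[g]] == g) {
      pairs[[length(pairs) + 1L]] <- c(g, fa[g])
    }
  }
  if (!length(pairs)) {
    return(data.frame(gene_a = character(0), gene_b = character(0)))
  }
  m <- do.call(rbind, pairs)
  data.frame(gene_a = m[, 1], gene_b = m[, 2], stringsAsFactors = FALSE)
}

# Plant a CDS (character) into a random background chromosome at `at`
# (0-based), optionally on the minus strand. Returns the DNAStringSet.
plant_into_genome <- function(cds, len = 10000L, at = 4000L, strand = "+",
                              seed = 42) {
  bg <- famscan:::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  ins <- if (strand == "+") cds else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  substr(bg, at + 1L, at + nchar(ins)) <- ins
  Biostrings::DNAStringSet(c(chrT = bg))
}

# Deterministic back-translation (first codon of the standard table).
simple_cds <- function(protein, stop = TRUE) {
  code <- Biostrings::GENETIC_CODE
  pick <- vapply(strsplit(protein, "")[[1]], function(a)
    names(code)[code == a][1], "")
  paste0(paste(pick, collapse = ""), if (stop) "TAA" else "")
}
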