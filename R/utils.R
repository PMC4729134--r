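# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that generator calls never disturb the
#' caller's random-number stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# The 20 standard amino acids, fixed order used by every profile/matrix here.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Point-mutate a protein: each residue independently replaced (by a different
# residue) with probability `rate`.
mutate_protein <- function(protein, rate) {
  if (rate <= 0) return(protein)
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  hit <- runif(length(aa)) < rate
  if (any(hit)) {
    aa[hit] <- vapply(aa[hit], function(a) sample(setdiff(AA20, a), 1L), "")
  }
  paste(aa, collapse = "")
}

# Reverse genetic code: amino acid -> codons (standard table, stops excluded).
codons_for_aa <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) {
      code <- Biostrings::GENETIC_CODE
      gc <<- split(names(code), code)
    }
    gc
  }
})

# Back-translate a protein to a CDS, sampling synonymous codons uniformly.
# A stop codon is appended.
protein_to_cds <- function(protein) {
  aa <- strsplit(protein, "", fixed = TRUE)[[1]]
  tab <- codons_for_aa()
  cod <- vapply(aa, function(a) {
    cs <- tab[[a]]
    if (length(cs) == 1L) cs else sample(cs, 1L)
  }, "")
  paste0(paste(cod, collapse = ""), "TAA")
}

# Ungapped percent identity between two equal-length strings.
pct_identity_aligned <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(x) == length(y))
  100 * mean(x == y)
}

# Global percent identity between two unaligned proteins via Needleman-Wunsch
# (Biostrings); used for generator post-condition checks and small oracles.
pct_identity_global <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
    type = "global"
  )
  Biostrings::pid(aln, type = "PID1")
}

blosum62 <- local({
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

# Runs of `N` of at least `min_len` in a DNA character string.
# Returns a matrix with 0-based half-open [start, end) rows.
n_runs <- function(seq, min_len = 20L) {
  m <- gregexpr(sprintf("N{%d,}", min_len), seq)[[1]]
  if (m[1] == -1L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  cbind(start = starts, end = starts + lens)
}

# Do two 0-based half-open intervals overlap?
overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

`%||%` <- function(a, b) if (is.null(a)) b else a
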