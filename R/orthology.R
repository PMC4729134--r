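# Cross-species homology and one-to-one ortholog calling by reciprocal best
# hit, with the retention filter E-value < 1e-20 and percent identity > 40.

#' Score all protein pairs between two proteomes
#'
#' One best-scoring Smith-Waterman local alignment (BLOSUM62, affine gaps
#' 11/1) is retained per pair. E-values use Karlin-Altschul statistics with
#' `m` the query length and `n` the total residue count of the opposing
#' proteome.
#'
#' @param proteome_a,proteome_b named [Biostrings::AAStringSet] (or character
#'   vectors); `proteome_a` is the focal species.
#' @param params a [scan_params()] list (gap penalties and lambda/K are
#'   used).
#' @return data.frame of `PairScore` rows: `gene_a`, `gene_b`, `score`,
#'   `bitscore`, `evalue`, `homology_pct` (percent identity over the aligned
#'   region).
#' @export
score_all_pairs <- function(proteome_a, proteome_b, params = scan_params()) {
  a <- stats::setNames(as.character(proteome_a), names(proteome_a))
  b <- stats::setNames(as.character(proteome_b), names(proteome_b))
  if (length(a) == 0L || length(b) == 0L) stop("usage error: empty proteome")
  if (is.null(names(a))) names(a) <- sprintf("a%d", seq_along(a))
  if (is.null(names(b))) names(b) <- sprintf("b%d", seq_along(b))
  bset <- Biostrings::AAStringSet(b)
  n_db <- sum(nchar(b))
  out <- vector("list", length(a))
  for (i in seq_along(a)) {
    aln <- Biostrings::pairwiseAlignment(
      bset, Biostrings::AAString(a[[i]]),
      type = "local", substitutionMatrix = blosum62(),
      gapOpening = params$gap_open, gapExtension = params$gap_ext
    )
    S <- Biostrings::score(aln)
    out[[i]] <- data.frame(
      gene_a = names(a)[i], gene_b = names(b),
      score = S,
      bitscore = (params$lambda * S - log(params$K)) / log(2),
      evalue = karlin_altschul_evalue(S, nchar(a[[i]]), n_db,
                                      params$lambda, params$K),
      homology_pct = Biostrings::pid(aln, type = "PID1"),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Retain homologous pairs
#'
#' Strict thresholds: `evalue < max_evalue` AND `homology_pct > min_homology`.
#'
#' @param scores data.frame from [score_all_pairs()].
#' @param max_evalue E-value cutoff (default 1e-20, strict `<`).
#' @param min_homology percent-identity cutoff (default 40, strict `>`).
#' @return the retained subset of `scores`.
#' @export
filter_homologs <- function(scores, max_evalue = 1e-20, min_homology = 40) {
  scores[scores$evalue < max_evalue & scores$homology_pct > min_homology, ,
         drop = FALSE]
}

# Best match per gene with the deterministic tie-break chain:
# highest bitscore, then lowest evalue, then lexicographically smallest id.
best_match <- function(scores, from = "gene_a", to = "gene_b") {
  if (nrow(scores) == 0L) {
    return(stats::setNames(character(0), character(0)))
  }
  ord <- order(scores[[from]], -scores$bitscore, scores$evalue, scores[[to]])
  s <- scores[ord, , drop = FALSE]
  first <- !duplicated(s[[from]])
  stats::setNames(s[[to]][first], s[[from]][first])
}

#' Call one-to-one orthologs between two species
#'
#' Gene `A` (focal) and `B` are one-to-one orthologs when `B` is the best
#' retained match of `A` and `A` is the best retained match of `B`
#' (reciprocal best hit). Genes with at least one retained pair but no
#' reciprocal best are homologs only.
#'
#' @param retained filtered scores from [filter_homologs()].
#' @param genes_a character vector of all focal-species gene ids (so genes
#'   with no retained pair are reported as `none`).
#' @return list with `pairs` (data.frame `gene_a`, `gene_b` of reciprocal
#'   best hits) and `cells` (named character vector over `genes_a` with
#'   values `one_to_one`, `homolog_only`, `none`).
#' @export
call_orthologs <- function(retained, genes_a = unique(retained$gene_a)) {
  fwd <- best_match(retained, "gene_a", "gene_b")
  rev <- best_match(retained, "gene_b", "gene_a")
  rbh_a <- names(fwd)[!is.na(rev[fwd]) & rev[fwd] == names(fwd)]
  pairs <- data.frame(gene_a = rbh_a, gene_b = unname(fwd[rbh_a]),
                      stringsAsFactors = FALSE)
  cells <- stats::setNames(rep("none", length(genes_a)), genes_a)
  cells[genes_a %in% retained$gene_a] <- "homolog_only"
  cells[genes_a %in% pairs$gene_a] <- "one_to_one"
  list(pairs = pairs, cells = cells)
}

#' Build the gene x species orthology matrix
#'
#' Runs [score_all_pairs()], [filter_homologs()] and [call_orthologs()] for
#' the focal proteome against every other species and assembles the
#' three-state matrix.
#'
#' @param focal named [Biostrings::AAStringSet]; focal-species proteins.
#' @param others named list of [Biostrings::AAStringSet], one per species.
#' @param params a [scan_params()] list.
#' @param max_evalue,min_homology retention thresholds (see
#'   [filter_homologs()]).
#' @return list with `matrix` (character matrix, genes x species, values
#'   `one_to_one` / `homolog_only` / `none`) and `pairs` (data.frame
#'   `species`, `gene_a`, `gene_b`).
#' @export
orthology_matrix <- function(focal, others, params = scan_params(),
                             max_evalue = 1e-20, min_homology = 40) {
  genes <- names(focal)
  mat <- matrix("none", nrow = length(genes), ncol = length(others),
                dimnames = list(genes, names(others)))
  pairs <- list()
  for (sp in names(others)) {
    sc <- score_all_pairs(focal, others[[sp]], params)
    keep <- filter_homologs(sc, max_evalue, min_homology)
    call <- call_orthologs(keep, genes_a = genes)
    mat[, sp] <- call$cells[genes]
    if (nrow(call$pairs)) {
      pairs[[sp]] <- cbind(species = sp, call$pairs)
    }
  }
  list(matrix = mat,
       pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(species = character(0), gene_a = character(0),
                    gene_b = character(0)))
}
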