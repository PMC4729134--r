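# Phylogeny: site-coverage filtering, bootstrap consensus trees over
# neighbor-joining with JTT maximum-likelihood pairwise distances, support
# based branch collapsing, and anchor-driven clade assignment.

#' Remove low-coverage alignment columns
#'
#' Columns whose non-gap fraction is below `min_coverage` are eliminated
#' (strictly below: a column at exactly the threshold is retained). Column
#' order is preserved; the operation is idempotent.
#'
#' @param aln an [msa()] object.
#' @param min_coverage minimum non-gap fraction (default 0.95).
#' @return a filtered [msa()] object.
#' @export
filter_sites <- function(aln, min_coverage = 0.95) {
  m <- as.matrix(aln)
  keep <- aln$coverage >= min_coverage
  if (!any(keep)) stop("empty alignment: all columns removed by the coverage filter")
  rows <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  msa(stats::setNames(rows, aln$ids))
}

# JTT maximum-likelihood pairwise distances for an alignment matrix.
jtt_distances <- function(m) {
  pd <- phangorn::phyDat(m, type = "AA")
  phangorn::dist.ml(pd, model = "JTT")
}

# Leaf bipartitions of every internal edge of an unrooted tree, as sorted
# character vectors of the smaller-side labels (canonical form).
tree_splits <- function(tree) {
  labs <- tree$tip.label
  parts <- ape::prop.part(tree)
  out <- list()
  for (p in parts) {
    side <- sort(labs[p])
    if (length(side) <= 1L || length(side) >= length(labs) - 1L) next
    comp <- sort(setdiff(labs, side))
    key <- if (length(side) < length(comp) ||
               (length(side) == length(comp) &&
                paste(side, collapse = ";") < paste(comp, collapse = ";")))
      side else comp
    out[[paste(key, collapse = ";")]] <- key
  }
  out
}

# Are two splits (canonical smaller sides) compatible on the same taxon set?
splits_compatible <- function(a, b, taxa) {
  ac <- setdiff(taxa, a)
  bc <- setdiff(taxa, b)
  !length(intersect(a, b)) || !length(intersect(a, bc)) ||
    !length(intersect(ac, b)) || !length(intersect(ac, bc))
}

# Greedy majority-rule-extended consensus: splits sorted by bootstrap
# frequency (ties: larger first by key) are added when compatible with the
# accepted set; the tree is then built from the nested cluster hierarchy.
consensus_from_trees <- function(trees) {
  taxa <- sort(trees[[1]]$tip.label)
  counts <- list()
  for (tr in trees) {
    for (key in names(tree_splits(tr))) {
      counts[[key]] <- (counts[[key]] %||% 0) + 1
    }
  }
  if (!length(counts)) {
    return(list(splits = list(), support = numeric(0), taxa = taxa))
  }
  freq <- unlist(counts) / length(trees)
  ord <- order(-freq, names(freq))
  accepted <- list()
  support <- numeric(0)
  for (k in ord) {
    key <- names(freq)[k]
    side <- strsplit(key, ";", fixed = TRUE)[[1]]
    ok <- all(vapply(accepted, splits_compatible, TRUE, b = side, taxa = taxa))
    if (ok) {
      accepted[[key]] <- side
      support[key] <- 100 * freq[k]
    }
  }
  list(splits = accepted, support = support, taxa = taxa)
}

# Build an ape::phylo from compatible splits. The tree is represented rooted
# at an arbitrary taxon-free basal node; each split becomes the cluster on
# the side not containing the first taxon, so clusters form a laminar family.
tree_from_splits <- function(splits, support, taxa) {
  first <- taxa[1]
  clusters <- lapply(names(splits), function(key) {
    side <- splits[[key]]
    if (first %in% side) setdiff(taxa, side) else side
  })
  labels <- sprintf("%g", unname(support))
  ord <- order(lengths(clusters))
  clusters <- clusters[ord]
  labels <- labels[ord]
  build <- function(members, avail) {
    # avail: indices of clusters strictly inside `members`, largest last
    child_cl <- avail[vapply(avail, function(i)
      all(clusters[[i]] %in% members) && length(clusters[[i]]) < length(members),
      TRUE)]
    taken <- character(0)
    parts <- character(0)
    for (i in rev(child_cl)) {  # largest first: maximal clusters only
      cl <- clusters[[i]]
      if (any(cl %in% taken)) next
      parts <- c(parts, paste0(build(cl, child_cl), labels[i]))
      taken <- c(taken, cl)
    }
    singles <- setdiff(members, taken)
    paste0("(", paste(c(parts, singles), collapse = ","), ")")
  }
  nwk <- paste0(build(taxa, seq_along(clusters)), ";")
  ape::read.tree(text = nwk)
}

#' Build a bootstrap consensus tree
#'
#' Pairwise distances under the JTT maximum-likelihood model feed
#' neighbor-joining; `bootstrap_n` replicates resample filtered alignment
#' columns with replacement, and the majority-rule-extended consensus of the
#' replicate trees is returned with per-branch support (replicate frequency
#' x 100) stored as internal node labels.
#'
#' @param aln a site-filtered [msa()] object with at least 4 sequences and
#'   at least 10 columns.
#' @param method currently `"nj_jtt"`.
#' @param bootstrap_n number of bootstrap replicates (default 100).
#' @param seed integer seed controlling column resampling.
#' @return an [ape::phylo] tree with node labels carrying supports (0-100);
#'   attribute `bootstrap_n` records the replicate count.
#' @export
build_tree <- function(aln, method = "nj_jtt", bootstrap_n = 100L, seed = 1L) {
  stopifnot(method == "nj_jtt")
  m <- as.matrix(aln)
  if (nrow(m) < 4L) stop("at least 4 sequences are required for an unrooted tree")
  if (ncol(m) < 10L) stop("unreliable input: fewer than 10 retained columns")
  trees <- with_seed(seed, {
    lapply(seq_len(bootstrap_n), function(b) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      ape::nj(jtt_distances(m[, cols, drop = FALSE]))
    })
  })
  cons <- consensus_from_trees(trees)
  tree <- tree_from_splits(cons$splits, cons$support, cons$taxa)
  attr(tree, "bootstrap_n") <- bootstrap_n
  tree
}

#' Collapse weakly supported branches
#'
#' Internal branches with bootstrap support strictly below `min_support` are
#' contracted into polytomies. The leaf set is unchanged and the internal
#' branch count never increases.
#'
#' @param tree an [ape::phylo] with numeric node labels (supports).
#' @param min_support support threshold (default 30; a branch at exactly the
#'   threshold is kept).
#' @return the collapsed tree.
#' @export
collapse_branches <- function(tree, min_support = 30) {
  sup <- suppressWarnings(as.numeric(tree$node.label))
  ntip <- length(tree$tip.label)
  weak <- which(!is.na(sup) & sup < min_support) + ntip
  weak <- setdiff(weak, ntip + 1L)  # never contract the root
  if (!length(weak)) return(tree)
  edge <- tree$edge
  parent_of <- function(n) edge[edge[, 2] == n, 1]
  remap <- seq_len(ntip + tree$Nnode)
  for (n in sort(weak, decreasing = TRUE)) {
    p <- parent_of(n)
    while (remap[p] != p) p <- remap[p]
    remap[n] <- p
  }
  resolve <- function(n) { while (remap[n] != n) n <- remap[n]; n }
  keep <- !(edge[, 2] %in% weak)
  new_edge <- edge[keep, , drop = FALSE]
  new_edge[, 1] <- vapply(new_edge[, 1], resolve, 0)
  kept_nodes <- sort(unique(c(ntip + 1L, new_edge[new_edge[, 1] > ntip, 1],
                              new_edge[new_edge[, 2] > ntip, 2])))
  node_map <- stats::setNames(ntip + seq_along(kept_nodes), kept_nodes)
  big <- new_edge > ntip
  new_edge[big] <- node_map[as.character(new_edge[big])]
  out <- list(edge = new_edge, Nnode = length(kept_nodes),
              tip.label = tree$tip.label,
              node.label = tree$node.label[kept_nodes - ntip])
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  attr(out, "bootstrap_n") <- attr(tree, "bootstrap_n")
  out
}

#' Assign clade labels from anchor leaves
#'
#' For every unlabeled leaf, candidate clades are the sides (containing the
#' leaf) of all splits of the collapsed tree, plus the full leaf set. The
#' smallest candidate containing at least one anchor determines the label,
#' provided its anchors agree; leaves whose smallest anchored clade mixes
#' labels are `unplaced`. The search is rooting-independent.
#'
#' @param tree an [ape::phylo] (typically from [collapse_branches()]).
#' @param anchors named character vector: anchor leaf id -> subfamily label;
#'   at least one anchor per expected subfamily.
#' @return named character vector: leaf id -> label (anchors keep their own
#'   label).
#' @export
assign_clades <- function(tree, anchors) {
  labs <- tree$tip.label
  if (!any(names(anchors) %in% labs)) stop("no anchor is present in the tree")
  ntip <- length(labs)
  # clades below each internal node and their complements
  desc <- vector("list", tree$Nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    p <- po$edge[k, 1] - ntip
    ch <- po$edge[k, 2]
    add <- if (ch <= ntip) labs[ch] else desc[[ch - ntip]]
    desc[[p]] <- c(desc[[p]], add)
  }
  sides <- list()
  for (d in desc) {
    if (length(d) >= 2L && length(d) < ntip) {
      sides[[length(sides) + 1L]] <- d
      comp <- setdiff(labs, d)
      if (length(comp) >= 2L) sides[[length(sides) + 1L]] <- comp
    }
  }
  sides[[length(sides) + 1L]] <- labs
  out <- stats::setNames(rep(NA_character_, ntip), labs)
  anchor_in <- names(anchors)[names(anchors) %in% labs]
  for (leaf in labs) {
    if (leaf %in% anchor_in) {
      out[leaf] <- anchors[leaf]
      next
    }
    cand <- sides[vapply(sides, function(s)
      leaf %in% s && any(anchor_in %in% s), TRUE)]
    if (!length(cand)) {
      out[leaf] <- "unplaced"
      next
    }
    best <- cand[[which.min(lengths(cand))]]
    labels_here <- unique(anchors[anchor_in[anchor_in %in% best]])
    out[leaf] <- if (length(labels_here) == 1L) labels_here else "unplaced"
  }
  out
}
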