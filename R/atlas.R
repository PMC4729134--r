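# Expression atlas: replicate averaging, expression calls, Plant Ontology
# attribution, background smoothing, redundancy collapse of conditions and
# co-expression grouping (Pearson distance, average linkage, strict cuts).

#' Average replicate samples into conditions
#'
#' @param matrix_ gene x sample numeric matrix.
#' @param sample_map data.frame with columns `sample`, `condition`; every
#'   sample must map to exactly one condition.
#' @return gene x condition matrix (arithmetic mean over replicates).
#'   Conditions with no samples are dropped with a warning.
#' @export
average_replicates <- function(matrix_, sample_map) {
  if (anyDuplicated(sample_map$sample)) {
    stop("every sample must map to exactly one condition")
  }
  keep <- colnames(matrix_) %in% sample_map$sample
  m <- matrix_[, keep, drop = FALSE]
  cond <- sample_map$condition[match(colnames(m), sample_map$sample)]
  known <- unique(sample_map$condition)
  conds <- unique(cond)
  out <- matrix(0, nrow(m), length(conds),
                dimnames = list(rownames(m), conds))
  for (cd in conds) {
    out[, cd] <- rowMeans(m[, cond == cd, drop = FALSE])
  }
  lost <- setdiff(known, unique(cond))
  if (length(lost)) {
    warning("conditions with no samples dropped: ", paste(lost, collapse = ", "))
  }
  out
}

#' Construct an expression atlas
#'
#' @param values gene x condition numeric matrix (log2 intensities for array
#'   platforms, read counts for count platforms).
#' @param platform named character vector mapping each condition (column) to
#'   its platform name.
#' @param platform_type named character vector mapping platform name to
#'   `"array"` or `"count"`.
#' @param po optional data.frame `condition`, `po` (and optionally `tissue`)
#'   for ontology attribution.
#' @return object of class `expression_atlas`.
#' @export
expression_atlas <- function(values, platform, platform_type, po = NULL) {
  stopifnot(all(colnames(values) %in% names(platform)))
  ptype <- platform_type[platform[colnames(values)]]
  if (any(is.na(ptype)) || !all(ptype %in% c("array", "count"))) {
    stop("config error: unknown platform type")
  }
  structure(list(values = values,
                 platform = platform[colnames(values)],
                 platform_type = platform_type, po = po),
            class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  cat(sprintf("<expression_atlas> %d genes x %d conditions (%d platforms)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$platform))))
  invisible(x)
}

# Expression-call thresholds. Arrays (log2): expressed > 8 (strict),
# detected in [5, 8], background < 5. Counts: expressed >= 10 reads,
# detected 1..9, background 0.
ARRAY_EXPRESSED_MIN <- 8
ARRAY_DETECTED_MIN <- 5
COUNT_EXPRESSED_MIN <- 10

#' Per-cell expression calls and per-gene status
#'
#' Every cell receives exactly one of three calls (see thresholds above).
#' Gene status is `gene` when any cell is `expressed`, `putative` when only
#' `detected` cells exist, `hypothetical` otherwise.
#'
#' @param atlas an [expression_atlas()].
#' @return list with `calls` (character matrix, same shape as the values)
#'   and `status` (named character vector per gene).
#' @export
call_expression <- function(atlas) {
  v <- atlas$values
  type <- atlas$platform_type[atlas$platform]
  calls <- matrix(NA_character_, nrow(v), ncol(v), dimnames = dimnames(v))
  arr <- type == "array"
  if (any(arr)) {
    x <- v[, arr, drop = FALSE]
    calls[, arr] <- ifelse(x > ARRAY_EXPRESSED_MIN, "expressed",
                           ifelse(x >= ARRAY_DETECTED_MIN, "detected",
                                  "background"))
  }
  if (any(!arr)) {
    x <- v[, !arr, drop = FALSE]
    calls[, !arr] <- ifelse(x >= COUNT_EXPRESSED_MIN, "expressed",
                            ifelse(x >= 1, "detected", "background"))
  }
  status <- apply(calls, 1, function(cc) {
    if (any(cc == "expressed")) "gene"
    else if (any(cc == "detected")) "putative"
    else "hypothetical"
  })
  list(calls = calls, status = status)
}

#' Attribute Plant Ontology terms to genes
#'
#' A gene receives the PO term of every condition in which its cell is
#' `expressed` (set union across platforms). Conditions without a PO mapping
#' are skipped with a warning.
#'
#' @param atlas an [expression_atlas()] whose `po` slot (or the `po_map`
#'   argument) maps conditions to PO ids.
#' @param po_map optional data.frame `condition`, `po` overriding the atlas
#'   slot.
#' @return named list: gene -> character vector of PO ids (possibly empty).
#' @export
attribute_po <- function(atlas, po_map = atlas$po) {
  if (is.null(po_map)) stop("no condition -> PO mapping available")
  calls <- call_expression(atlas)$calls
  unmapped <- setdiff(colnames(calls), po_map$condition)
  if (length(unmapped)) {
    warning("conditions without PO mapping skipped: ",
            paste(unmapped, collapse = ", "))
  }
  po_of <- stats::setNames(po_map$po, po_map$condition)
  lapply(stats::setNames(rownames(calls), rownames(calls)), function(g) {
    cond <- colnames(calls)[calls[g, ] == "expressed"]
    sort(unique(unname(po_of[intersect(cond, names(po_of))])))
  })
}

#' Smooth background values for clustering
#'
#' Array cells below the basal log2 value of 5 are raised to 5 (noise there
#' is uninformative for co-expression); count cells are transformed to
#' `log2(reads + 1)` and floored the same way. Idempotent; the input atlas
#' is not modified.
#'
#' @param atlas an [expression_atlas()].
#' @param floor basal log2 value (default 5).
#' @return a new [expression_atlas()] with smoothed log2 values (all
#'   platforms on the log2 scale afterwards).
#' @export
smooth_background <- function(atlas, floor = 5) {
  v <- atlas$values
  type <- atlas$platform_type[atlas$platform]
  cnt <- type == "count"
  if (any(cnt)) {
    x <- v[, cnt, drop = FALSE]
    # already-smoothed atlases are on the log2 scale; only raw counts are
    # transformed (identifiable by the platform type staying "count")
    v[, cnt] <- log2(x + 1)
  }
  v[v < floor] <- floor
  ptype <- atlas$platform_type
  ptype[] <- "array"  # after smoothing everything is on the log2 scale
  expression_atlas(v, atlas$platform, ptype, atlas$po)
}

# Pearson distance d = 1 - r between columns (or rows) of a matrix.
# Zero-variance profiles have undefined correlation; they are returned as NA
# and handled by the callers (singleton clusters).
pearson_dist <- function(m, margin = 2) {
  if (margin == 1) m <- t(m)
  suppressWarnings(d <- 1 - stats::cor(m))
  d
}

# Average-linkage clustering with a strict cut: exactly the merges with
# height < threshold are applied. Zero-variance profiles become singletons.
strict_cut_groups <- function(m, threshold, margin = 2) {
  items <- if (margin == 2) colnames(m) else rownames(m)
  vars <- if (margin == 2) apply(m, 2, stats::var) else apply(m, 1, stats::var)
  flat <- items[vars == 0]
  live <- setdiff(items, flat)
  groups <- list()
  if (length(live) >= 2L) {
    mm <- if (margin == 2) m[, live, drop = FALSE] else m[live, , drop = FALSE]
    d <- pearson_dist(mm, margin)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    k <- length(live) - sum(hc$height < threshold)
    cl <- stats::cutree(hc, k = k)
    groups <- split(names(cl), cl)
  } else if (length(live) == 1L) {
    groups <- list(live)
  }
  groups <- c(groups, as.list(flat))
  names(groups) <- sprintf("cluster%02d", seq_along(groups))
  attr(groups, "hclust") <- if (length(live) >= 2L) hc else NULL
  groups
}

#' Collapse redundant conditions
#'
#' Within each platform, conditions whose family-expression profiles lie
#' within Pearson distance `threshold` of each other (average linkage,
#' merges strictly below the threshold) are averaged into one
#' pseudo-condition. Zero-variance condition profiles cannot be correlated
#' and stay as singletons.
#'
#' @param atlas a smoothed [expression_atlas()] (see [smooth_background()]).
#' @param threshold Pearson-distance cut (default 0.05, strict `<`).
#' @return list with `atlas` (collapsed [expression_atlas()]) and `members`
#'   (named list pseudo-condition -> original conditions).
#' @export
collapse_redundant_conditions <- function(atlas, threshold = 0.05) {
  if (ncol(atlas$values) < 2L) stop("at least 2 conditions are required")
  v <- atlas$values
  new_cols <- list()
  members <- list()
  new_platform <- character(0)
  po_rows <- list()
  for (pf in unique(atlas$platform)) {
    cols <- colnames(v)[atlas$platform == pf]
    sub <- v[, cols, drop = FALSE]
    groups <- if (length(cols) == 1L) list(cols) else
      strict_cut_groups(sub, threshold, margin = 2)
    for (gi in seq_along(groups)) {
      cl <- groups[[gi]]
      id <- sprintf("%s#%02d", pf, gi)
      new_cols[[id]] <- rowMeans(sub[, cl, drop = FALSE])
      members[[id]] <- cl
      new_platform[id] <- pf
      if (!is.null(atlas$po)) {
        po <- unique(atlas$po$po[atlas$po$condition %in% cl])
        if (length(po)) {
          po_rows[[id]] <- data.frame(condition = id, po = po,
                                      stringsAsFactors = FALSE)
        }
      }
    }
  }
  vals <- do.call(cbind, new_cols)
  rownames(vals) <- rownames(v)
  out <- expression_atlas(
    vals, new_platform, atlas$platform_type,
    if (length(po_rows)) do.call(rbind, po_rows) else atlas$po
  )
  list(atlas = out, members = members)
}

#' Group co-expressed genes
#'
#' Hierarchical clustering of gene profiles over the collapsed conditions
#' (Pearson distance, average linkage); groups are the clusters formed by
#' merges strictly below `threshold`. Zero-variance genes are singletons.
#'
#' @param atlas a collapsed, smoothed [expression_atlas()].
#' @param threshold Pearson-distance cut (default 0.15, strict `<`).
#' @return list (`CoexprResult`) with `groups` (named list of gene id
#'   vectors, a partition), `dendrogram` (the [stats::hclust] object over
#'   non-degenerate genes, or NULL), `metric` (record of distance and
#'   linkage) and `conditions` (condition ids used).
#' @export
group_coexpressed <- function(atlas, threshold = 0.15) {
  if (nrow(atlas$values) < 2L) stop("at least 2 genes are required")
  groups <- strict_cut_groups(atlas$values, threshold, margin = 1)
  hc <- attr(groups, "hclust")
  attr(groups, "hclust") <- NULL
  list(groups = groups, dendrogram = hc,
       metric = list(distance = "1 - Pearson r", linkage = "average",
                     threshold = threshold),
       conditions = colnames(atlas$values))
}
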