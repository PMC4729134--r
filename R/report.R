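# Catalog summaries, paralogous-segment mapping, packaged fixture readers and
# the end-to-end pipeline runner.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "famscan")
  if (!nzchar(p)) stop("fixture not found: ", file)
  p
}

#' Read the packaged family-locus catalog fixture
#'
#' @return data.frame with one row per locus: `locus_id`, `chromosome`,
#'   `start`, `end`, `strand`, `new_v0`, `new_v1`, `position_curated`.
#' @export
read_table1_catalog <- function() {
  utils::read.delim(fixture_path("table1_catalog.tsv"),
                    stringsAsFactors = FALSE)
}

#' Read the packaged candidate-region triage counts fixture
#'
#' @return data.frame `triage_class`, `n_regions`,
#'   `of_which_possibly_assembly`.
#' @export
read_triage_counts <- function() {
  utils::read.delim(fixture_path("triage_counts.tsv"),
                    stringsAsFactors = FALSE)
}

#' Read the packaged subclass/clade membership fixture
#'
#' Member symbols, where enumerated, are validated against [parse_symbol()]
#' (the parsed subclass and clade must match the row) and against the row's
#' gene count.
#'
#' @return data.frame `subclass`, `clade`, `n_genes`, `members` (list column
#'   of symbol vectors; empty where the source only states a count).
#' @export
read_subclass_counts <- function() {
  df <- utils::read.delim(fixture_path("subclass_counts_source.tsv"),
                          stringsAsFactors = FALSE)
  df$members <- lapply(df$members, function(m)
    if (is.na(m)) character(0) else strsplit(m, ";", fixed = TRUE)[[1]])
  for (i in seq_len(nrow(df))) {
    mem <- df$members[[i]]
    if (!length(mem)) next
    if (length(mem) != df$n_genes[i]) {
      stop("fixture row ", i, ": member count disagrees with n_genes")
    }
    p <- parse_symbol(mem)
    if (!all(p$kind == "subclass_clade" & p$subclass == df$subclass[i] &
             p$clade == df$clade[i])) {
      stop("fixture row ", i, ": member symbols do not parse to the row's subclass/clade")
    }
  }
  df
}

#' Summarize a family catalog
#'
#' @param catalog data.frame with at least `locus_id` and `chromosome`;
#'   optional columns `subclass`, `clade`, `new_v0` enrich the summary.
#' @param unplaced_name chromosome name holding unplaced loci (default
#'   `"chr00"`; `"chrUn"` is also common).
#' @return list with `n_loci`, `n_numbered_chromosomes`, `n_unplaced`,
#'   `per_chromosome` (named counts), and, when available, `per_subclass`,
#'   `per_clade` and `n_new_v0`.
#' @export
summarize_catalog <- function(catalog, unplaced_name = "chr00") {
  if (nrow(catalog) == 0L) stop("catalog is empty")
  if (anyDuplicated(catalog$locus_id)) stop("catalog locus ids must be unique")
  chrom <- catalog$chromosome
  placed <- chrom[chrom != unplaced_name]
  out <- list(
    n_loci = nrow(catalog),
    n_numbered_chromosomes = length(unique(placed)),
    n_unplaced = sum(chrom == unplaced_name),
    per_chromosome = table(chrom)
  )
  if ("subclass" %in% names(catalog)) {
    out$per_subclass <- table(catalog$subclass)
  }
  if (all(c("subclass", "clade") %in% names(catalog))) {
    has <- !is.na(catalog$clade)
    out$per_clade <- table(paste0(catalog$subclass[has], ":", catalog$clade[has]))
  }
  if ("new_v0" %in% names(catalog)) out$n_new_v0 <- sum(catalog$new_v0 == 1)
  out
}

#' Map catalog loci onto paralogous chromosome segments
#'
#' A gene belongs to a segment when its interval overlaps it by at least one
#' base. For every paralogous segment pair, subfamilies (or any grouping
#' column) with members overlapping both sides are reported.
#'
#' @param catalog data.frame with `locus_id`, `chromosome`, `start`, `end`
#'   and a grouping column (default `subfamily`).
#' @param segments data.frame of paired intervals: `pair_id`, `chrom_a`,
#'   `start_a`, `end_a`, `chrom_b`, `start_b`, `end_b` (same coordinate
#'   convention as the catalog).
#' @param group_col name of the catalog grouping column.
#' @return data.frame `pair_id`, `group`, `genes_a`, `genes_b` (semicolon
#'   lists), one row per (segment pair, group) with members on both sides;
#'   zero rows when `segments` is empty.
#' @export
map_paralog_segments <- function(catalog, segments, group_col = "subfamily") {
  need <- c("pair_id", "chrom_a", "start_a", "end_a",
            "chrom_b", "start_b", "end_b")
  if (!all(need %in% names(segments))) {
    stop("parse error: segment table must have columns ",
         paste(need, collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(segments))) {
    sg <- segments[i, ]
    in_seg <- function(chrom, s, e) {
      catalog$chromosome == chrom & catalog$start < e & catalog$end > s
    }
    a <- catalog[in_seg(sg$chrom_a, sg$start_a, sg$end_a), , drop = FALSE]
    b <- catalog[in_seg(sg$chrom_b, sg$start_b, sg$end_b), , drop = FALSE]
    shared <- intersect(a[[group_col]], b[[group_col]])
    shared <- shared[!is.na(shared)]
    for (g in shared) {
      out[[length(out) + 1L]] <- data.frame(
        pair_id = sg$pair_id, group = g,
        genes_a = paste(a$locus_id[a[[group_col]] == g], collapse = ";"),
        genes_b = paste(b$locus_id[b[[group_col]] == g], collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(pair_id = character(0), group = character(0),
                      genes_a = character(0), genes_b = character(0)))
  }
  do.call(rbind, out)
}

#' Run the full synthetic-data pipeline
#'
#' Generates a ground-truthed genome, proteomes, clade set and expression
#' compendium from one config, then runs every stage: profile construction
#' and translated scan, region merging and triage, gene-model translation,
#' orthology matrix, phylogeny with clade assignment, symbol assignment,
#' and the expression atlas with PO attribution and co-expression groups.
#' Stage outputs are written under `out_dir` together with a JSON manifest
#' of parameters and file hashes.
#'
#' @param config a [syn_config()].
#' @param out_dir output directory (created; default a fresh temporary
#'   directory).
#' @return list with `catalog` (one row per functional region recovered from
#'   the genome), `regions`, `hsps`, `orthology`, `tree`, `clades`,
#'   `symbols`, `atlas` (calls, PO, groups), `truth` handles and
#'   `manifest_path`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("famscan_run_")) {
  stopifnot(inherits(config, "syn_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logln <- function(...) cat(sprintf(...), "\n", file = log_path, append = TRUE)
  logln("stage=config seed=%d", config$seed)

  sim <- generate_genome(config)
  paths <- write_syn_genome(sim, file.path(out_dir, "genome"))
  logln("stage=generate_genome genes=%d", nrow(sim$truth$planted_genes))

  empty_genome <- nrow(sim$truth$planted_genes) == 0L
  profile <- build_profile(sim$seed_domain_alignment)
  hsps <- scan_translated(sim$genome, profile, sim$seeds)
  regions <- merge_regions(hsps)
  regions <- triage_regions(regions, sim$genome, profile)
  logln("stage=scan hsps=%d regions=%d", nrow(hsps), nrow(regions))

  functional <- regions[!is.na(regions$triage_class) &
                          regions$triage_class == "functional", , drop = FALSE]

  prot <- generate_proteomes(config)
  ortho <- orthology_matrix(prot$proteomes[["GV"]],
                            prot$proteomes[names(prot$proteomes) != "GV"])
  logln("stage=orthology pairs=%d", nrow(ortho$pairs))

  cl <- generate_clade_proteins(config)
  aln <- filter_sites(align_sequences(cl$proteins), 0.95)
  tree <- build_tree(aln, bootstrap_n = 100L, seed = config$seed)
  tree <- collapse_branches(tree, 30)
  clades <- assign_clades(tree, cl$anchors)
  logln("stage=phylo leaves=%d", length(tree$tip.label))

  expr <- generate_expression(config)
  per_cond <- lapply(names(expr$matrices), function(pf)
    average_replicates(expr$matrices[[pf]],
                       expr$sample_map[expr$sample_map$platform == pf, ]))
  values <- do.call(cbind, per_cond)
  cond_platform <- stats::setNames(
    expr$sample_map$platform[match(colnames(values), expr$sample_map$condition)],
    colnames(values))
  atlas <- expression_atlas(values, cond_platform, expr$platforms,
                            po = expr$po_map)
  calls <- call_expression(atlas)
  po <- attribute_po(atlas)
  smoothed <- smooth_background(atlas)
  collapsed <- collapse_redundant_conditions(smoothed, 0.05)
  coexpr <- group_coexpressed(collapsed$atlas, 0.15)
  logln("stage=atlas conditions=%d collapsed=%d", ncol(values),
        ncol(collapsed$atlas$values))

  # catalog: functional regions matched back to planted loci
  catalog <- data.frame(locus_id = character(0), chromosome = character(0),
                        start = numeric(0), end = numeric(0),
                        strand = character(0), triage_class = character(0))
  if (nrow(functional)) {
    tg <- sim$truth$planted_genes
    match_locus <- vapply(seq_len(nrow(functional)), function(i) {
      hit <- which(tg$chromosome == functional$chromosome[i] &
                     tg$start < functional$end[i] &
                     tg$end > functional$start[i] &
                     tg$strand == functional$strand[i])
      if (length(hit)) tg$locus_id[hit[1]] else
        sprintf("novel_%s", functional$region_id[i])
    }, "")
    catalog <- data.frame(
      locus_id = match_locus,
      chromosome = functional$chromosome,
      start = functional$start, end = functional$end,
      strand = functional$strand,
      triage_class = functional$triage_class,
      stringsAsFactors = FALSE
    )
  }
  symbols <- NULL
  if (nrow(catalog)) {
    # synthetic loci carry no subfamily semantics; they are named as one
    # subclass clade so that symbol assignment is exercised end to end
    symbols <- assign_symbols(data.frame(
      locus_id = catalog$locus_id, subclass = "M_GAMMA", clade = 1L,
      chromosome = catalog$chromosome, start = catalog$start,
      stringsAsFactors = FALSE
    ))
    catalog$symbol <- symbols$symbol[match(catalog$locus_id, symbols$locus_id)]
  }
  utils::write.table(catalog, file.path(out_dir, "catalog.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  region_tbl <- regions[, setdiff(names(regions), "hsps")]
  utils::write.table(region_tbl, file.path(out_dir, "regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ortho$matrix, file.path(out_dir, "orthology_matrix.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  ape::write.tree(tree, file.path(out_dir, "consensus_tree.nwk"))

  files <- c(paths, catalog = file.path(out_dir, "catalog.tsv"),
             regions = file.path(out_dir, "regions.tsv"),
             orthology = file.path(out_dir, "orthology_matrix.tsv"),
             tree = file.path(out_dir, "consensus_tree.nwk"))
  manifest <- list(
    seed = config$seed,
    parameters = config[c("genome", "proteome", "clades", "expression")],
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    names(files)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  logln("stage=done")

  list(catalog = catalog, regions = regions, hsps = hsps,
       orthology = ortho, tree = tree, clades = clades, symbols = symbols,
       atlas = list(atlas = atlas, calls = calls, po = po,
                    collapsed = collapsed, coexpr = coexpr),
       truth = list(genome = sim$truth, proteomes = prot$truth,
                    clades = cl$truth, expression = expr$truth),
       out_dir = out_dir, manifest_path = manifest_path)
}
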