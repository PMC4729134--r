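# Synthetic data generators: genomes with planted family genes and pseudogenes,
# multi-species proteomes with a known ortholog map, clade-structured protein
# sets, and multi-platform expression matrices with planted co-regulated groups.
# All randomness flows from the single integer seed in the config.

#' Build a synthetic-data configuration
#'
#' Returns the generator settings used by [generate_genome()],
#' [generate_proteomes()], [generate_clade_proteins()] and
#' [generate_expression()]. Defaults reproduce the study conditions used
#' throughout the package: a 2-Mb genome in two chromosomes carrying
#' 10 functional family genes, 5 internal-stop pseudogenes, 3 truncated
#' pseudogenes and 2 assembly-gap-disrupted pseudogenes; a 60-residue family
#' domain; four-species proteomes with separated identity bands; and a
#' three-array-plus-RNA-seq expression design with planted co-expression
#' groups.
#'
#' @param seed integer; the single source of randomness for all generators.
#' @param genome named list overriding genome-generator settings
#'   (`n_chrom`, `chrom_len`, `functional`, `internal_stop`, `truncated`,
#'   `gap_disrupted`, `decoy`, `domain_len`, `tail_len`, `n_seeds`,
#'   `seed_mut`, `gene_mut`, `tail_mut`, `truncated_keep`, `gap_len`,
#'   `min_gene_sep`, `edge_margin`).
#' @param proteome named list overriding proteome-generator settings
#'   (`n_species`, `n_one_to_one`, `n_homolog_families`,
#'   `paralogs_per_species`, `n_species_specific`, `ortholog_mut`,
#'   `homolog_mut`, `prot_len`).
#' @param clades named list overriding clade-set settings (`n_clades`,
#'   `genes_per_clade`, `anchors_per_clade`, `within_mut`, `between_mut`,
#'   `prot_len`).
#' @param expression named list overriding expression settings (`platforms`,
#'   `n_conditions`, `replicates`, `n_genes`, `n_groups`, `group_size`,
#'   `n_putative`, `n_hypothetical`, `noise_sd`).
#' @return an object of class `syn_config`.
#' @export
#' @examples
#' cfg <- syn_config(seed = 1, genome = list(functional = 5, internal_stop = 2))
syn_config <- function(seed = 1L, genome = list(), proteome = list(),
                       clades = list(), expression = list()) {
  g <- list(
    n_chrom = 2L, chrom_len = 1e6, functional = 10L, internal_stop = 5L,
    truncated = 3L, gap_disrupted = 2L, decoy = 0L,
    domain_len = 60L, tail_len = 120L, n_seeds = 6L,
    seed_mut = 0.05, gene_mut = 0.05, tail_mut = 0.10,
    truncated_keep = 0.75, gap_len = 24L,
    min_gene_sep = 25000L, edge_margin = 5000L
  )
  p <- list(
    n_species = 4L, n_one_to_one = 8L, n_homolog_families = 2L,
    paralogs_per_species = 2L, n_species_specific = 4L,
    ortholog_mut = 0.10, homolog_mut = 0.25, prot_len = 180L
  )
  cl <- list(
    n_clades = 4L, genes_per_clade = 5L, anchors_per_clade = 2L,
    within_mut = 0.08, between_mut = 0.40, prot_len = 150L
  )
  e <- list(
    platforms = c(genechip = "array", grapegen = "array",
                  nimblegen = "array", rnaseq = "count"),
    n_conditions = c(genechip = 16L, grapegen = 16L, nimblegen = 16L,
                     rnaseq = 11L),
    replicates = 3L, n_genes = 30L, n_groups = 4L, group_size = 3L,
    n_putative = 3L, n_hypothetical = 3L, noise_sd = 0.2
  )
  cfg <- list(
    seed = as.integer(seed),
    genome = utils::modifyList(g, genome),
    proteome = utils::modifyList(p, proteome),
    clades = utils::modifyList(cl, clades),
    expression = utils::modifyList(e, expression)
  )
  if (cfg$genome$domain_len < 50L) {
    stop("config error: family domain consensus must be at least 50 aa")
  }
  class(cfg) <- "syn_config"
  cfg
}

# Tissue vocabulary shared by the expression generator and PO attribution.
SYN_TISSUES <- data.frame(
  tissue = c("leaf", "root", "flower", "seed", "berry", "pollen", "bud",
             "tendril"),
  po = c("PO:0025034", "PO:0009005", "PO:0009046", "PO:0009010",
         "PO:0009001", "PO:0025281", "PO:0000055", "PO:0025361"),
  stringsAsFactors = FALSE
)

#' Generate a synthetic genome with planted family genes
#'
#' Plants single-exon family genes of five classes into i.i.d. uniform-ACGT
#' background chromosomes: `functional` (intact ORF carrying the family
#' domain), `internal_stop` (one codon substituted to TAA at least 30 codons
#' from either end, downstream of the domain so the domain stays detectable),
#' `truncated` (only the 5' part of the domain followed by a stop),
#' `gap_disrupted` (a run of >= 20 `N` replacing part of the coding sequence
#' downstream of the domain), and `decoy` (family-like tail but an unrelated
#' domain region, so the region shares homology with seeds yet has no domain).
#'
#' @param config a [syn_config()] object.
#' @return a list with components `genome` (a [Biostrings::DNAStringSet]),
#'   `truth` (a `syn_truth` object; see Details), `models` (list of
#'   [gene_model()] objects, the emitted gene-model set), `seeds` (full-length
#'   seed proteins as an [Biostrings::AAStringSet]) and `seed_domain_alignment`
#'   (the gap-free alignment of the seed domain region used to build the
#'   family PSSM).
#' @details The `truth` object carries `planted_genes` (locus id, chromosome,
#'   0-based half-open start/end, strand, class, final translated protein,
#'   and the genomic disruption interval where applicable), plus the RNG seed.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "syn_config"))
  g <- config$genome
  with_seed(config$seed, {
    dom_cons <- random_protein(g$domain_len)
    tail_cons <- random_protein(g$tail_len)

    seeds <- character(g$n_seeds)
    seed_dom <- character(g$n_seeds)
    for (i in seq_len(g$n_seeds)) {
      d <- mutate_protein(dom_cons, g$seed_mut)
      t <- mutate_protein(tail_cons, g$tail_mut)
      seeds[i] <- paste0("M", d, t)
      seed_dom[i] <- paste0("M", d)
    }
    names(seeds) <- names(seed_dom) <- sprintf("seed%02d", seq_len(g$n_seeds))

    classes <- rep(c("functional", "internal_stop", "truncated",
                     "gap_disrupted", "decoy"),
                   times = c(g$functional, g$internal_stop, g$truncated,
                             g$gap_disrupted, g$decoy))
    n_genes <- length(classes)

    make_gene <- function(class) {
      dom <- mutate_protein(dom_cons, g$gene_mut)
      tl <- mutate_protein(tail_cons, g$tail_mut)
      if (class == "decoy") {
        prot <- paste0("M", random_protein(g$domain_len), tl)
        return(list(cds = protein_to_cds(prot), disrupt = NULL))
      }
      if (class == "truncated") {
        keep <- round(g$truncated_keep * (g$domain_len + 1L)) - 1L
        prot <- paste0("M", substr(dom, 1L, keep))
        return(list(cds = protein_to_cds(prot), disrupt = NULL))
      }
      prot <- paste0("M", dom, tl)
      cds <- protein_to_cds(prot)
      n_cod <- nchar(cds) / 3L
      if (class == "internal_stop") {
        # stop placed downstream of the domain, >= 30 codons from both ends
        lo <- g$domain_len + 12L
        hi <- n_cod - 31L
        at <- sample(seq(lo, hi), 1L)
        substr(cds, 3L * (at - 1L) + 1L, 3L * at) <- "TAA"
        return(list(cds = cds, disrupt = c(3L * (at - 1L), 3L * at)))
      }
      if (class == "gap_disrupted") {
        lo <- 3L * (g$domain_len + 12L)
        at <- sample(seq(lo, nchar(cds) - 31L * 3L - g$gap_len), 1L)
        substr(cds, at + 1L, at + g$gap_len) <-
          paste(rep("N", g$gap_len), collapse = "")
        return(list(cds = cds, disrupt = c(at, at + g$gap_len)))
      }
      list(cds = cds, disrupt = NULL)
    }

    genes <- lapply(classes, make_gene)
    gene_len <- vapply(genes, function(x) nchar(x$cds), 0)

    # distribute genes over chromosomes and pick well-separated positions
    chrom_of <- sort(rep_len(seq_len(g$n_chrom), n_genes))
    per_chrom <- tabulate(chrom_of, nbins = g$n_chrom)
    max_len <- if (n_genes > 0) max(gene_len) else 0
    need <- per_chrom * (g$min_gene_sep + max_len) + 2 * g$edge_margin
    if (any(need > g$chrom_len)) {
      stop("sizing error: chromosome too short for requested genes")
    }
    chrom_names <- sprintf("chr%d", seq_len(g$n_chrom))
    chrom_seq <- vapply(seq_len(g$n_chrom), function(i) random_dna(g$chrom_len), "")
    names(chrom_seq) <- chrom_names

    placements <- vector("list", n_genes)
    idx_by_chrom <- split(seq_len(n_genes), chrom_of)
    for (ci in seq_len(g$n_chrom)) {
      idx <- idx_by_chrom[[as.character(ci)]]
      if (is.null(idx) || length(idx) == 0L) next
      k <- length(idx)
      lo <- g$edge_margin
      hi <- g$chrom_len - g$edge_margin - max_len
      sep <- g$min_gene_sep + max_len
      slack <- (hi - lo) - (k - 1L) * sep
      if (slack < k) {
        stop("sizing error: could not place genes with the requested separation")
      }
      # sample in the separation-reduced span, then add back the spacers
      pos <- sort(sample.int(slack, k)) + lo + (seq_len(k) - 1L) * sep
      for (j in seq_len(k)) {
        placements[[idx[j]]] <- list(chrom = ci, start = pos[j])
      }
    }

    rows <- vector("list", n_genes)
    models <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      pl <- placements[[i]]
      cds <- genes[[i]]$cds
      strand <- sample(c("+", "-"), 1L)
      start0 <- pl$start
      end0 <- start0 + nchar(cds)
      insert <- if (strand == "+") cds else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
      substr(chrom_seq[pl$chrom], start0 + 1L, end0) <- insert
      locus <- sprintf("Fam%02dg%03d", pl$chrom, i)
      disrupt <- genes[[i]]$disrupt
      if (!is.null(disrupt)) {
        # lift CDS-relative disruption to genomic coordinates
        dg <- if (strand == "+") start0 + disrupt else
          c(end0 - disrupt[2], end0 - disrupt[1])
      } else {
        dg <- c(NA_integer_, NA_integer_)
      }
      prot <- as.character(Biostrings::translate(
        Biostrings::DNAString(cds), if.fuzzy.codon = "solve"))
      prot <- sub("\\*$", "", prot)
      rows[[i]] <- data.frame(
        locus_id = locus, chromosome = chrom_names[pl$chrom],
        start = start0, end = end0, strand = strand, class = classes[i],
        protein = prot, disrupt_start = dg[1], disrupt_end = dg[2],
        stringsAsFactors = FALSE
      )
      models[[i]] <- gene_model(
        locus_id = locus, chrom = chrom_names[pl$chrom], strand = strand,
        exons = matrix(c(start0, end0), ncol = 2,
                       dimnames = list(NULL, c("start", "end"))),
        cds = matrix(c(start0, end0), ncol = 2,
                     dimnames = list(NULL, c("start", "end"))),
        status = "gene", class = classes[i]
      )
    }
    planted <- if (n_genes > 0) do.call(rbind, rows) else
      data.frame(locus_id = character(0), chromosome = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 class = character(0), protein = character(0),
                 disrupt_start = integer(0), disrupt_end = integer(0))

    truth <- structure(
      list(planted_genes = planted, ortholog_map = NULL, clade_map = NULL,
           coexpr_groups = NULL, rng_seed = config$seed,
           domain_consensus = dom_cons, tail_consensus = tail_cons),
      class = "syn_truth"
    )
    list(
      genome = Biostrings::DNAStringSet(chrom_seq),
      truth = truth,
      models = models,
      seeds = Biostrings::AAStringSet(seeds),
      seed_domain_alignment = Biostrings::AAStringSet(seed_dom)
    )
  })
}

#' Generate multi-species proteomes with a known ortholog map
#'
#' Species `GV` (focal) plus `SP1`, `SP2`, ... share three kinds of genes:
#' one-to-one ortholog sets (each species one copy of a common ancestor,
#' mutual identity > 60 percent), homolog-only families (several paralogs per
#' species from a family ancestor, no one-to-one pair in the truth map) and
#' species-specific genes (unrelated to everything else, < 30 percent identity
#' across species).
#'
#' @param config a [syn_config()] object.
#' @return list with `proteomes` (named list of [Biostrings::AAStringSet], one
#'   per species) and `truth` (a `syn_truth` whose `ortholog_map` is a
#'   data.frame of unordered cross-species id pairs, stored with
#'   `gene_a < gene_b`; symmetry is by interpretation).
#' @export
generate_proteomes <- function(config) {
  stopifnot(inherits(config, "syn_config"))
  p <- config$proteome
  if (p$ortholog_mut >= 0.5 || p$prot_len < 30L) {
    stop("config error: requested identity bands are infeasible for the sequence length")
  }
  with_seed(config$seed + 1L, {
    species <- c("GV", sprintf("SP%d", seq_len(p$n_species - 1L)))
    prot <- stats::setNames(vector("list", length(species)), species)
    for (s in species) prot[[s]] <- character(0)
    pairs <- list()

    for (i in seq_len(p$n_one_to_one)) {
      anc <- random_protein(p$prot_len)
      ids <- character(length(species))
      for (si in seq_along(species)) {
        id <- sprintf("%s_oto%02d", tolower(species[si]), i)
        prot[[species[si]]][id] <- mutate_protein(anc, p$ortholog_mut)
        ids[si] <- id
      }
      cmb <- utils::combn(ids, 2)
      pairs[[length(pairs) + 1L]] <-
        data.frame(gene_a = pmin(cmb[1, ], cmb[2, ]),
                   gene_b = pmax(cmb[1, ], cmb[2, ]), stringsAsFactors = FALSE)
    }
    for (f in seq_len(p$n_homolog_families)) {
      anc <- random_protein(p$prot_len)
      for (s in species) {
        for (k in seq_len(p$paralogs_per_species)) {
          id <- sprintf("%s_hom%02d_%d", tolower(s), f, k)
          prot[[s]][id] <- mutate_protein(anc, p$homolog_mut)
        }
      }
    }
    for (s in species) {
      for (k in seq_len(p$n_species_specific)) {
        id <- sprintf("%s_uniq%02d", tolower(s), k)
        prot[[s]][id] <- random_protein(p$prot_len)
      }
    }
    omap <- if (length(pairs)) do.call(rbind, pairs) else
      data.frame(gene_a = character(0), gene_b = character(0))
    truth <- structure(
      list(planted_genes = NULL, ortholog_map = omap, clade_map = NULL,
           coexpr_groups = NULL, rng_seed = config$seed),
      class = "syn_truth"
    )
    list(proteomes = lapply(prot, Biostrings::AAStringSet), truth = truth)
  })
}

#' Generate a clade-structured protein set with anchors
#'
#' Each clade descends from its own ancestor (all ancestors mutated from a
#' common family root at `between_mut`); members are mutated from the clade
#' ancestor at `within_mut`, so within-clade similarity clearly exceeds
#' between-clade similarity. `anchors_per_clade` members per clade are marked
#' as anchors (reference proteins of known subfamily) for clade assignment.
#'
#' @param config a [syn_config()] object.
#' @return list with `proteins` ([Biostrings::AAStringSet]), `anchors` (named
#'   character vector anchor id -> clade label) and `truth` (a `syn_truth`
#'   whose `clade_map` labels every sequence).
#' @export
generate_clade_proteins <- function(config) {
  stopifnot(inherits(config, "syn_config"))
  cl <- config$clades
  with_seed(config$seed + 2L, {
    root <- random_protein(cl$prot_len)
    seqs <- character(0)
    clade_map <- character(0)
    anchors <- character(0)
    for (c in seq_len(cl$n_clades)) {
      lab <- sprintf("clade%d", c)
      anc <- mutate_protein(root, cl$between_mut)
      for (m in seq_len(cl$genes_per_clade + cl$anchors_per_clade)) {
        is_anchor <- m <= cl$anchors_per_clade
        id <- if (is_anchor) sprintf("anchor_%s_%d", lab, m) else
          sprintf("gene_%s_%d", lab, m - cl$anchors_per_clade)
        seqs[id] <- mutate_protein(anc, cl$within_mut)
        clade_map[id] <- lab
        if (is_anchor) anchors[id] <- lab
      }
    }
    truth <- structure(
      list(planted_genes = NULL, ortholog_map = NULL, clade_map = clade_map,
           coexpr_groups = NULL, rng_seed = config$seed),
      class = "syn_truth"
    )
    list(proteins = Biostrings::AAStringSet(seqs), anchors = anchors,
         truth = truth)
  })
}

#' Generate multi-platform expression matrices with planted co-expression
#'
#' Emulates a gene-expression compendium over several array platforms
#' (log2 intensities) and one read-count platform. Genes in the same planted
#' group share a tissue on/off profile (on about log2 = 11, off about
#' log2 = 3.5) plus independent Gaussian noise; additional genes are planted
#' as `putative` (intensity between the detection and expression thresholds)
#' and `hypothetical` (background everywhere). Count platforms derive reads
#' from the same latent log2 profile.
#'
#' @param config a [syn_config()] object.
#' @return list with `matrices` (named list of gene x sample matrices, one per
#'   platform), `sample_map` (data.frame sample/condition/platform),
#'   `platforms` (named vector of platform types), `po_map` (data.frame
#'   condition/tissue/po) and `truth` (`syn_truth` with `coexpr_groups`, the
#'   intended per-gene status and per-platform zero-variance flags).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "syn_config"))
  e <- config$expression
  if (any(e$n_conditions < 2L)) {
    stop("config error: at least 2 conditions are required per platform")
  }
  with_seed(config$seed + 3L, {
    n_grouped <- e$n_groups * e$group_size
    n_indep <- e$n_genes - n_grouped - e$n_putative - e$n_hypothetical
    if (n_indep < 0) stop("config error: n_genes too small for the requested groups")
    genes <- sprintf("g%02d", seq_len(e$n_genes))
    kind <- rep(c("grouped", "independent", "putative", "hypothetical"),
                times = c(n_grouped, n_indep, e$n_putative, e$n_hypothetical))
    group_of <- rep(NA_integer_, e$n_genes)
    group_of[seq_len(n_grouped)] <- rep(seq_len(e$n_groups), each = e$group_size)

    tissues <- SYN_TISSUES
    # tissue on/off patterns; each group / independent gene receives a
    # distinct on-set so that planted partitions are exact at zero noise
    used <- character(0)
    pattern_for <- function(on_value = 11) {
      repeat {
        on <- sort(sample(nrow(tissues), sample(2:4, 1L)))
        key <- paste(on, collapse = ",")
        if (!key %in% used) {
          used <<- c(used, key)
          return(ifelse(seq_len(nrow(tissues)) %in% on, on_value, 3.5))
        }
      }
    }
    group_pat <- vapply(seq_len(e$n_groups), function(i) pattern_for(),
                        numeric(nrow(tissues)))
    gene_pat <- matrix(3.5, nrow = e$n_genes, ncol = nrow(tissues))
    for (i in seq_len(e$n_genes)) {
      gene_pat[i, ] <- switch(
        kind[i],
        grouped = group_pat[, group_of[i]],
        independent = pattern_for(),
        putative = pattern_for(on_value = 6),
        hypothetical = rep(3.5, nrow(tissues))
      )
    }

    matrices <- list()
    sample_map <- list()
    po_map <- list()
    for (pf in names(e$platforms)) {
      ncond <- e$n_conditions[[pf]]
      tis <- tissues$tissue[rep_len(seq_len(nrow(tissues)), ncond)]
      cond <- sprintf("%s:%s%02d", pf, tis, seq_len(ncond))
      nrep <- if (e$platforms[[pf]] == "count") 1L else e$replicates
      samples <- as.vector(vapply(seq_len(ncond), function(ci)
        sprintf("%s_r%d", cond[ci], seq_len(nrep)), character(nrep)))
      scond <- rep(cond, each = nrep)
      m <- matrix(0, nrow = e$n_genes, ncol = length(samples),
                  dimnames = list(genes, samples))
      ti <- match(rep(tis, each = nrep), tissues$tissue)
      for (i in seq_len(e$n_genes)) {
        latent <- gene_pat[i, ti] +
          (if (e$noise_sd > 0) stats::rnorm(length(ti), 0, e$noise_sd) else 0)
        if (e$platforms[[pf]] == "count") {
          m[i, ] <- round(pmax(2^(latent - 3) - 1, 0))
        } else {
          m[i, ] <- latent
        }
      }
      matrices[[pf]] <- m
      sample_map[[pf]] <- data.frame(sample = samples, condition = scond,
                                     platform = pf, stringsAsFactors = FALSE)
      po_map[[pf]] <- data.frame(condition = cond, tissue = tis,
                                 po = tissues$po[match(tis, tissues$tissue)],
                                 stringsAsFactors = FALSE)
    }
    zero_var <- lapply(matrices, function(m)
      rownames(m)[apply(m, 1, function(x) stats::var(x) == 0)])
    groups <- split(genes[seq_len(n_grouped)], group_of[seq_len(n_grouped)])
    names(groups) <- sprintf("group%d", seq_along(groups))
    singles <- as.list(genes[-seq_len(n_grouped)])
    names(singles) <- genes[-seq_len(n_grouped)]
    truth <- structure(
      list(planted_genes = NULL, ortholog_map = NULL, clade_map = NULL,
           coexpr_groups = c(groups, singles),
           intended_status = stats::setNames(
             c("gene", "gene", "putative", "hypothetical")[
               match(kind, c("grouped", "independent", "putative",
                             "hypothetical"))], genes),
           zero_variance = zero_var, rng_seed = config$seed),
      class = "syn_truth"
    )
    list(matrices = matrices,
         sample_map = do.call(rbind, unname(sample_map)),
         platforms = e$platforms,
         po_map = do.call(rbind, unname(po_map)),
         truth = truth)
  })
}

#' Write a synthetic genome bundle to disk
#'
#' Emits `genome.fa`, `genes.gff3` (1-based inclusive, `##gff-version 3`),
#' `seeds.fa`, `seed_domain_alignment.fa` and `truth.json`.
#'
#' @param sim result of [generate_genome()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_syn_genome <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    gff = file.path(dir, "genes.gff3"),
    seeds = file.path(dir, "seeds.fa"),
    seed_aln = file.path(dir, "seed_domain_alignment.fa"),
    truth = file.path(dir, "truth.json")
  )
  Biostrings::writeXStringSet(sim$genome, paths["genome"])
  write_gff(sim$models, paths["gff"])
  Biostrings::writeXStringSet(sim$seeds, paths["seeds"])
  Biostrings::writeXStringSet(sim$seed_domain_alignment, paths["seed_aln"])
  jsonlite::write_json(
    list(planted_genes = sim$truth$planted_genes,
         rng_seed = sim$truth$rng_seed),
    paths["truth"], auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(paths)
}
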