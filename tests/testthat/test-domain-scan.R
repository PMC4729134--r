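make_seeds <- function(n = 3, len = 60, seed = 1) {
  famscan:::with_seed(seed, {
    cons <- famscan:::random_protein(len)
    stats::setNames(replicate(n, famscan:::mutate_protein(cons, 0.05)),
                    sprintf("s%d", seq_len(n)))
  })
}

test_that("profile construction follows the log-odds formula", {
  seeds <- rep(paste(rep("A", 60), collapse = ""), 3)
  names(seeds) <- sprintf("s%d", 1:3)
  prof <- build_profile(seeds, pseudocount = 0)
  expect_equal(prof$length, 60)
  # a column that is 100 percent alanine with no pseudocount scores log2(20)
  expect_equal(unname(prof$scores["A", 1]), log2(20))
  # consensus self-score equals the independent per-column max-sum
  expect_equal(prof$self_score, sum(apply(prof$scores, 2, max)))
  expect_equal(prof$self_score, 60 * log2(20))
  expect_lt(prof$threshold, prof$self_score)
  expect_error(build_profile(seeds[1:2]), "insufficient data")
})

test_that("profile span uses 50 percent column occupancy and mixed columns", {
  seeds <- c(a = paste0(paste(rep("A", 59), collapse = ""), "-R"),
             b = paste0(paste(rep("A", 59), collapse = ""), "-K"),
             c = paste0(paste(rep("A", 59), collapse = ""), "RK"),
             d = paste0(paste(rep("A", 59), collapse = ""), "RR"))
  prof <- build_profile(seeds, pseudocount = 1)
  # column 60 has occupancy 0.5 -> retained; profile keeps 61 columns
  expect_equal(prof$length, 61)
  # column 60: R at frequency 1 among its 2 non-gap rows
  expect_equal(unname(prof$scores["R", 60]),
               log2((1 + 0.05) / (2 * 0.05)))
  # mixed final column: R and K each at frequency 1/2
  expect_equal(unname(prof$scores["K", 61]), log2((0.5 + 0.05) / (2 * 0.05)))
})

test_that("gapless profile scan recovers the consensus and partial matches", {
  seeds <- make_seeds(seed = 2)
  prof <- build_profile(seeds)
  hit <- scan_profile(prof, prof$consensus)
  expect_equal(hit$score, prof$self_score)
  expect_equal(hit$coverage, 1)
  frag <- substr(prof$consensus, 1, 40)
  hit2 <- scan_profile(prof, paste0("MMMM", frag))
  expect_equal(hit2$col_start, 1)
  expect_equal(hit2$col_end, 40)
  expect_lt(hit2$coverage, 0.8)
})

test_that("translated scan finds verbatim queries on both strands of any frame", {
  prot <- famscan:::with_seed(30, famscan:::random_protein(80))
  cds <- simple_cds(prot, stop = FALSE)
  for (frame in 0:2) {
    for (strand in c("+", "-")) {
      genome <- plant_into_genome(cds, at = 4000L + frame, strand = strand,
                                  seed = 50 + frame)
      hsps <- scan_translated(genome, queries = c(q1 = prot))
      expect_gte(nrow(hsps), 1)
      top <- hsps[which.min(hsps$evalue), ]
      expect_equal(top$identity_pct, 100)
      expect_equal(top$strand, strand)
      # the reading frame is the insertion offset modulo 3, measured from the
      # strand's 5' end
      expected_frame <- if (strand == "+") (4000 + frame) %% 3 else
        (10000 - (4000 + frame + nchar(cds))) %% 3
      expect_equal(top$frame, expected_frame)
      # coordinates point exactly at the planted CDS
      expect_equal(top$start, 4000 + frame)
      expect_equal(top$end, 4000 + frame + nchar(cds))
    }
  }
})

test_that("reverse-complementing the genome flips strand but keeps the score", {
  prot <- famscan:::with_seed(31, famscan:::random_protein(70))
  cds <- simple_cds(prot, stop = FALSE)
  g_fwd <- plant_into_genome(cds, strand = "+", seed = 60)
  g_rev <- Biostrings::DNAStringSet(Biostrings::reverseComplement(g_fwd[[1]]))
  names(g_rev) <- names(g_fwd)
  h_fwd <- scan_translated(g_fwd, queries = c(q = prot))
  h_rev <- scan_translated(g_rev, queries = c(q = prot))
  expect_equal(h_fwd$score[which.min(h_fwd$evalue)],
               h_rev$score[which.min(h_rev$evalue)])
  expect_equal(h_rev$strand[which.min(h_rev$evalue)], "-")
})

test_that("HSP scores match a Smith-Waterman oracle and E-values the closed form", {
  prot <- famscan:::with_seed(32, famscan:::random_protein(60))
  mutated <- famscan:::with_seed(33, famscan:::mutate_protein(prot, 0.15))
  genome <- plant_into_genome(simple_cds(mutated, stop = FALSE), seed = 61)
  hsps <- scan_translated(genome, queries = c(q = prot))
  top <- hsps[which.min(hsps$evalue), ]
  frame_aa <- as.character(Biostrings::translate(
    Biostrings::subseq(genome[[1]], top$frame + 1,
                       top$frame + 3 * ((length(genome[[1]]) - top$frame) %/% 3)),
    if.fuzzy.codon = "solve"))
  expect_equal(top$score, sw_local_score_oracle(prot, frame_aa))
  expect_equal(top$evalue,
               0.041 * top$m * top$n_searched * exp(-0.267 * top$score),
               tolerance = 1e-12)
  # E-value is monotonically decreasing in S at fixed m, n
  s_grid <- seq(20, 200, by = 20)
  ev <- karlin_altschul_evalue(s_grid, m = 60, n = 1e6)
  expect_true(all(diff(ev) < 0))
  expect_error(scan_translated(genome, queries = character(0)), "usage error")
})

test_that("region merging equals connected components of the proximity graph", {
  base <- data.frame(query_id = "q", chromosome = "chr1", strand = "+",
                     frame = 0L, score = 100, bitscore = 40, evalue = 1e-10,
                     identity_pct = 90, m = 60L, n_searched = 1e6)
  two <- rbind(cbind(base, start = 1000, end = 1500),
               cbind(base, start = 6500, end = 7000))
  expect_equal(nrow(merge_regions(two, max_gap = 10000)), 1)
  expect_equal(nrow(merge_regions(two, max_gap = 4000)), 2)
  opp <- two
  opp$strand <- c("+", "-")
  opp$start <- c(1000, 1000); opp$end <- c(1500, 1500)
  expect_equal(nrow(merge_regions(opp, max_gap = 10000)), 2)

  for (seed in 1:5) {
    hs <- famscan:::with_seed(seed, {
      n <- 30
      st <- sample.int(2e5, n)
      data.frame(query_id = "q", chromosome = "chr1", strand = "+",
                 frame = 0L, score = 100, bitscore = 40, evalue = 1e-10,
                 identity_pct = 90, m = 60L, n_searched = 1e6,
                 start = st, end = st + sample(200:2000, n, replace = TRUE))
    })
    got <- merge_regions(hs, max_gap = 3000)
    expect_equal(nrow(got),
                 interval_components_oracle(hs$start, hs$end, 3000))
    # regions are disjoint and sorted
    expect_true(all(diff(got$start) > 0))
    expect_true(all(got$start[-1] > got$end[-nrow(got)]))
  }
})

test_that("triage recovers planted class labels and is a partition", {
  cfg <- syn_config(seed = 21, genome = list(
    n_chrom = 1, chrom_len = 4e5, functional = 3, internal_stop = 2,
    truncated = 2, gap_disrupted = 1, decoy = 2))
  sim <- generate_genome(cfg)
  prof <- build_profile(sim$seed_domain_alignment)
  hsps <- scan_translated(sim$genome, prof, sim$seeds)
  regions <- triage_regions(merge_regions(hsps), sim$genome, prof)
  expect_true(all(regions$triage_class %in%
                    c("no_domain", "nonfunctional", "functional",
                      "possibly_assembly")))
  expected <- c(functional = "functional", internal_stop = "nonfunctional",
                truncated = "nonfunctional", gap_disrupted = "possibly_assembly",
                decoy = "no_domain")
  evidence <- c(internal_stop = "internal_stop", truncated = "truncation",
                gap_disrupted = "gap_overlap")
  tg <- sim$truth$planted_genes
  for (i in seq_len(nrow(tg))) {
    j <- which(regions$chromosome == tg$chromosome[i] &
                 regions$start < tg$end[i] & regions$end > tg$start[i] &
                 regions$strand == tg$strand[i])
    expect_length(j, 1)
    expect_equal(regions$triage_class[j], unname(expected[tg$class[i]]))
    if (tg$class[i] %in% names(evidence)) {
      expect_equal(regions$disruption_evidence[j],
                   unname(evidence[tg$class[i]]))
    }
    if (tg$class[i] == "functional") {
      expect_true(is.na(regions$disruption_evidence[j]))
    }
  }
  bad <- regions[1, , drop = FALSE]
  bad$start <- -5; bad$end <- 100
  expect_error(triage_region(bad, sim$genome, prof), "coordinate error")
})
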