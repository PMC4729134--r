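random_model <- function(id, seed) {
  famscan:::with_seed(seed, {
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(1:4, 1)
    starts <- sort(sample.int(5e4, n_ex)) + cumsum(rep(200, n_ex))
    ex <- cbind(start = starts, end = starts + sample(50:150, n_ex, TRUE))
    gene_model(id, chrom = "chr1", strand = strand, exons = ex, cds = ex,
               status = sample(c("gene", "putative", "hypothetical"), 1))
  })
}

test_that("GFF round-trip preserves coordinates and the 1-based file convention", {
  m <- gene_model("gA", "chr1", "+", exons = cbind(99, 400))
  path <- tempfile(fileext = ".gff3")
  write_gff(list(m), path)
  lines <- readLines(path)
  expect_equal(lines[1], "##gff-version 3")
  gene_line <- grep("\tgene\t", lines, value = TRUE)[1]
  f <- strsplit(gene_line, "\t")[[1]]
  expect_equal(as.integer(f[4]), 100)
  expect_equal(as.integer(f[5]), 400)
  back <- read_gff(path)
  expect_equal(back$gA$exons, m$exons)
  expect_equal(back$gA$cds, m$cds)
})

test_that("minus-strand exons are kept in transcript 5'->3' order", {
  m <- gene_model("gB", "chr1", "-",
                  exons = rbind(c(100, 200), c(300, 420)),
                  cds = rbind(c(100, 200), c(300, 420)))
  expect_equal(unname(m$exons[1, "start"]), 300)  # transcript-first exon is genomic-last
  path <- tempfile(fileext = ".gff3")
  write_gff(list(m), path)
  back <- read_gff(path)$gB
  expect_equal(back$exons, m$exons)
  expect_equal(back$phase, m$phase)
})

test_that("round-trip of 50 random models is field-identical", {
  models <- lapply(1:50, function(i) random_model(sprintf("g%02d", i), i))
  names(models) <- vapply(models, `[[`, "", "locus_id")
  path <- tempfile(fileext = ".gff3")
  write_gff(models, path)
  back <- read_gff(path)
  expect_setequal(names(back), names(models))
  for (id in names(models)) {
    expect_equal(back[[id]]$exons, models[[id]]$exons, info = id)
    expect_equal(back[[id]]$cds, models[[id]]$cds, info = id)
    expect_equal(back[[id]]$strand, models[[id]]$strand, info = id)
    expect_equal(back[[id]]$status, models[[id]]$status, info = id)
    expect_equal(back[[id]]$phase, models[[id]]$phase, info = id)
  }
})

test_that("malformed GFF lines are reported with their line number", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t100\t.\t+\t.\tID=x",
               "chr1\tsrc\tgene\t1\t100"), path)
  expect_error(read_gff(path), "line 3")
})

test_that("translation follows the standard code and flags defects", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    "ATGGCTTAA", "ATGTAAGCTGCT", strrep("ACGT", 10))))
  m1 <- gene_model("ok", "chr1", "+", exons = cbind(0, 9))
  t1 <- translate_model(m1, genome)
  expect_equal(t1$protein, "MA")
  expect_false(t1$internal_stop)
  expect_false(t1$no_start)
  m2 <- gene_model("broken", "chr1", "+", exons = cbind(9, 21))
  t2 <- translate_model(m2, genome)
  expect_true(t2$internal_stop)
  expect_error(translate_model(gene_model("off", "chr1", "+",
                                          exons = cbind(100, 400)), genome),
               "coordinate error")
})

test_that("a minus-strand model translates like its plus-strand lift", {
  prot <- famscan:::with_seed(77, famscan:::random_protein(40))
  cds <- simple_cds(prot)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  genome <- Biostrings::DNAStringSet(c(
    chrP = paste0(strrep("A", 30), cds, strrep("A", 30)),
    chrM = paste0(strrep("A", 30), rc, strrep("A", 30))))
  mp <- gene_model("p", "chrP", "+", exons = cbind(30, 30 + nchar(cds)))
  mm <- gene_model("m", "chrM", "-", exons = cbind(30, 30 + nchar(cds)))
  expect_equal(translate_model(mp, genome)$protein,
               translate_model(mm, genome)$protein)
  expect_equal(translate_model(mp, genome)$protein, prot)
})

test_that("structure comparison distinguishes confirmed from curated models", {
  a <- gene_model("x", "chr1", "+", exons = rbind(c(0, 100), c(200, 320)))
  expect_equal(compare_structures(a, a)$verdict, "confirmed")
  expect_equal(compare_structures(a, a)$changed_exons, 0)
  b <- gene_model("x", "chr1", "+", exons = rbind(c(0, 100), c(200, 332)))
  cmp <- compare_structures(a, b)
  expect_equal(cmp$verdict, "curated")
  expect_equal(cmp$changed_exons, 1)
  far <- gene_model("y", "chr1", "+", exons = cbind(5000, 5100))
  expect_error(compare_structures(a, far), "not comparable")
  expect_error(compare_structures(a, gene_model("z", "chr1", "-",
                                                exons = cbind(0, 100))),
               "not comparable")
})

test_that("changed_exons matches a brute-force changed-interval oracle", {
  for (seed in 1:8) {
    famscan:::with_seed(seed, {
      n <- sample(3:6, 1)
      starts <- cumsum(sample(200:400, n))
      ex <- cbind(start = starts, end = starts + sample(50:150, n, TRUE))
      k <- sample(0:n, 1)
      ex2 <- ex
      if (k > 0) {
        which_mod <- sample(n, k)
        ex2[which_mod, "end"] <- ex2[which_mod, "end"] + 3 * seq_len(k)
      }
      a <- gene_model("a", "chr1", "+", exons = ex, cds = ex)
      b <- gene_model("b", "chr1", "+", exons = ex2, cds = ex2)
      cmp <- compare_structures(a, b)
      key <- function(m) apply(m, 1, paste, collapse = "-")
      oracle <- max(length(setdiff(key(a$exons), key(b$exons))),
                    length(setdiff(key(b$exons), key(a$exons))))
      expect_equal(cmp$changed_exons, oracle)
      expect_equal(cmp$verdict, if (k == 0) "confirmed" else "curated")
    })
  }
})

test_that("coverage validation supports exons by median depth", {
  m <- gene_model("g", "chr1", "+",
                  exons = rbind(c(100, 200), c(300, 400)))
  uniform <- data.frame(chrom = "chr1", start = 0, end = 1000, depth = 100)
  v <- validate_exons_with_coverage(m, uniform)
  expect_true(all(v$exons$supported))
  expect_false(v$flagged)
  gap <- data.frame(chrom = "chr1", start = c(0, 300), end = c(300, 400),
                    depth = c(100, 0))
  v2 <- validate_exons_with_coverage(m, gap)
  expect_equal(v2$exons$supported, c(TRUE, FALSE))
  expect_true(v2$flagged)
  # a region missing from the track counts as depth 0, with a warning
  partial <- data.frame(chrom = "chr1", start = 0, end = 250, depth = 100)
  expect_warning(v3 <- validate_exons_with_coverage(m, partial),
                 "partially covered")
  expect_false(v3$exons$supported[2])
})

test_that("synthetic truth-derived tracks validate planted exons exactly", {
  cfg <- syn_config(seed = 31, genome = list(n_chrom = 1, chrom_len = 2e5,
                                             functional = 3, internal_stop = 1,
                                             truncated = 1, gap_disrupted = 0,
                                             decoy = 0))
  sim <- generate_genome(cfg)
  tg <- sim$truth$planted_genes
  track <- data.frame(chrom = tg$chromosome, start = tg$start, end = tg$end,
                      depth = 50)
  for (m in sim$models) {
    v <- validate_exons_with_coverage(m, track)
    expect_true(all(v$exons$supported))   # support recall 1.0
  }
  # an unexpressed decoy interval yields no false support
  off <- gene_model("off", "chr1", "+", exons = cbind(10, 500))
  expect_warning(v0 <- validate_exons_with_coverage(off, track))
  expect_false(any(v0$exons$supported))
})
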