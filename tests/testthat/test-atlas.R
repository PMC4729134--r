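toy_atlas <- function(values, type = "array") {
  plat <- stats::setNames(rep("p1", ncol(values)), colnames(values))
  expression_atlas(values, plat, c(p1 = type))
}

test_that("replicate averaging is an exact group-by mean", {
  m <- matrix(c(6, 8, 10, 4, 4, 4), nrow = 1,
              dimnames = list("g1", sprintf("s%d", 1:6)))
  map <- data.frame(sample = sprintf("s%d", 1:6),
                    condition = rep(c("c1", "c2"), each = 3))
  avg <- average_replicates(m, map)
  expect_equal(avg["g1", "c1"], 8)
  expect_equal(avg["g1", "c2"], 4)
  single <- average_replicates(m[, 1, drop = FALSE],
                               map[1, , drop = FALSE])
  expect_equal(unname(single[1, 1]), 6)
  expect_error(average_replicates(m, rbind(map, map[1, ])), "exactly one")
  expect_warning(average_replicates(m[, 1:3, drop = FALSE], map), "dropped")

  for (seed in 1:4) {
    famscan:::with_seed(seed, {
      mm <- matrix(rnorm(5 * 12), 5, 12,
                   dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:12)))
      mp <- data.frame(sample = colnames(mm),
                       condition = sample(c("a", "b", "c"), 12, TRUE))
      got <- average_replicates(mm, mp)
      for (cd in colnames(got)) {
        expect_equal(got[, cd],
                     rowMeans(mm[, mp$condition == cd, drop = FALSE]))
      }
    })
  }
})

test_that("expression calls respect the platform thresholds exactly", {
  arr <- toy_atlas(matrix(c(8.1, 8.0, 7.99, 5.0, 4.99, 0), nrow = 1,
                          dimnames = list("g", sprintf("c%d", 1:6))), "array")
  calls <- call_expression(arr)$calls
  expect_equal(unname(calls[1, ]),
               c("expressed", "detected", "detected", "detected",
                 "background", "background"))
  cnt <- toy_atlas(matrix(c(10, 9, 1, 0), nrow = 1,
                          dimnames = list("g", sprintf("c%d", 1:4))), "count")
  expect_equal(unname(call_expression(cnt)$calls[1, ]),
               c("expressed", "detected", "detected", "background"))
  # every cell gets exactly one of the three calls
  rand <- toy_atlas(matrix(runif(60, 0, 16), 5, 12,
                           dimnames = list(sprintf("g%d", 1:5),
                                           sprintf("c%d", 1:12))))
  expect_true(all(call_expression(rand)$calls %in%
                    c("expressed", "detected", "background")))
  expect_error(expression_atlas(matrix(1, 1, 1, dimnames = list("g", "c")),
                                c(c = "p1"), c(p1 = "weird")),
               "config error")
})

test_that("gene status reflects the strongest call and matches planted intent", {
  v <- matrix(c(9, 3, 6, 3, 3, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("on", "mid", "off"), c("c1", "c2")))
  st <- call_expression(toy_atlas(v))$status
  expect_equal(unname(st), c("gene", "putative", "hypothetical"))

  ex <- generate_expression(syn_config(seed = 61,
                                       expression = list(noise_sd = 0)))
  per_cond <- lapply(names(ex$matrices), function(pf)
    average_replicates(ex$matrices[[pf]],
                       ex$sample_map[ex$sample_map$platform == pf, ]))
  vals <- do.call(cbind, per_cond)
  plat <- stats::setNames(
    ex$sample_map$platform[match(colnames(vals), ex$sample_map$condition)],
    colnames(vals))
  at <- expression_atlas(vals, plat, ex$platforms, po = ex$po_map)
  st <- call_expression(at)$status
  expect_identical(unname(st), unname(ex$truth$intended_status[names(st)]))
})

test_that("PO attribution collects the terms of expressed conditions only", {
  v <- matrix(c(9, 9, 3, 6), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), c("leaf1", "leaf2")))
  at <- toy_atlas(v)
  at$po <- data.frame(condition = c("leaf1", "leaf2"),
                      po = c("PO:0025034", "PO:0025034"))
  po <- attribute_po(at)
  expect_equal(po$gA, "PO:0025034")
  expect_equal(po$gB, character(0))
  at2 <- at
  at2$po <- at2$po[1, , drop = FALSE]
  expect_warning(attribute_po(at2), "without PO mapping")

  for (seed in 1:3) {
    famscan:::with_seed(seed, {
      vv <- matrix(runif(40, 0, 16), 4, 10,
                   dimnames = list(sprintf("g%d", 1:4), sprintf("c%d", 1:10)))
      att <- toy_atlas(vv)
      att$po <- data.frame(condition = colnames(vv),
                           po = sprintf("PO:%07d", sample(5, 10, TRUE)))
      got <- attribute_po(att)
      for (g in rownames(vv)) {
        expect_setequal(got[[g]],
                        unique(att$po$po[att$po$condition %in%
                                           colnames(vv)[vv[g, ] > 8]]))
      }
    })
  }
})

test_that("background smoothing floors at log2 = 5 and is idempotent", {
  v <- matrix(c(3.2, 5.0, 7, 12), nrow = 1,
              dimnames = list("g", sprintf("c%d", 1:4)))
  sm <- smooth_background(toy_atlas(v))
  expect_equal(unname(sm$values[1, ]), c(5, 5, 7, 12))
  hi <- matrix(c(5, 6, 7, 8), nrow = 1,
               dimnames = list("g", sprintf("c%d", 1:4)))
  expect_equal(smooth_background(toy_atlas(hi))$values, hi)
  expect_equal(smooth_background(sm)$values, sm$values)
  # counts enter on the log2(reads + 1) scale before flooring
  cnt <- matrix(c(0, 63, 1023), nrow = 1,
                dimnames = list("g", sprintf("c%d", 1:3)))
  smc <- smooth_background(toy_atlas(cnt, "count"))
  expect_equal(unname(smc$values[1, ]), c(5, 6, 10))
})

test_that("pearson distance is a proper profile dissimilarity", {
  famscan:::with_seed(5, {
    m <- matrix(rnorm(50), 5, 10)
    rownames(m) <- sprintf("g%d", 1:5)
    d <- famscan:::pearson_dist(t(m))
    expect_equal(unname(diag(d)), rep(0, 5))
    expect_true(all(d >= 0 & d <= 2))
    expect_equal(d, t(d))
  })
})

test_that("condition collapse merges within platform below the strict 0.05 cut", {
  base <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  # profile pairs engineered around the threshold
  make <- function(target_r, contrast) {
    # mix base with an orthogonalized contrast to hit the target correlation
    b <- base - mean(base)
    contrast <- contrast - mean(contrast)
    contrast <- contrast - sum(contrast * b) / sum(b * b) * b
    w <- sqrt(1 / target_r^2 - 1) * sqrt(sum(b^2) / sum(contrast^2))
    base + w * contrast
  }
  # mutually orthogonal contrasts keep c3 and c4 dissimilar to each other
  v <- cbind(c1 = base, c2 = base + 1,
             c3 = make(0.96, c(5, -5, 5, -5, 5, -5, 5, -5, 5, -5)),
             c4 = make(0.94, c(5, 5, -5, -5, 5, 5, -5, -5, 5, 5)))
  rownames(v) <- sprintf("g%02d", 1:10)
  stopifnot(abs(cor(v[, "c1"], v[, "c3"]) - 0.96) < 1e-9,
            abs(cor(v[, "c1"], v[, "c4"]) - 0.94) < 1e-9)
  at <- toy_atlas(v + 8)
  col <- collapse_redundant_conditions(at, 0.05)
  mem <- col$members
  holds <- vapply(mem, function(cl) all(c("c1", "c2") %in% cl), TRUE)
  expect_true(any(holds))                       # d = 0 pair merged
  with_c3 <- mem[[which(vapply(mem, function(cl) "c3" %in% cl, TRUE))]]
  expect_true(all(c("c1", "c2", "c3") %in% with_c3))  # d = 0.04 merges
  expect_equal(mem[[which(vapply(mem, function(cl) "c4" %in% cl, TRUE))]],
               "c4")                            # d = 0.06 does not
  # averaged pseudo-condition values are exact
  expect_equal(col$atlas$values[, which(holds)],
               rowMeans(v[, with_c3] + 8))
})

test_that("condition collapse equals a brute-force agglomeration oracle", {
  for (seed in 1:4) {
    famscan:::with_seed(seed + 200, {
      v <- matrix(rnorm(8 * 15, mean = 9, sd = 2), 15, 8,
                  dimnames = list(sprintf("g%02d", 1:15), sprintf("c%d", 1:8)))
      at <- toy_atlas(v)
      thr <- 0.4  # generous cut so random profiles actually merge
      col <- collapse_redundant_conditions(at, thr)
      d <- famscan:::pearson_dist(v)
      oracle <- average_linkage_oracle(d, thr)
      got <- unname(lapply(col$members, sort))
      want <- unname(lapply(oracle, sort))
      expect_setequal(lapply(got, paste, collapse = ";"),
                      lapply(want, paste, collapse = ";"))
    })
  }
})

test_that("zero-variance conditions become singleton pseudo-conditions", {
  v <- cbind(c1 = c(1, 5, 9, 2), c2 = c(1, 5, 9, 2), flat = rep(7, 4))
  rownames(v) <- sprintf("g%d", 1:4)
  col <- collapse_redundant_conditions(toy_atlas(v + 5), 0.05)
  expect_true(any(vapply(col$members, function(cl)
    identical(cl, "flat"), TRUE)))
})

test_that("co-expression groups recover the planted partition", {
  ex <- generate_expression(syn_config(seed = 62,
                                       expression = list(noise_sd = 0)))
  per_cond <- lapply(names(ex$matrices), function(pf)
    average_replicates(ex$matrices[[pf]],
                       ex$sample_map[ex$sample_map$platform == pf, ]))
  vals <- do.call(cbind, per_cond)
  plat <- stats::setNames(
    ex$sample_map$platform[match(colnames(vals), ex$sample_map$condition)],
    colnames(vals))
  at <- expression_atlas(vals, plat, ex$platforms)
  collapsed <- collapse_redundant_conditions(smooth_background(at), 0.05)
  res <- group_coexpressed(collapsed$atlas, 0.15)
  got <- membership(res$groups)
  want <- membership(ex$truth$coexpr_groups)
  expect_equal(rand_index(got, want), 1)

  # permutation invariance: shuffling condition order changes nothing
  perm <- sample(ncol(vals))
  at_p <- expression_atlas(vals[, perm], plat[perm], ex$platforms)
  collapsed_p <- collapse_redundant_conditions(smooth_background(at_p), 0.05)
  res_p <- group_coexpressed(collapsed_p$atlas, 0.15)
  expect_equal(rand_index(membership(res_p$groups), got), 1)
})

test_that("independent random genes stay mostly singletons at the 0.15 cut", {
  famscan:::with_seed(63, {
    v <- matrix(rnorm(20 * 30, 9, 2), 20, 30,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("c%d", 1:30)))
    res <- group_coexpressed(toy_atlas(v), 0.15)
    expect_gte(mean(lengths(res$groups) == 1), 0.9)
  })
})
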