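test_that("combined co-expression averages cross-pair correlations", {
  e <- rbind(g1 = c(1, 2, 3), g2 = c(2, 4, 6), g3 = c(3, 2, 1),
             g4 = c(1, 2, 3))
  expect_equal(combined_coexpression(e, "g1", "g4"), 1.0)
  expect_equal(combined_coexpression(e, "g1", "g3"), -1.0)
  # {g1, g3} x {g4}: r = 1 and r = -1 average to 0
  expect_equal(combined_coexpression(e, c("g1", "g3"), "g4"), 0)
  # mean of hand-computed correlations, mixed values
  e2 <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(4, 3, 2, 1))
  expect_equal(combined_coexpression(e2, c("a", "b"), "c"),
               mean(c(cor(e2["a", ], e2["c", ]), cor(e2["b", ], e2["c", ]))))
  # constant profiles are skipped; all-degenerate input errors
  e3 <- rbind(flat = c(1, 1, 1), g1 = c(1, 2, 3))
  expect_error(combined_coexpression(e3, "flat", "g1"), "degenerate")
})

test_that("rank binning forms near-equal blocks with stable ties", {
  b <- bin_series(1:6, (1:6) * 10, bins = 3)
  expect_equal(b$mean_x, c(1.5, 3.5, 5.5))
  expect_equal(b$mean_y, c(15, 35, 55))
  # N = B: each bin is one tuple
  b1 <- bin_series(c(3, 1, 2), c(30, 10, 20), bins = 3)
  expect_equal(b1$mean_x, c(1, 2, 3))
  expect_equal(b1$mean_y, c(10, 20, 30))
  # remainder goes to the earliest bins
  expect_equal(bin_series(1:7, 1:7, bins = 3)$n, c(3, 2, 2))
  # mass conservation and order: concatenated members = x-sorted series
  set.seed(71)
  x <- rnorm(100); y <- rnorm(100)
  b2 <- bin_series(x, y, bins = 30)
  expect_equal(sum(b2$n), 100)
  expect_equal(sum(b2$n * b2$mean_y), sum(y))
  expect_equal(b2$mean_x,
               as.numeric(tapply(sort(x), rep(1:30, b2$n), mean)))
  expect_error(bin_series(1:5, 1:5, bins = 30), "at least as many")
})

test_that("binned correlation flags degenerate responses", {
  expect_equal(binned_correlation(1:60, (1:60) * 2 + 5, bins = 30), 1)
  expect_warning(r <- binned_correlation(1:60, rep(1, 60), bins = 30),
                 "constant")
  expect_true(is.na(r))
})

test_that("binning reveals a planted trend that raw correlation misses", {
  set.seed(72)
  n <- 6000
  x <- runif(n)
  y <- 0.25 * x + rnorm(n, 0, 1)   # heavy noise: raw r small
  expect_lt(abs(cor(x, y)), 0.15)
  expect_gt(binned_correlation(x, y, bins = 30), 0.5)
})

test_that("permutation p-value is calibrated and detects planted trends", {
  set.seed(73)
  x <- runif(400)
  y <- 0.1 * x + rnorm(400)
  pv <- permutation_pvalue(x, y, bins = 30, reps = 300, seed = 74)
  expect_lt(pv$p, 0.05)
  expect_equal(length(pv$null), 300)
  # observed below every null replicate: raw fraction 1
  y_anti <- -5 * x + rnorm(400, 0, 0.01)
  pv2 <- permutation_pvalue(x, y_anti, bins = 30, reps = 100, seed = 75)
  expect_equal(pv2$p, 1.0)
  # null data: p roughly uniform; mean near 0.5 across seeds
  ps <- vapply(1:40, function(s) {
    set.seed(760 + s)
    permutation_pvalue(runif(150), rnorm(150), bins = 30, reps = 60,
                       seed = s)$p
  }, numeric(1))
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  # type-I error at alpha = 0.05 stays near nominal
  expect_lte(mean(ps <= 0.05), 0.15)
})

test_that("pair series ties proximity to gene-set responses", {
  spec <- small_spec()
  sim <- simulate_contacts(spec, seed = 76)
  genes <- simulate_genes(spec$layout, 4, seed = 77)
  asg <- assign_genes(genes, sim$index)
  st <- score_all_pairs(sim$counts, sim$background, sim$index)
  ex <- simulate_expression(genes, asg, sim$truth, sim$index,
                            a = 0.8, sigma_e = 0.1, seed = 78)
  ser <- pair_series(st, asg, expr = ex$expression)
  expect_true(all(is.finite(ser$x)) && all(is.finite(ser$y)))
  expect_gte(nrow(ser), 30)
  pv <- permutation_pvalue(ser$x, ser$y, bins = 30, reps = 300, seed = 79)
  expect_lt(pv$p, 0.01)
  # similarity-table route agrees in direction
  ser2 <- pair_series(st, asg, similarity = ex$similarity)
  pv2 <- permutation_pvalue(ser2$x, ser2$y, bins = 30, reps = 300,
                            seed = 80)
  expect_lt(pv2$p, 0.01)
})
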