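test_that("binomial tail matches enumeration on spot cases", {
  expect_equal(binom_tail(0, 100, 0.01), 1.0)
  # 1 - sum_{i<3} C(10,i) 0.1^i 0.9^(10-i)
  expect_equal(binom_tail(3, 10, 0.1), binom_tail_brute(3, 10, 0.1),
               tolerance = 1e-12)
  expect_equal(round(binom_tail(3, 10, 0.1), 4), 0.0702)
  expect_equal(binom_tail(5, 5, 0.5), 0.5^5)
  expect_error(binom_tail(6, 5, 0.5), "k <= n")
  expect_error(binom_tail(1, 5, 1.5), "\\[0, 1\\]")
})

test_that("BH adjustment is step-up, order-preserving and bounded", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))  # ties are fixed points
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  set.seed(11)
  for (rep in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_true(all(q >= p))
    expect_true(max(q) <= 1)
    # order-preserving: adjusted values are nondecreasing in p
    expect_true(all(diff(q[order(p)]) >= 0))
  }
})

test_that("length normalization scales by relative chromosome-pair length", {
  lay <- genome_layout(c(c1 = 2e6, c2 = 2e6, c3 = 6e6), bin_size = 5e5)
  # pair lengths: 4, 8, 8 Mb; mean 20/3 Mb
  mpl <- mean(c(4e6, 8e6, 8e6))
  expect_equal(length_normalize(1e-4, 2e6, 2e6, lay), 1e-4 * mpl / 4e6)
  # a pair exactly at the mean is unchanged
  lay2 <- genome_layout(c(a = 1e6, b = 1e6, c = 1e6), bin_size = 5e5)
  expect_equal(length_normalize(0.01, 1e6, 1e6, lay2), 0.01)
  # pair at half the mean doubles q
  lay3 <- genome_layout(c(a = 1e6, b = 1e6, c = 3e6, d = 3e6), bin_size = 5e5)
  expect_equal(mean_pair_length(lay3) / 2e6, 2)
  expect_equal(length_normalize(1e-4, 1e6, 1e6, lay3), 2e-4)
  # gamma 0 switches normalization off
  expect_equal(length_normalize(0.3, 2e6, 2e6, lay, gamma = 0), 0.3)
  expect_error(length_normalize(0.1, 0, 1e6, lay), "> 0")
})

test_that("proximity value is the observed/expected ratio", {
  expect_equal(proximity_value(20, 1000, 0.005), 4.0)
  expect_equal(proximity_value(5, 1000, 0.005), 1.0)  # k = n m
  expect_equal(proximity_value(0, 1000, 0.005), 0.0)
  expect_error(proximity_value(1, 10, 0), "> 0")
  # alternative definition is monotone decreasing in q_norm
  v <- proximity_value(c(1, 1), c(10, 10), c(0.1, 0.1),
                       q_norm = c(1e-4, 1e-2), method = "neglog_q")
  expect_true(v[1] > v[2])
})

test_that("pair scoring uses chromosome-pair totals and drops cis entries", {
  idx <- tiny_index()
  counts <- contact_counts(c(1, 2, 1), c(4, 4, 2), c(8, 2, 99))
  bg <- background_probs(c(1, 2), c(4, 4), c(0.01, 0.01))
  st <- score_all_pairs(counts, bg, idx)
  # cis pair (1,2) excluded; n is the cross total 8 + 2 = 10 for both
  expect_equal(nrow(st), 2L)
  expect_true(all(st$n == 10))
  expect_equal(st$p[st$i == 1], binom_tail_brute(8, 10, 0.01),
               tolerance = 1e-12)
  expect_equal(st$q, bh_adjust(st$p))
  # proximity column consistent with its definition
  expect_equal(st$proximity, st$k / (st$n * st$m_norm))
  # missing background entry for a counted pair is an error
  expect_error(score_all_pairs(counts, background_probs(1, 4, 0.01), idx),
               "background")
  # single pair with k = n, m = 1 has p = 1
  st1 <- score_all_pairs(contact_counts(1, 4, 5),
                         background_probs(1, 4, 1), idx)
  expect_equal(st1$p, 1)
})

test_that("region significance aggregates counts and background mass", {
  idx <- tiny_index()
  # two 2-segment regions; all four cross pairs have one read
  counts <- contact_counts(c(1, 1, 2, 2, 3), c(4, 5, 4, 5, 4),
                           c(1, 1, 1, 1, 996))
  bg <- background_probs(c(1, 1, 2, 2, 3), c(4, 5, 4, 5, 4),
                         c(0.001, 0.001, 0.001, 0.001, 0.9))
  r <- region_significance(list(chrom = "chrA", start = 0, end = 1e6),
                           list(chrom = "chrB", start = 0, end = 1e6),
                           counts, bg, idx)
  expect_equal(r$k, 4)
  expect_equal(r$m, 0.004)
  expect_equal(r$n, 1000)
  expect_equal(r$p, binom_tail_brute(4, 1000, 0.004), tolerance = 1e-12)
  # a single-segment region pair reduces to the pairwise statistic
  st <- score_all_pairs(counts, bg, idx)
  r1 <- region_significance(list(chrom = "chrA", start = 0, end = 5e5),
                            list(chrom = "chrB", start = 0, end = 5e5),
                            counts, bg, idx)
  expect_equal(r1$p, st$p[st$i == 1 & st$j == 4])
  expect_error(region_significance(list(chrom = "chrA", start = 0, end = 5e5),
                                   list(chrom = "chrA", start = 5e5, end = 1e6),
                                   counts, bg, idx), "different chromosomes")
})

test_that("null simulation keeps the q-value false call rate at its level", {
  sim <- simulate_contacts(null_spec(), seed = 301)
  st <- score_all_pairs(sim$counts, sim$background, sim$index)
  for (alpha in c(0.05, 1e-3)) {
    mc_se <- sqrt(alpha * (1 - alpha) / nrow(st))
    expect_lte(mean(st$q <= alpha), alpha + 3 * mc_se)
  }
})

test_that("planted contacts are recovered with high sensitivity and low FDR", {
  sim <- simulate_contacts(architecture_spec(), seed = 302)
  st <- score_all_pairs(sim$counts, sim$background, sim$index)
  truth_keys <- paste(sim$truth$planted$i, sim$truth$planted$j)
  called <- st[st$q_norm <= 1e-3, ]
  called_keys <- paste(called$i, called$j)
  expect_gte(mean(truth_keys %in% called_keys), 0.95)
  expect_lte(mean(!(called_keys %in% truth_keys)), 0.05)
})
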