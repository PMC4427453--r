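test_that("contact simulation conserves reads and is seed-deterministic", {
  spec <- small_spec()
  s1 <- simulate_contacts(spec, seed = 7)
  s2 <- simulate_contacts(spec, seed = 7)
  expect_equal(s1$counts, s2$counts)
  expect_equal(s1$background, s2$background)
  # reads conserved per chromosome pair
  chrom <- s1$index$chrom
  key <- paste(pmin(chrom[s1$counts$i], chrom[s1$counts$j]),
               pmax(chrom[s1$counts$i], chrom[s1$counts$j]))
  inter <- chrom[s1$counts$i] != chrom[s1$counts$j]
  totals <- tapply(s1$counts$count[inter], key[inter], sum)
  expect_true(all(totals == spec$n_reads_per_chrom_pair))
  # every counted pair has a background entry
  expect_true(all(pair_key(s1$counts$i, s1$counts$j) %in%
                    pair_key(s1$background$i, s1$background$j)))
  # zero reads: empty count table
  s0 <- simulate_contacts(small_spec(n_reads_per_chrom_pair = 0), seed = 1)
  expect_equal(sum(s0$counts$count), 0)
})

test_that("planted pairs are enriched against the emitted background", {
  spec <- small_spec()
  sim <- simulate_contacts(spec, seed = 8)
  pk <- pair_key(sim$truth$planted$i, sim$truth$planted$j)
  bk <- pair_key(sim$background$i, sim$background$j)
  m0 <- sim$background$m[match(pk, bk)]
  k <- sim$counts$count[match(pk, pair_key(sim$counts$i, sim$counts$j))]
  k[is.na(k)] <- 0
  # observed counts on planted pairs far exceed the background expectation
  expected0 <- spec$n_reads_per_chrom_pair * m0
  expect_gt(median(k / expected0), 5)
})

test_that("gene simulation matches its Poisson target and stays in bounds", {
  lay <- genome_layout(c(chr1 = 30e6, chr2 = 20e6), bin_size = 5e5)
  g <- simulate_genes(lay, 5, seed = 9)
  n_seg <- sum(n_segments(lay))
  # mean genes/segment within 3 SE of 5
  expect_lt(abs(nrow(g) / n_seg - 5), 3 * sqrt(5 / n_seg))
  expect_true(all(g$end <= lay$chrom_lengths[g$chrom]))
  expect_true(all(g$start >= 0))
  expect_false(anyDuplicated(g$gene_id) > 0)
  # genes within a segment never overlap
  idx <- segment_index(lay)
  asg <- assign_genes(g, idx)
  for (s in split(g, asg[g$gene_id])) {
    s <- s[order(s$start), ]
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
  expect_equal(nrow(simulate_genes(lay, 0, seed = 1)), 0L)
})

test_that("feature generator separates classes only when asked to", {
  spec <- small_spec()
  sim <- simulate_contacts(spec, seed = 10)
  idx <- sim$index
  trans <- unique(c(sim$truth$planted$i, sim$truth$planted$j))
  cov_of <- function(tr) (tr$end - tr$start) / (idx$end - idx$start)
  # strong log-odds: planted-incident segments clearly higher coverage
  tr3 <- simulate_features(idx, sim$truth, logodds = 3, seed = 11)
  c3 <- cov_of(tr3)
  expect_gt(mean(c3[trans]), mean(c3[-trans]) + 0.2)
  # null: means within noise of each other (averaged over replicates)
  d0 <- vapply(1:10, function(s) {
    c0 <- cov_of(simulate_features(idx, sim$truth, logodds = 0,
                                   seed = 110 + s))
    mean(c0[trans]) - mean(c0[-trans])
  }, numeric(1))
  expect_lt(abs(mean(d0)), 0.05)
  # no planted structure: everything background class, still valid track
  tr <- simulate_features(idx, NULL, logodds = 3, seed = 12)
  expect_equal(nrow(tr), nrow(idx))
})

test_that("null expression shows no cross-pair correlation structure", {
  spec <- small_spec()
  sim <- simulate_contacts(spec, seed = 13)
  genes <- simulate_genes(spec$layout, 4, seed = 14)
  asg <- assign_genes(genes, sim$index)
  ex <- simulate_expression(genes, asg, sim$truth, sim$index, a = 0,
                            sigma_e = 0.1, seed = 15)
  st <- score_all_pairs(sim$counts, sim$background, sim$index)
  ser <- pair_series(st, asg, expr = ex$expression)
  expect_lt(abs(mean(ser$y)), 0.05)
  expect_equal(ncol(ex$expression), 43)  # reference sample count
})

test_that("synteny generator replicates the requested contact fraction", {
  spec <- architecture_spec(n_planted_contacts = 200, hub_partners = 0,
                            chrom_lengths = c(chr1 = 40e6, chr2 = 35e6,
                                              chr3 = 30e6, chr4 = 25e6))
  sim <- simulate_contacts(spec, seed = 16)
  genes <- simulate_genes(spec$layout, 3, seed = 17)
  asg <- assign_genes(genes, sim$index)
  syn <- simulate_synteny(sim$index, genes, asg, sim$truth, 0.5, seed = 18)
  n_cons <- sum(syn$truth_b$planted$conserved)
  n_pl <- nrow(sim$truth$planted)
  expect_equal(nrow(syn$truth_b$planted), n_pl)
  # recovered fraction within the binomial 95% interval around 0.5
  ci <- qbinom(c(0.025, 0.975), n_pl, 0.5)
  expect_gte(n_cons, ci[1])
  expect_lte(n_cons, ci[2])
  # extremes
  syn1 <- simulate_synteny(sim$index, genes, asg, sim$truth, 1, seed = 19)
  expect_true(all(syn1$truth_b$planted$conserved))
  syn0 <- simulate_synteny(sim$index, genes, asg, sim$truth, 0, seed = 20)
  expect_false(any(syn0$truth_b$planted$conserved))
  # ortholog maps are 1:1 within regions by construction
  expect_s3_class(syn$synteny, "synteny_map")
})
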