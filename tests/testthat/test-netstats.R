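test_that("clustering coefficient averages per-node values with zeros", {
  expect_equal(clustering_coefficient(toy_graph(c("A","B","B","C","C","A"))),
               1.0)
  expect_equal(clustering_coefficient(toy_graph(c("H","A","H","B","H","C"))),
               0.0)  # star: no closed triples
  g <- toy_graph(c("A","B","A","C","B","C","C","D"))
  expect_equal(clustering_coefficient(g), (1 + 1 + 1/3 + 0) / 4)
  # isolated nodes contribute zero, diluting the average
  g2 <- toy_graph(c("A","B","A","C","B","C"), isolated = c("X", "Y"))
  expect_equal(clustering_coefficient(g2), 3/5)
  expect_equal(clustering_coefficient(igraph::make_empty_graph(0,
                                                               directed = FALSE)),
               0)
})

test_that("centralization separates stars from regular graphs", {
  star4 <- toy_graph(c("H","A","H","B","H","C"))
  expect_equal(centralization(star4), 1.0)
  path3 <- toy_graph(c("A","B","B","C"))
  expect_equal(centralization(path3), 1.0)
  ring <- toy_graph(c("A","B","B","C","C","D","D","A"))
  expect_equal(centralization(ring), 0)  # 2-regular
  expect_error(centralization(toy_graph(c("A","B"))), "more than 2")
  # approximate form: max(k)/N - mean(k)/(N-1)
  expect_equal(centralization(star4, approximate = TRUE), 3/4 - 1.5/3)
})

test_that("heterogeneity is the degree coefficient of variation", {
  expect_equal(heterogeneity(toy_graph(c("A","B","B","C","C","A"))), 0)
  expect_equal(heterogeneity(toy_graph(c("A","C","B","C"))),
               sqrt(2/9) / (4/3))  # degrees 1,1,2
  expect_equal(heterogeneity(igraph::make_empty_graph(3, directed = FALSE)),
               0)
})

test_that("path statistics cover connected pairs only", {
  path3 <- toy_graph(c("A","B","B","C"))
  ps <- path_stats(path3)
  expect_equal(ps$characteristic_path_length, 4/3)
  expect_equal(ps$diameter, 2)
  single <- toy_graph(c("A","B"))
  expect_equal(path_stats(single), list(characteristic_path_length = 1,
                                        diameter = 1))
  two <- toy_graph(c("A","B","C","D"))
  ps2 <- path_stats(two)
  expect_equal(ps2$characteristic_path_length, 1)  # disconnected excluded
  expect_equal(ps2$diameter, 1)
  expect_equal(path_stats(two, scope = "largest_component")$diameter, 1)
})

test_that("network summary is internally consistent and relabel-invariant", {
  g <- toy_graph(c("A","B","A","C","B","C","C","D"), isolated = "E")
  s <- summarize_network(g)
  expect_equal(s$n_nodes, 5)
  expect_equal(s$n_edges, 4)
  expect_equal(s$average_degree, 2 * s$n_edges / s$n_nodes)
  expect_equal(s$isolated_nodes, 1)
  expect_equal(s$heterogeneity,
               sqrt(s$variance_over_mean / s$average_degree))
  expect_equal(s$clustering_coefficient, (1 + 1 + 1/3 + 0 + 0) / 5)
  # relabeling the nodes changes nothing
  g2 <- toy_graph(c("n4","n5","n4","n1","n5","n1","n1","n2"),
                  isolated = "n3")
  s2 <- summarize_network(g2)
  expect_equal(s2[setdiff(names(s2), "component_sizes")],
               s[setdiff(names(s), "component_sizes")])
  # empty graph: all-zero summary with N set
  s0 <- summarize_network(igraph::make_empty_graph(4, directed = FALSE))
  expect_equal(s0$n_nodes, 4)
  expect_equal(s0$n_edges, 0)
  expect_equal(s0$average_degree, 0)
})

test_that("randomized geometric networks have Poisson-like degree spread", {
  g <- geometric_random_network(2000, 1577, seed = 41)
  s <- summarize_network(g)
  expect_gte(s$variance_over_mean, 0.85)
  expect_lte(s$variance_over_mean, 1.15)
})

test_that("degree-length correlation sees the planted log-log line", {
  lay <- genome_layout(c(X = 1e6, Y = 2e6, Z = 4e6, H = 8e6),
                       bin_size = 5e5)
  # mean degrees per chromosome: X 4, Y 2, Z 1 (H excluded as helper)
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("x","x","x","x","y","y","z"),
               to   = c("h1","h2","h3","h4","h1","h2","h3")),
    directed = FALSE,
    vertices = data.frame(name = c("x","y","z","h1","h2","h3","h4"),
                          chrom = c("X","Y","Z","H","H","H","H")))
  expect_equal(degree_length_correlation(g, lay, exclude = "H"), -1)
  # two usable chromosomes: |r| = 1 degenerate
  expect_equal(abs(degree_length_correlation(g, lay,
                                             exclude = c("H", "Z"))), 1)
})

test_that("power-law fit recovers exact log-linear histograms", {
  degrees <- rep(c(1, 2, 4, 8), c(64, 16, 4, 1))  # f(d) = 64 d^-2
  fit <- powerlaw_slope(degrees)
  expect_equal(fit$slope, -2)
  expect_equal(fit$fit_correlation, 1)
  expect_error(powerlaw_slope(rep(3, 10)), "distinct")
  # hub-dominated synthetic network: negative slope
  sim <- simulate_contacts(architecture_spec(), seed = 43)
  st <- score_all_pairs(sim$counts, sim$background, sim$index)
  sin <- build_sin(st, 1e-3, sim$index)
  expect_lt(powerlaw_slope(igraph::degree(sin))$slope, 0)
})
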