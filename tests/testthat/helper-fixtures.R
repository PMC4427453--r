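# Shared fixtures and independent oracles, all built in code.

# small two-chromosome layout: 3 + 2 segments of 500 kb
tiny_layout <- function(bin = 5e5)
  genome_layout(c(chrA = 3 * bin, chrB = 2 * bin), bin_size = bin)

tiny_index <- function() segment_index(tiny_layout())

# independent step-up FDR oracle (never calls p.adjust)
bh_reference <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# brute-force binomial upper tail by direct pmf summation
binom_tail_brute <- function(k, n, m) {
  i <- k:n
  sum(choose(n, i) * m^i * (1 - m)^(n - i))
}

# igraph from an explicit edge character vector plus isolated nodes
toy_graph <- function(edges, isolated = character()) {
  g <- igraph::make_graph(edges, directed = FALSE)
  if (length(isolated)) g <- igraph::add_vertices(g, length(isolated),
                                                  name = isolated)
  g
}

# reduced-size architecture for the slower seeded checks
small_spec <- function(n_reads_per_chrom_pair = 15000, ...) {
  architecture_spec(chrom_lengths = c(chr1 = 10e6, chr2 = 8e6, chr3 = 6e6),
                    n_reads_per_chrom_pair = n_reads_per_chrom_pair, ...)
}

# null architecture: nothing planted anywhere
null_spec <- function(...) {
  architecture_spec(n_planted_contacts = 0, hub_partners = 0,
                    feature_logodds = 0, coexpr_a = 0, ...)
}
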