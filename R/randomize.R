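#' Geometric random network on the unit cube
#'
#' Null model for a contact network: nodes are dropped uniformly into
#' [0,1]^dim and the \code{n_edges} globally closest pairs (Euclidean
#' distance) become edges, giving a spatially clustered graph with exactly
#' the observed edge count. Distance ties at the cutoff are broken by
#' (id_a, id_b) lexicographic order, so the construction is deterministic
#' given the positions.
#'
#' @param n_nodes number of nodes.
#' @param n_edges number of edges (<= n_nodes(n_nodes-1)/2).
#' @param seed RNG seed for the positions.
#' @param dim cube dimensionality (default 3, physical space).
#' @param names optional node names (default "1".."n").
#' @param positions optional precomputed n x dim position matrix (used in
#'   place of random positions; for tests).
#' @return an \code{igraph} graph with exactly \code{n_edges} edges.
#' @export
geometric_random_network <- function(n_nodes, n_edges, seed = 1L, dim = 3,
                                     names = NULL, positions = NULL) {
  if (n_edges > n_nodes * (n_nodes - 1) / 2)
    abort("n_edges exceeds the number of node pairs")
  if (is.null(positions))
    positions <- with_seed(seed,
                           matrix(stats::runif(n_nodes * dim), ncol = dim))
  stopifnot(nrow(positions) == n_nodes)
  if (is.null(names)) names <- as.character(seq_len(n_nodes))
  if (n_edges == 0) {
    return(igraph::make_empty_graph(n = n_nodes, directed = FALSE) |>
             igraph::set_vertex_attr("name", value = names))
  }
  dv <- stats::dist(positions)
  # pair (i, j), i < j, in the same order dist() stores them:
  # d(1,2), d(1,3), ..., d(1,n), d(2,3), ...
  i <- rep(seq_len(n_nodes - 1), times = rev(seq_len(n_nodes - 1)))
  j <- unlist(lapply(seq_len(n_nodes - 1), function(x) (x + 1):n_nodes),
              use.names = FALSE)
  ord <- order(as.numeric(dv), i, j)[seq_len(n_edges)]
  igraph::graph_from_data_frame(
    data.frame(from = names[i[ord]], to = names[j[ord]]),
    directed = FALSE, vertices = data.frame(name = names))
}

# adjacency as a list of sorted integer neighbor vectors
adj_list <- function(net) {
  n <- igraph::vcount(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  adj <- vector("list", n)
  for (v in seq_len(n)) adj[[v]] <- integer(0)
  for (r in seq_len(nrow(el))) {
    a <- el[r, 1]; b <- el[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, sort)
}

# number of triangles in a graph given its adjacency list and edge list
count_triangles_el <- function(adj, el) {
  t <- 0
  for (r in seq_len(nrow(el)))
    t <- t + length(intersect(adj[[el[r, 1]]], adj[[el[r, 2]]]))
  t / 3
}

#' Rewire a network toward a target transitivity
#'
#' Attempts \code{sweeps_factor * |E|} degree-preserving double-edge
#' swaps; a swap is kept only if it strictly increases the number of
#' triangles and does not push global transitivity above
#' \code{target_transitivity}. Because degree-preserving swaps leave the
#' connected-triple count unchanged, transitivity comparisons reduce to
#' triangle counts. Edge count and degree sequence are invariant; the
#' output transitivity is always >= the input's.
#'
#' @param net a simple undirected \code{igraph} graph.
#' @param target_transitivity cap on global transitivity (e.g. the
#'   observed network's value). \code{Inf} removes the cap.
#' @param sweeps_factor attempted swaps per edge (default 10).
#' @param seed RNG seed for swap proposals.
#' @return the rewired \code{igraph} graph (vertex attributes preserved).
#' @export
transitivity_rewire <- function(net, target_transitivity = Inf,
                                sweeps_factor = 10, seed = 1L) {
  m <- igraph::ecount(net)
  if (m < 2 || sweeps_factor <= 0) return(net)
  el <- igraph::as_edgelist(net, names = FALSE)
  adj <- adj_list(net)
  triples <- sum(vapply(adj, function(x) {
    k <- length(x); k * (k - 1) / 2
  }, numeric(1)))
  tri <- count_triangles_el(adj, el)
  cap <- if (is.finite(target_transitivity) && triples > 0)
    target_transitivity * triples / 3 + 1e-9 else Inf
  has_edge <- function(a, b) b %in% adj[[a]]
  common <- function(a, b) length(intersect(adj[[a]], adj[[b]]))
  n_try <- round(sweeps_factor * m)
  with_seed(seed, {
    for (it in seq_len(n_try)) {
      pick <- sample.int(m, 2)
      e1 <- el[pick[1], ]; e2 <- el[pick[2], ]
      a <- e1[1]; b <- e1[2]; c <- e2[1]; d <- e2[2]
      if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      # proposed rewiring: (a,b),(c,d) -> (a,c),(b,d)
      if (length(unique(c(a, b, c, d))) < 4) next
      if (has_edge(a, c) || has_edge(b, d)) next
      lost <- common(a, b) + common(c, d)
      # gains must be counted on the graph with both old edges removed,
      # otherwise triangles through a deleted edge are credited
      adj2 <- adj
      adj2[[a]] <- setdiff(adj2[[a]], b)
      adj2[[b]] <- setdiff(adj2[[b]], a)
      adj2[[c]] <- setdiff(adj2[[c]], d)
      adj2[[d]] <- setdiff(adj2[[d]], c)
      gained <- length(intersect(adj2[[a]], adj2[[c]])) +
        length(intersect(adj2[[b]], adj2[[d]]))
      delta <- gained - lost
      if (delta <= 0 || tri + delta > cap) next
      adj2[[a]] <- sort(c(adj2[[a]], c))
      adj2[[c]] <- sort(c(adj2[[c]], a))
      adj2[[b]] <- sort(c(adj2[[b]], d))
      adj2[[d]] <- sort(c(adj2[[d]], b))
      adj <- adj2
      el[pick[1], ] <- c(min(a, c), max(a, c))
      el[pick[2], ] <- c(min(b, d), max(b, d))
      tri <- tri + delta
    }
  })
  out <- igraph::graph_from_edgelist(el, directed = FALSE)
  out <- igraph::add_vertices(out, max(0, igraph::vcount(net) -
                                         igraph::vcount(out)))
  for (at in igraph::vertex_attr_names(net))
    out <- igraph::set_vertex_attr(out, at,
                                   value = igraph::vertex_attr(net, at))
  out
}

#' Gene-randomized network from a randomized segment network
#'
#' Re-populates the segments of a randomized segment network with genes
#' drawn without replacement from the gene pool, each segment receiving as
#' many genes as it originally held, then expands to a gene network by the
#' usual complete-bipartite rule.
#'
#' @param rsin randomized segment network (vertex names = segment ids).
#' @param genes_per_segment named integer vector: segment id -> original
#'   gene count.
#' @param gene_pool character vector of gene ids to draw from.
#' @param seed RNG seed.
#' @return an \code{igraph} gene network.
#' @export
randomize_gin <- function(rsin, genes_per_segment, gene_pool, seed = 1L) {
  segs <- igraph::V(rsin)$name
  y <- stats::setNames(rep(0L, length(segs)), segs)
  known <- intersect(names(genes_per_segment), segs)
  y[known] <- as.integer(genes_per_segment[known])
  if (sum(y) > length(gene_pool))
    abort("gene pool smaller than total gene count")
  drawn <- with_seed(seed, sample(gene_pool, sum(y)))
  assignment <- stats::setNames(rep(segs, y), drawn)
  # vertex chromosome labels are meaningless in the geometric null; tag NA
  rsin2 <- igraph::set_vertex_attr(rsin, "chrom",
                                   value = igraph::vertex_attr(rsin, "chrom") %||%
                                     rep(NA_character_, length(segs)))
  g <- build_gin(rsin2, assignment)
  # genes never drawn stay isolated nodes of the pool universe
  missing <- setdiff(gene_pool, names(assignment))
  if (length(missing))
    g <- igraph::add_vertices(g, length(missing), name = missing)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
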