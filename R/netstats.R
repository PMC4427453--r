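#' Average clustering coefficient
#'
#' Per-node \eqn{C_n = 2 e_n / (k_n (k_n - 1))} with \eqn{e_n} the number
#' of edges among the neighbors of \eqn{n}; nodes with fewer than two
#' neighbors contribute \eqn{C_n = 0} (so a singleton-rich network is not
#' credited with clustering it does not have). The network value is the
#' mean over all nodes.
#'
#' @param net an \code{igraph} graph.
#' @return value in [0, 1]; 0 for an empty graph.
#' @export
clustering_coefficient <- function(net) {
  if (igraph::vcount(net) == 0) return(0)
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  cc[igraph::degree(net) < 2] <- 0
  mean(cc)
}

#' Connectivity centralization
#'
#' Degree centralization \eqn{\frac{N}{N-2}\left(\frac{max(k) -
#' mean(k)}{N-1}\right)}: 0 for regular graphs, 1 for a star. The widely
#' quoted approximation \code{max(k)/N - mean(k)/(N-1)} is available via
#' \code{approximate = TRUE}.
#'
#' @param net an \code{igraph} graph with more than 2 nodes.
#' @param approximate use the approximate form.
#' @return centralization value.
#' @export
centralization <- function(net, approximate = FALSE) {
  N <- igraph::vcount(net)
  if (N <= 2) abort("centralization needs more than 2 nodes")
  k <- igraph::degree(net)
  if (approximate) max(k) / N - mean(k) / (N - 1)
  else N / (N - 2) * (max(k) - mean(k)) / (N - 1)
}

#' Degree heterogeneity
#'
#' \eqn{\sqrt{variance(k)} / mean(k)} with the population variance: the
#' coefficient of variation of the degree distribution. 0 for regular
#' graphs; hub-dominated networks score high.
#'
#' @param net an \code{igraph} graph.
#' @return non-negative value; 0 when the graph has no edges.
#' @export
heterogeneity <- function(net) {
  k <- igraph::degree(net)
  m <- mean(k)
  if (!length(k) || m == 0) return(0)
  sqrt(mean((k - m)^2)) / m
}

#' Characteristic path length and diameter
#'
#' Shortest-path statistics over connected node pairs only (disconnected
#' pairs are excluded rather than given infinite length); optionally
#' restricted to the largest connected component.
#'
#' @param net an \code{igraph} graph.
#' @param scope \code{"connected_pairs"} or \code{"largest_component"}.
#' @return list with \code{characteristic_path_length} and \code{diameter}
#'   (both 0 for an edgeless graph).
#' @export
path_stats <- function(net, scope = c("connected_pairs", "largest_component")) {
  scope <- match.arg(scope)
  if (igraph::ecount(net) == 0)
    return(list(characteristic_path_length = 0, diameter = 0))
  g <- net
  if (scope == "largest_component") {
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
  }
  d <- igraph::distances(g)
  d <- d[upper.tri(d)]
  d <- d[is.finite(d)]
  list(characteristic_path_length = mean(d), diameter = max(d))
}

#' Summarize network topology
#'
#' The standard descriptive suite for contact networks: size, degree
#' statistics (mean, max, population variance, variance/mean,
#' heterogeneity), clustering coefficient, centralization (exact and
#' approximate), path statistics, isolated-node and component counts.
#'
#' @param net an \code{igraph} graph.
#' @param path_scope passed to \code{\link{path_stats}}.
#' @return a \code{network_summary} list.
#' @export
summarize_network <- function(net, path_scope = "connected_pairs") {
  N <- igraph::vcount(net)
  k <- igraph::degree(net)
  mk <- if (N) mean(k) else 0
  vk <- if (N) mean((k - mk)^2) else 0
  ps <- path_stats(net, path_scope)
  comp <- igraph::components(net)
  csize <- sort(comp$csize, decreasing = TRUE)
  big <- if (N) which.max(comp$csize) else integer(0)
  lc_nodes <- if (N) max(comp$csize) else 0
  lc_edges <- if (N)
    igraph::ecount(igraph::induced_subgraph(net, which(comp$membership == big)))
  else 0
  out <- list(
    n_nodes = N,
    n_edges = igraph::ecount(net),
    connected_nodes = if (N) sum(k > 0) else 0,
    isolated_nodes = if (N) sum(k == 0) else 0,
    average_degree = mk,
    max_degree = if (N) max(k) else 0,
    degree_variance = vk,
    variance_over_mean = if (mk > 0) vk / mk else 0,
    heterogeneity = heterogeneity(net),
    clustering_coefficient = clustering_coefficient(net),
    centralization = if (N > 2) centralization(net) else 0,
    centralization_approx = if (N > 2) centralization(net, approximate = TRUE)
    else 0,
    characteristic_path_length = ps$characteristic_path_length,
    diameter = ps$diameter,
    n_components = if (N) comp$no else 0,
    largest_component_nodes = lc_nodes,
    largest_component_edges = lc_edges,
    component_sizes = utils::head(csize, 10))
  class(out) <- "network_summary"
  out
}

#' @export
print.network_summary <- function(x, ...) {
  cat("network summary\n")
  flds <- c("n_nodes", "n_edges", "connected_nodes", "isolated_nodes",
            "average_degree", "max_degree", "variance_over_mean",
            "heterogeneity", "clustering_coefficient", "centralization",
            "characteristic_path_length", "diameter")
  for (f in flds)
    cat(sprintf("  %-28s %s\n", f, format(x[[f]], digits = 4)))
  invisible(x)
}

#' Correlation of mean segment degree with chromosome length
#'
#' Pearson correlation of log10(mean degree per chromosome) against
#' log10(chromosome length). A negative value means short chromosomes form
#' disproportionately many trans contacts. Chromosomes with zero mean
#' degree are dropped (log undefined); named chromosomes can be excluded,
#' e.g. ones dominated by a single hub segment.
#'
#' @param net a segment network with vertex attribute \code{chrom}.
#' @param layout the \code{genome_layout}.
#' @param exclude chromosome names to leave out.
#' @return Pearson r.
#' @export
degree_length_correlation <- function(net, layout, exclude = character()) {
  k <- igraph::degree(net)
  chrom <- igraph::V(net)$chrom
  keep <- !(chrom %in% exclude)
  md <- tapply(k[keep], chrom[keep], mean)
  md <- md[md > 0]
  if (length(md) < 2) abort("need >= 2 chromosomes with nonzero mean degree")
  len <- layout$chrom_lengths[names(md)]
  stats::cor(log10(len), log10(md))
}

#' Least-squares power-law fit to a degree distribution
#'
#' Fits a line to (log10 degree, log10 frequency) over degrees >= 1 with
#' nonzero frequency; the slope is the power-law exponent estimate and the
#' fit correlation (absolute Pearson r of the log-log points) measures
#' linearity.
#'
#' @param degrees vector of node degrees.
#' @return list with \code{slope} and \code{fit_correlation} in [0, 1].
#' @export
powerlaw_slope <- function(degrees) {
  tab <- table(degrees[degrees >= 1])
  d <- as.numeric(names(tab))
  f <- as.numeric(tab)
  if (length(d) < 2) abort("power-law fit needs >= 2 distinct degrees")
  x <- log10(d)
  y <- log10(f)
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       fit_correlation = abs(stats::cor(x, y)))
}
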