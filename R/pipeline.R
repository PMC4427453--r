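#' Pipeline configuration
#'
#' Collects the tunables of the full analysis: significance cutoff,
#' length-normalization exponent, proximity definition, binning and
#' permutation settings, exclusion lists and per-stage seeds (per-stage so
#' any stage can be re-run in isolation).
#'
#' @param tau q_norm confidence cutoff for the segment network.
#' @param gamma length-normalization exponent.
#' @param proximity \code{"obs_exp"} or \code{"neglog_q"}.
#' @param bins association rank bins.
#' @param reps permutation replicates (association and conservation).
#' @param exclude_chroms chromosomes excluded from enrichment classes.
#' @param path_scope path-statistic scope, see \code{\link{path_stats}}.
#' @param sweeps_factor rewiring sweeps per edge.
#' @param seeds named list of per-stage seeds (\code{simulate},
#'   \code{randomize}, \code{associate}, \code{conserve}).
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(tau = 1e-3, gamma = 1, proximity = "obs_exp",
                            bins = 30, reps = 1000,
                            exclude_chroms = character(),
                            path_scope = "connected_pairs",
                            sweeps_factor = 10,
                            seeds = list(simulate = 1L, randomize = 2L,
                                         associate = 3L, conserve = 4L)) {
  if (tau <= 0 || tau > 1) abort("tau must lie in (0, 1]")
  structure(list(tau = tau, gamma = gamma, proximity = proximity,
                 bins = bins, reps = reps,
                 exclude_chroms = exclude_chroms,
                 path_scope = path_scope, sweeps_factor = sweeps_factor,
                 seeds = seeds),
            class = "pipeline_config")
}

#' Run the full trans-contact analysis
#'
#' Orchestrates every stage on in-memory inputs: contact significance,
#' segment- and gene-network construction, matched randomization, network
#' summaries, feature enrichment, binned association and (when a synteny
#' map and second-species network are supplied) conservation scoring.
#' Deterministic given the config's seeds.
#'
#' @param counts,background,index contact inputs, see
#'   \code{\link{score_all_pairs}}.
#' @param genes optional gene table (enables GIN, clusters, association).
#' @param features optional named list of feature tracks.
#' @param tfbs optional named list of binding-site tracks.
#' @param expr optional expression matrix.
#' @param similarity optional gene-pair similarity table.
#' @param synteny optional \code{synteny_map}.
#' @param gin_b optional second-species gene network (for conservation).
#' @param config a \code{\link{pipeline_config}}.
#' @return list of stage artifacts (\code{stats}, \code{sin}, \code{gin},
#'   \code{rsin}, \code{rgin}, summaries, enrichment and association
#'   results, conservation results, and a stage \code{log}).
#' @export
run_pipeline <- function(counts, background, index, genes = NULL,
                         features = NULL, tfbs = NULL, expr = NULL,
                         similarity = NULL, synteny = NULL, gin_b = NULL,
                         config = pipeline_config()) {
  log <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message("[transnet] ", msg)
    log <<- c(log, msg)
  }
  out <- list(config = config)

  stats <- score_all_pairs(counts, background, index,
                           gamma = config$gamma,
                           proximity = config$proximity)
  note("significance: %d inter-chromosomal pairs scored", nrow(stats))
  out$stats <- stats

  sin <- build_sin(stats, config$tau, index)
  note("network: %d edges at tau = %g", igraph::ecount(sin), config$tau)
  out$sin <- sin
  out$sin_summary <- summarize_network(sin, config$path_scope)

  rsin <- geometric_random_network(igraph::vcount(sin),
                                   igraph::ecount(sin),
                                   seed = config$seeds$randomize,
                                   names = igraph::V(sin)$name)
  rsin <- transitivity_rewire(rsin,
                              target_transitivity =
                                igraph::transitivity(sin, type = "global"),
                              sweeps_factor = config$sweeps_factor,
                              seed = config$seeds$randomize)
  out$rsin <- rsin
  out$rsin_summary <- summarize_network(rsin, config$path_scope)
  note("randomization: %d edges, variance/mean %.3f",
       igraph::ecount(rsin), out$rsin_summary$variance_over_mean)

  if (!is.null(genes)) {
    assignment <- assign_genes(genes, index)
    out$assignment <- assignment
    gin <- build_gin(sin, assignment)
    out$gin <- gin
    out$gin_summary <- summarize_network(gin, config$path_scope)
    out$clusters <- spatial_clusters(sin, assignment)
    note("gin: %d edges, %d spatial clusters",
         igraph::ecount(gin), length(out$clusters))
    y <- table(assignment)
    out$rgin <- randomize_gin(rsin,
                              stats::setNames(as.integer(y), names(y)),
                              genes$gene_id,
                              seed = config$seeds$randomize)
  }

  if (!is.null(features)) {
    classes <- classify_segments(sin, index, config$exclude_chroms)
    out$classes <- classes
    out$enrichment <- feature_enrichment(classes, features, index)
    note("enrichment: %d features over %d trans / %d other segments",
         length(features), length(classes$trans), length(classes$other))
    if (!is.null(tfbs)) {
      out$tfbs_counts <- tfbs_mean_counts(classes, tfbs, index)
      if (!is.null(genes))
        out$cluster_binding <- cluster_binding_percent(out$clusters, genes,
                                                       tfbs)
    }
  }

  if (!is.null(genes) && (!is.null(expr) || !is.null(similarity))) {
    series <- pair_series(stats, out$assignment, expr = expr,
                          similarity = similarity)
    out$series <- series
    if (nrow(series) >= config$bins) {
      out$association <- permutation_pvalue(series$x, series$y,
                                            bins = config$bins,
                                            reps = config$reps,
                                            seed = config$seeds$associate)
      note("association: binned r = %.3f, permutation p = %.4g",
           out$association$r_observed, out$association$p)
    } else note("association skipped: %d < %d tuples", nrow(series),
                config$bins)
  }

  if (!is.null(synteny) && !is.null(gin_b) && !is.null(out$gin)) {
    out$conservation <- conservation_scores(out$gin, gin_b, synteny)
    out$conservation_null <- shuffle_null(out$gin, gin_b, synteny,
                                          reps = config$reps,
                                          seed = config$seeds$conserve)
    note("conservation: %d/%d regions overlap (null mean %.1f)",
         out$conservation_null$observed, nrow(out$conservation),
         out$conservation_null$null_mean)
  }

  out$log <- log
  out
}
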