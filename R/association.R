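#' Combined co-expression of two gene sets
#'
#' Mean Pearson correlation across samples over all cross-set gene pairs.
#' Genes with a constant expression profile are skipped (their correlation
#' is undefined); it is an error if every pair is degenerate.
#'
#' @param expr genes-by-samples numeric matrix with gene ids as rownames.
#' @param genes_a,genes_b character vectors of gene ids.
#' @return value in [-1, 1].
#' @export
combined_coexpression <- function(expr, genes_a, genes_b) {
  if (ncol(expr) < 2) abort("need >= 2 samples")
  ga <- intersect(genes_a, rownames(expr))
  gb <- intersect(genes_b, rownames(expr))
  if (!length(ga) || !length(gb)) abort("gene set absent from matrix")
  ok <- function(g) apply(expr[g, , drop = FALSE], 1, stats::sd) > 0
  ga <- ga[ok(ga)]
  gb <- gb[ok(gb)]
  if (!length(ga) || !length(gb))
    abort("all gene pairs degenerate (constant profiles)")
  cm <- stats::cor(t(expr[ga, , drop = FALSE]), t(expr[gb, , drop = FALSE]))
  # a gene shared by both sets would correlate with itself; drop those cells
  shared <- intersect(ga, gb)
  for (g in shared) cm[g, g] <- NA
  mean(cm, na.rm = TRUE)
}

#' Rank-bin a proximity/response series
#'
#' Sorts the (x, y) tuples by x (stable: ties keep input order), splits
#' them into \code{bins} consecutive rank blocks of near-equal size (any
#' remainder goes to the earliest bins), and represents each bin by
#' mean(x) and mean(y). Binning suppresses the per-pair noise that hides
#' weak trends in raw scatter.
#'
#' @param x proximity values.
#' @param y response values (co-expression, similarity, ...), same length.
#' @param bins number of bins (default 30); requires \code{length(x) >=
#'   bins}.
#' @return data.frame (class \code{"binned_series"}) with \code{bin},
#'   \code{n}, \code{mean_x}, \code{mean_y}.
#' @export
bin_series <- function(x, y, bins = 30) {
  N <- length(x)
  if (length(y) != N) abort("x and y lengths differ")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    abort("series values must be finite")
  if (N < bins) abort("need at least as many tuples as bins")
  ord <- order(x, seq_len(N))
  base <- N %/% bins
  extra <- N %% bins
  sizes <- rep(base, bins) + c(rep(1L, extra), rep(0L, bins - extra))
  grp <- rep(seq_len(bins), sizes)
  out <- data.frame(
    bin = seq_len(bins),
    n = sizes,
    mean_x = as.numeric(tapply(x[ord], grp, mean)),
    mean_y = as.numeric(tapply(y[ord], grp, mean)))
  class(out) <- c("binned_series", "data.frame")
  out
}

#' Pearson correlation of bin means
#'
#' @inheritParams bin_series
#' @return Pearson r over the \code{bins} (mean_x, mean_y) points;
#'   \code{NA} with a warning when either coordinate is constant.
#' @export
binned_correlation <- function(x, y, bins = 30) {
  b <- bin_series(x, y, bins)
  if (stats::sd(b$mean_x) == 0 || stats::sd(b$mean_y) == 0) {
    warning("constant bin means; correlation undefined")
    return(NA_real_)
  }
  stats::cor(b$mean_x, b$mean_y)
}

#' Permutation significance of a binned correlation
#'
#' The binned correlation overestimates association strength by
#' construction (variance reduction), so its value is not interpreted
#' directly; instead the y values are randomly re-paired with the x values
#' \code{reps} times, the binned correlation is recomputed each time, and
#' the p-value is read off the null cumulative distribution. One-sided
#' (positive association) by default.
#'
#' @inheritParams bin_series
#' @param reps number of permutation replicates (default 1000).
#' @param seed RNG seed.
#' @param alternative \code{"greater"}, \code{"less"} or
#'   \code{"two.sided"}.
#' @param add_one use the (b+1)/(R+1) permutation-p convention instead of
#'   the raw fraction.
#' @return list with \code{p}, \code{r_observed} and the \code{null}
#'   correlation vector.
#' @export
permutation_pvalue <- function(x, y, bins = 30, reps = 1000, seed = 1L,
                               alternative = c("greater", "less",
                                               "two.sided"),
                               add_one = FALSE) {
  alternative <- match.arg(alternative)
  if (reps < 1) abort("reps must be >= 1")
  r_obs <- binned_correlation(x, y, bins)
  if (is.na(r_obs)) abort("degenerate series")
  null <- with_seed(seed, vapply(seq_len(reps), function(r)
    binned_correlation(x, sample(y), bins), numeric(1)))
  null <- null[!is.na(null)]
  hits <- switch(alternative,
                 greater = sum(null >= r_obs),
                 less = sum(null <= r_obs),
                 two.sided = sum(abs(null) >= abs(r_obs)))
  p <- if (add_one) (hits + 1) / (length(null) + 1) else hits / length(null)
  list(p = p, r_observed = r_obs, null = null)
}

#' Proximity / co-expression series over scored segment pairs
#'
#' Builds the (x, y) tuples the binned association test consumes: x is the
#' spatial proximity value of each scored segment pair with genes on both
#' sides, y the combined co-expression of the two gene sets (or the mean
#' of supplied pair scores for similarity input).
#'
#' @param stats a \code{contact_table}.
#' @param assignment gene-to-segment map.
#' @param expr expression matrix (for co-expression response); or
#' @param similarity data.frame (gene_a, gene_b, score) of precomputed
#'   pair scores. Exactly one of \code{expr}/\code{similarity} is used.
#' @return data.frame with \code{x} and \code{y}, one row per usable
#'   segment pair.
#' @export
pair_series <- function(stats, assignment, expr = NULL, similarity = NULL) {
  if (is.null(expr) == is.null(similarity))
    abort("supply exactly one of expr or similarity")
  bysec <- genes_by_segment(assignment)
  sim_key <- if (!is.null(similarity))
    stats::setNames(similarity$score,
                    pair_key(similarity$gene_a, similarity$gene_b))
  xs <- numeric(0)
  ys <- numeric(0)
  for (r in seq_len(nrow(stats))) {
    ga <- bysec[[as.character(stats$i[r])]]
    gb <- bysec[[as.character(stats$j[r])]]
    if (!length(ga) || !length(gb)) next
    y <- if (!is.null(expr)) {
      ga2 <- intersect(ga, rownames(expr))
      gb2 <- intersect(gb, rownames(expr))
      if (!length(ga2) || !length(gb2)) next
      tryCatch(combined_coexpression(expr, ga2, gb2),
               error = function(e) NA_real_)
    } else {
      keys <- pair_key(rep(ga, each = length(gb)), rep(gb, length(ga)))
      mean(sim_key[keys], na.rm = TRUE)
    }
    if (is.na(y)) next
    xs <- c(xs, stats$proximity[r])
    ys <- c(ys, y)
  }
  data.frame(x = xs, y = ys)
}
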