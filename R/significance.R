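#' Binomial tail probability of a contact count
#'
#' Probability of observing at least \code{k} reads for a segment pair out
#' of \code{n} reads total for its chromosome pair, when each read falls on
#' the pair independently with background probability \code{m}:
#' \deqn{P(X \ge k) = \sum_{i=k}^{n} \binom{n}{i} m^i (1-m)^{n-i}.}
#' Computed through the numerically stable binomial survival function.
#'
#' @param k observed counts (vectorized).
#' @param n chromosome-pair read totals.
#' @param m background probabilities in [0, 1].
#' @return tail probabilities in [0, 1].
#' @examples
#' binom_tail(3, 10, 0.1)   # 0.0702
#' binom_tail(5, 5, 0.5)    # 0.5^5
#' @export
binom_tail <- function(k, n, m) {
  if (any(k < 0) || any(n < 0) || any(k > n)) abort("need 0 <= k <= n")
  if (any(m < 0) || any(m > 1)) abort("m must lie in [0, 1]")
  stats::pbinom(k - 1, n, m, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control, order-preserving with the input (the q-values of
#' the contact caller).
#'
#' @param p vector of p-values in [0, 1]; an empty vector returns empty.
#' @return adjusted values, element-wise >= \code{p}, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0) || any(p > 1)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "fdr")
}

# mean of (L_C + L_D) over all unordered chromosome pairs
mean_pair_length <- function(layout) {
  L <- layout$chrom_lengths
  if (length(L) < 2) abort("length normalization needs >= 2 chromosomes")
  pairs <- utils::combn(length(L), 2)
  mean(L[pairs[1, ]] + L[pairs[2, ]])
}

#' Length-normalize a q-value
#'
#' Contact p-values are computed separately per chromosome pair, so pairs of
#' short chromosomes (fewer reads) get systematically smaller q-values. The
#' correction rescales each q by how short its chromosome pair is relative
#' to the average pair:
#' \deqn{q_{norm} = q \cdot \left(\frac{\bar{L}}{L_A + L_B}\right)^\gamma}
#' with \eqn{\bar{L}} the mean of \eqn{L_C + L_D} over all chromosome pairs.
#' \code{gamma = 0} switches the normalization off.
#'
#' @param q q-values.
#' @param len_a,len_b lengths (bp) of the two chromosomes of each pair.
#' @param layout the \code{genome_layout} (defines the pair-length mean).
#' @param gamma normalization exponent (default 1).
#' @return normalized q-values (> 0 whenever q > 0; may exceed 1).
#' @export
length_normalize <- function(q, len_a, len_b, layout, gamma = 1) {
  if (any(len_a <= 0) || any(len_b <= 0)) abort("chromosome lengths must be > 0")
  q * (mean_pair_length(layout) / (len_a + len_b))^gamma
}

#' Spatial proximity value of a scored pair
#'
#' Default is the observed/expected ratio \code{k / (n * m)}; the
#' alternative \code{-log10(q_norm)} is selectable. Both are monotone
#' summaries of contact strength used as the x-axis of the binned
#' association test.
#'
#' @param k,n,m count, total and background probability.
#' @param q_norm normalized q-values (needed for \code{"neglog_q"}).
#' @param method \code{"obs_exp"} or \code{"neglog_q"}.
#' @return non-negative proximity values.
#' @export
proximity_value <- function(k, n, m, q_norm = NULL,
                            method = c("obs_exp", "neglog_q")) {
  method <- match.arg(method)
  if (method == "obs_exp") {
    if (any(m <= 0)) abort("background probability must be > 0")
    k / (n * m)
  } else {
    if (is.null(q_norm)) abort("neglog_q proximity needs q_norm")
    -log10(pmax(q_norm, .Machine$double.xmin))
  }
}

#' Score all inter-chromosomal segment pairs
#'
#' For each chromosome pair (C, D), \code{n} is the total number of
#' inter-chromosomal reads between C and D; every counted segment pair gets
#' a binomial tail p-value against its background probability, BH
#' adjustment is applied genome-wide across all inter-chromosomal pairs,
#' q-values are length-normalized, and a proximity value is attached.
#' Intra-chromosomal entries in the count table are ignored. Pairs with
#' zero counts are implicitly p = 1 and never materialized.
#'
#' @param counts a \code{contact_counts} table.
#' @param bg a \code{background_probs} table covering every counted
#'   inter-chromosomal pair.
#' @param index a \code{segment_index}.
#' @param gamma length-normalization exponent.
#' @param proximity proximity definition, see \code{\link{proximity_value}}.
#' @return a \code{contact_table} data.frame with columns \code{i, j,
#'   chrom_a, start_a, chrom_b, start_b, k, n, m_norm, p, q, q_norm,
#'   proximity}.
#' @export
score_all_pairs <- function(counts, bg, index, gamma = 1,
                            proximity = c("obs_exp", "neglog_q")) {
  proximity <- match.arg(proximity)
  layout <- index_layout(index)
  ca <- index$chrom[counts$i]
  cb <- index$chrom[counts$j]
  inter <- ca != cb
  d <- counts[inter, , drop = FALSE]
  if (nrow(d) == 0) {
    out <- data.frame(i = integer(), j = integer(),
                      chrom_a = character(), start_a = numeric(),
                      chrom_b = character(), start_b = numeric(),
                      k = numeric(), n = numeric(), m_norm = numeric(),
                      p = numeric(), q = numeric(), q_norm = numeric(),
                      proximity = numeric())
    class(out) <- c("contact_table", "data.frame")
    return(out)
  }
  d$chrom_a <- index$chrom[d$i]
  d$chrom_b <- index$chrom[d$j]
  # chromosome-pair totals: n is shared by all segment pairs of (C, D)
  cp_key <- paste(pmin(d$chrom_a, d$chrom_b), pmax(d$chrom_a, d$chrom_b))
  totals <- rowsum(d$count, cp_key)
  d$n <- totals[cp_key, 1]
  m <- bg$m[match(pair_key(d$i, d$j), pair_key(bg$i, bg$j))]
  if (any(is.na(m)))
    abort("%d counted pairs lack a background entry", sum(is.na(m)))
  d$m_norm <- m
  d$p <- binom_tail(d$count, d$n, d$m_norm)
  d$q <- bh_adjust(d$p)
  len <- layout$chrom_lengths
  d$q_norm <- length_normalize(d$q, len[d$chrom_a], len[d$chrom_b],
                               layout, gamma = gamma)
  d$proximity <- proximity_value(d$count, d$n, d$m_norm,
                                 q_norm = d$q_norm, method = proximity)
  out <- data.frame(i = d$i, j = d$j,
                    chrom_a = d$chrom_a, start_a = index$start[d$i],
                    chrom_b = d$chrom_b, start_b = index$start[d$j],
                    k = d$count, n = d$n, m_norm = d$m_norm,
                    p = d$p, q = d$q, q_norm = d$q_norm,
                    proximity = d$proximity, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("contact_table", "data.frame")
  out
}

#' @export
print.contact_table <- function(x, ...) {
  cat(sprintf("contact_table: %d inter-chromosomal segment pairs\n", nrow(x)))
  if (nrow(x)) {
    cat(sprintf("  q_norm range: [%.3g, %.3g]\n", min(x$q_norm), max(x$q_norm)))
    print(utils::head(as.data.frame(x), 6))
    if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  }
  invisible(x)
}

#' Contact significance of two arbitrary regions
#'
#' Aggregates counts and background over all segment pairs spanning two
#' regions on different chromosomes (e.g. whole gene-cluster loci instead
#' of single segments) and applies the same binomial test, with \code{n}
#' the chromosome-pair read total.
#'
#' @param region_a,region_b lists with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), on different chromosomes.
#' @param counts,bg,index as in \code{\link{score_all_pairs}}.
#' @return one-row data.frame with \code{k}, \code{n}, \code{m}, \code{p}.
#' @export
region_significance <- function(region_a, region_b, counts, bg, index) {
  if (region_a$chrom == region_b$chrom)
    abort("regions must lie on different chromosomes")
  segs_of <- function(r) {
    s <- index$id[index$chrom == r$chrom &
                    index$start < r$end & index$end > r$start]
    if (!length(s)) abort("region maps to no segment")
    s
  }
  sa <- segs_of(region_a)
  sb <- segs_of(region_b)
  grid <- expand.grid(i = sa, j = sb)
  gk <- pair_key(grid$i, grid$j)
  k <- sum(counts$count[match(gk, pair_key(counts$i, counts$j))], na.rm = TRUE)
  mm <- bg$m[match(gk, pair_key(bg$i, bg$j))]
  m <- sum(mm, na.rm = TRUE)
  if (m <= 0) abort("no background mass for the region pair")
  # chromosome-pair total, as in score_all_pairs
  ci <- index$chrom[counts$i]
  cj <- index$chrom[counts$j]
  on_pair <- (ci == region_a$chrom & cj == region_b$chrom) |
    (ci == region_b$chrom & cj == region_a$chrom)
  n <- sum(counts$count[on_pair])
  data.frame(k = k, n = n, m = min(m, 1),
             p = binom_tail(k, n, min(m, 1)))
}
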