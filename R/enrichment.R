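#' Split segments into trans-interacting and other
#'
#' Trans-interacting segments are those with at least one edge in the
#' segment network; everything else is "other". Chromosomes in
#' \code{exclude_chroms} (typically the sex chromosomes, to avoid a bias
#' toward inactive marks) are removed from both classes.
#'
#' @param sin segment network from \code{\link{build_sin}}.
#' @param index the \code{segment_index}.
#' @param exclude_chroms chromosome names to drop.
#' @return list with integer id vectors \code{trans} and \code{other}.
#' @export
classify_segments <- function(sin, index, exclude_chroms = character()) {
  k <- igraph::degree(sin)
  ids <- as.integer(igraph::V(sin)$name)
  keep <- !(index$chrom[ids] %in% exclude_chroms)
  list(trans = sort(ids[keep & k >= 1]),
       other = sort(ids[keep & k == 0]))
}

# GRanges for a set of segment ids
segments_granges <- function(segment_ids, index) {
  s <- index[index$id %in% segment_ids, , drop = FALSE]
  GenomicRanges::GRanges(s$chrom,
                         IRanges::IRanges(start = s$start + 1, end = s$end))
}

# GRanges from a (chrom, start, end) data.frame, 0-based half-open input
track_granges <- function(track) {
  GenomicRanges::GRanges(track$chrom,
                         IRanges::IRanges(start = track$start + 1,
                                          end = track$end))
}

#' Percent base-pair overlap of a feature track with a segment set
#'
#' Track intervals are merged before intersection so overlapping intervals
#' are not double-counted; the result is coverage, not interval counts.
#'
#' @param segment_ids integer segment ids.
#' @param track interval data.frame (\code{chrom}, \code{start},
#'   \code{end}).
#' @param index the \code{segment_index}.
#' @return percentage in [0, 100] of the segment bases covered by the
#'   merged track.
#' @export
feature_overlap_percent <- function(segment_ids, track, index) {
  if (!length(segment_ids)) return(0)
  segs <- segments_granges(segment_ids, index)
  total <- sum(as.numeric(GenomicRanges::width(segs)))
  if (is.null(track) || nrow(track) == 0) return(0)
  merged <- GenomicRanges::reduce(track_granges(track))
  hit <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::intersect(merged, segs, ignore.strand = TRUE))))
  100 * hit / total
}

#' Feature enrichment of trans-interacting segments
#'
#' @param classes output of \code{\link{classify_segments}}.
#' @param tracks named list of feature interval data.frames.
#' @param index the \code{segment_index}.
#' @return data.frame with \code{feature}, \code{percent_trans},
#'   \code{percent_other}, \code{ratio}.
#' @export
feature_enrichment <- function(classes, tracks, index) {
  res <- lapply(names(tracks), function(nm) {
    pt <- feature_overlap_percent(classes$trans, tracks[[nm]], index)
    po <- feature_overlap_percent(classes$other, tracks[[nm]], index)
    data.frame(feature = nm, percent_trans = pt, percent_other = po,
               ratio = if (po > 0) pt / po else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Mean transcription-factor binding-site counts per segment class
#'
#' A site is one track interval; a segment's count is the number of
#' intervals overlapping it. Means are per segment within each class.
#'
#' @param classes output of \code{\link{classify_segments}}.
#' @param tfbs_tracks named list (one per factor) of site interval
#'   data.frames.
#' @param index the \code{segment_index}.
#' @return data.frame with \code{factor}, \code{mean_trans},
#'   \code{mean_other}.
#' @export
tfbs_mean_counts <- function(classes, tfbs_tracks, index) {
  gr_t <- segments_granges(classes$trans, index)
  gr_o <- segments_granges(classes$other, index)
  res <- lapply(names(tfbs_tracks), function(nm) {
    tr <- tfbs_tracks[[nm]]
    if (is.null(tr) || nrow(tr) == 0) {
      mt <- 0; mo <- 0
    } else {
      sites <- track_granges(tr)
      mt <- if (length(gr_t))
        mean(GenomicRanges::countOverlaps(gr_t, sites)) else 0
      mo <- if (length(gr_o))
        mean(GenomicRanges::countOverlaps(gr_o, sites)) else 0
    }
    data.frame(factor = nm, mean_trans = mt, mean_other = mo,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-factor binding percentage within spatial clusters
#'
#' For each transcription factor, the fraction of genes in each spatial
#' cluster with at least one site overlapping the gene body, averaged over
#' clusters.
#'
#' @param clusters list from \code{\link{spatial_clusters}}.
#' @param genes gene table (for gene coordinates).
#' @param tfbs_tracks named list of site interval data.frames.
#' @return data.frame with \code{factor} and \code{mean_percent_bound};
#'   zero rows when there are no clusters.
#' @export
cluster_binding_percent <- function(clusters, genes, tfbs_tracks) {
  if (!length(clusters))
    return(data.frame(factor = character(), mean_percent_bound = numeric()))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(start = genes$start + 1, end = genes$end))
  names(gene_gr) <- genes$gene_id
  res <- lapply(names(tfbs_tracks), function(nm) {
    tr <- tfbs_tracks[[nm]]
    bound <- if (is.null(tr) || nrow(tr) == 0) character(0)
    else names(gene_gr)[GenomicRanges::countOverlaps(gene_gr,
                                                     track_granges(tr)) > 0]
    pct <- vapply(clusters, function(cl)
      100 * mean(cl$genes %in% bound), numeric(1))
    data.frame(factor = nm, mean_percent_bound = mean(pct),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
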