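#' Genome layout: chromosomes tiled by fixed-size segments
#'
#' A genome layout records chromosome names, their lengths in base pairs and
#' the segment (bin) size used to tile them. All coordinates in the package
#' are 0-based half-open; the last segment of a chromosome may be shorter
#' than \code{bin_size}.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param bin_size segment size in bp (default 500 kb, the resolution at
#'   which inter-chromosomal read coverage supports contact calling).
#' @return an object of class \code{"genome_layout"}.
#' @examples
#' genome_layout(c(chr1 = 1.5e6, chr2 = 1e6), bin_size = 5e5)
#' @export
genome_layout <- function(chrom_lengths, bin_size = 5e5) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    abort("chrom_lengths must be a named vector")
  if (anyDuplicated(names(chrom_lengths)))
    abort("duplicate chromosome name")
  if (!is.numeric(chrom_lengths) || any(!is.finite(chrom_lengths)) ||
      any(chrom_lengths <= 0) || any(chrom_lengths != round(chrom_lengths)))
    abort("chromosome lengths must be positive integers")
  if (!is_scalar_num(bin_size) || bin_size <= 0)
    abort("bin_size must be a positive number")
  structure(
    list(chrom_names = names(chrom_lengths),
         chrom_lengths = stats::setNames(as.numeric(chrom_lengths),
                                         names(chrom_lengths)),
         bin_size = as.numeric(bin_size)),
    class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosomes, bin size %s bp, %d segments\n",
              length(x$chrom_names), format(x$bin_size, big.mark = ","),
              sum(n_segments(x))))
  invisible(x)
}

#' Number of segments per chromosome
#'
#' @param layout a \code{genome_layout}.
#' @return named integer vector, \code{ceiling(length / bin_size)} per
#'   chromosome.
#' @export
n_segments <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  stats::setNames(as.integer(ceiling(layout$chrom_lengths / layout$bin_size)),
                  layout$chrom_names)
}

#' Read a chromosome-sizes table
#'
#' Two-column tab-separated file (chromosome name, length in bp), no header.
#'
#' @param path file path.
#' @param bin_size segment size passed to \code{\link{genome_layout}}.
#' @return a \code{genome_layout}.
#' @export
read_chrom_sizes <- function(path, bin_size = 5e5) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         colClasses = c("character", "character"),
                         quote = "", comment.char = "")
  len <- suppressWarnings(as.numeric(d$length))
  if (any(is.na(len)) || any(len != round(len)))
    abort("non-integer chromosome length in %s", path)
  genome_layout(stats::setNames(len, d$chrom), bin_size = bin_size)
}

#' Build the segment index for a genome layout
#'
#' Assigns dense integer ids (1..N, chromosome-major) to the fixed-size
#' segments tiling every chromosome.
#'
#' @param layout a \code{genome_layout}.
#' @return a data.frame (class \code{"segment_index"}) with columns
#'   \code{id}, \code{chrom}, \code{start}, \code{end}; 0-based half-open,
#'   gap- and overlap-free within each chromosome.
#' @export
segment_index <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  ns <- n_segments(layout)
  chrom <- rep(layout$chrom_names, ns)
  start <- unlist(lapply(ns, function(k) (seq_len(k) - 1) * layout$bin_size),
                  use.names = FALSE)
  end <- pmin(start + layout$bin_size,
              rep(layout$chrom_lengths, ns))
  idx <- data.frame(id = seq_along(chrom), chrom = chrom,
                    start = start, end = end, stringsAsFactors = FALSE)
  attr(idx, "layout") <- layout
  # first id of each chromosome, for O(1) position -> id lookup
  attr(idx, "offsets") <- stats::setNames(
    cumsum(c(0L, ns[-length(ns)])), layout$chrom_names)
  class(idx) <- c("segment_index", "data.frame")
  idx
}

# layout stored on a segment_index
index_layout <- function(index) {
  l <- attr(index, "layout")
  if (is.null(l)) abort("segment index carries no layout")
  l
}

#' Map genomic positions to segment ids
#'
#' @param index a \code{segment_index}.
#' @param chrom chromosome names.
#' @param pos 0-based positions.
#' @return integer segment ids.
#' @export
segment_at <- function(index, chrom, pos) {
  layout <- index_layout(index)
  off <- attr(index, "offsets")
  unknown <- setdiff(unique(chrom), layout$chrom_names)
  if (length(unknown))
    abort("unknown chromosome: %s", paste(unknown, collapse = ", "))
  if (any(pos < 0) || any(pos >= layout$chrom_lengths[chrom]))
    abort("position outside chromosome bounds")
  as.integer(off[chrom] + floor(pos / layout$bin_size) + 1)
}
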