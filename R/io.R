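#' Read a binned contact-count table
#'
#' Tab-separated rows \code{(chromA, startA, chromB, startB, count)} with
#' 0-based segment start coordinates aligned to the bin grid. Rows naming
#' the same unordered segment pair are summed, so triangular and full dumps
#' load identically. Intra-chromosomal rows are retained (downstream
#' operations filter them).
#'
#' @param path file path.
#' @param index a \code{\link{segment_index}}.
#' @return data.frame (class \code{"contact_counts"}) with columns
#'   \code{i}, \code{j} (segment ids, \code{i <= j}) and \code{count}.
#' @export
read_contacts <- function(path, index) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom_a", "start_a",
                                       "chrom_b", "start_b", "count"),
                         colClasses = c("character", "numeric",
                                        "character", "numeric", "numeric"),
                         quote = "", comment.char = "")
  layout <- index_layout(index)
  bs <- layout$bin_size
  if (any(d$start_a %% bs != 0) || any(d$start_b %% bs != 0))
    abort("contact coordinates not aligned to the %g bp bin grid", bs)
  if (any(d$count < 0) || any(d$count != round(d$count)))
    abort("contact counts must be non-negative integers")
  i <- segment_at(index, d$chrom_a, d$start_a)
  j <- segment_at(index, d$chrom_b, d$start_b)
  contact_counts(i, j, d$count)
}

#' Construct a sparse symmetric count table from id pairs
#'
#' @param i,j segment ids of each pair (order irrelevant).
#' @param count non-negative read counts; duplicates of the same unordered
#'   pair are summed.
#' @return a \code{contact_counts} data.frame.
#' @export
contact_counts <- function(i, j, count) {
  o <- order_pairs(as.integer(i), as.integer(j))
  key <- paste(o$i, o$j)
  agg <- rowsum(as.numeric(count), key)
  ij <- do.call(rbind, strsplit(rownames(agg), " ", fixed = TRUE))
  out <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                    count = as.numeric(agg[, 1]))
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("contact_counts", "data.frame")
  out
}

#' Read a binned background-probability table
#'
#' Same shape as the contact table, with the fifth column holding the
#' expected interaction probability of the segment pair under the bias
#' model (values in (0, 1]). Duplicate rows for a pair must agree.
#'
#' @inheritParams read_contacts
#' @return data.frame with columns \code{i}, \code{j}, \code{m} (class
#'   \code{"background_probs"}).
#' @export
read_background <- function(path, index) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom_a", "start_a",
                                       "chrom_b", "start_b", "m"),
                         colClasses = c("character", "numeric",
                                        "character", "numeric", "numeric"),
                         quote = "", comment.char = "")
  layout <- index_layout(index)
  bs <- layout$bin_size
  if (any(d$start_a %% bs != 0) || any(d$start_b %% bs != 0))
    abort("background coordinates not aligned to the %g bp bin grid", bs)
  background_probs(segment_at(index, d$chrom_a, d$start_a),
                   segment_at(index, d$chrom_b, d$start_b), d$m)
}

#' @rdname read_background
#' @param i,j segment ids; \code{m} probabilities in (0, 1].
#' @export
background_probs <- function(i, j, m) {
  if (any(!is.finite(m)) || any(m <= 0) || any(m > 1))
    abort("background probabilities must lie in (0, 1]")
  o <- order_pairs(as.integer(i), as.integer(j))
  key <- paste(o$i, o$j)
  spread <- tapply(as.numeric(m), key, function(v) diff(range(v)))
  if (any(spread > 1e-12))
    abort("conflicting duplicate background entries")
  out <- data.frame(i = o$i, j = o$j, m = as.numeric(m))
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("background_probs", "data.frame")
  out
}

#' Read BED intervals
#'
#' BED3/BED4/BED6; 0-based half-open, as BED is natively.
#'
#' @param path file path.
#' @return data.frame with \code{chrom}, \code{start}, \code{end} and,
#'   when present, \code{name} and \code{strand}.
#' @export
read_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                         comment.char = "", stringsAsFactors = FALSE)
  if (ncol(d) < 3) abort("BED needs at least 3 columns")
  out <- data.frame(chrom = as.character(d[[1]]),
                    start = as.numeric(d[[2]]),
                    end = as.numeric(d[[3]]),
                    stringsAsFactors = FALSE)
  if (ncol(d) >= 4) out$name <- as.character(d[[4]])
  if (ncol(d) >= 6) out$strand <- as.character(d[[6]])
  if (any(out$start < 0) || any(out$end <= out$start))
    abort("invalid BED interval (need 0 <= start < end)")
  out
}

#' Read gene annotations
#'
#' Accepts BED4/BED6 (gene id in column 4) or a minimal GTF whose
#' \code{gene} features carry a \code{gene_id} attribute. GTF 1-based
#' closed coordinates are converted to the package's 0-based half-open
#' convention at this boundary. Strand is read but never used downstream.
#'
#' @param path file path.
#' @param format \code{"bed"} or \code{"gtf"}.
#' @return data.frame with \code{gene_id}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand}; gene ids unique.
#' @export
read_genes <- function(path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  if (format == "bed") {
    d <- read_bed(path)
    if (is.null(d$name)) abort("gene BED needs a name column")
    out <- data.frame(gene_id = d$name, chrom = d$chrom,
                      start = d$start, end = d$end,
                      strand = if (is.null(d$strand)) "." else d$strand,
                      stringsAsFactors = FALSE)
  } else {
    d <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
    d <- d[d[[3]] == "gene", , drop = FALSE]
    ids <- sub('.*gene_id[ ="]+([^";]+).*', "\\1", d[[9]])
    out <- data.frame(gene_id = ids, chrom = as.character(d[[1]]),
                      start = as.numeric(d[[4]]) - 1, end = as.numeric(d[[5]]),
                      strand = as.character(d[[7]]), stringsAsFactors = FALSE)
  }
  if (anyDuplicated(out$gene_id)) abort("duplicate gene ids")
  if (any(out$start >= out$end)) abort("gene with start >= end")
  out
}

#' Read an expression matrix
#'
#' Genes-by-samples TSV with a header row of sample ids and gene ids in the
#' first column.
#'
#' @param path file path.
#' @return numeric matrix, rownames = gene ids.
#' @export
read_expression <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                         quote = "", comment.char = "", check.names = FALSE)
  m <- as.matrix(d)
  if (!is.numeric(m)) abort("non-numeric expression values")
  m
}

#' Write / read a network edge list
#'
#' Tab-separated with header \code{id_a, id_b, q_norm}; the confidence
#' column is \code{NA} for networks without per-edge scores. Reading
#' requires the node universe so isolated nodes survive the round trip.
#'
#' @param net an \code{igraph} network.
#' @param path file path.
#' @export
write_edge_list <- function(net, path) {
  e <- igraph::as_edgelist(net)
  q <- igraph::edge_attr(net, "q_norm")
  d <- data.frame(id_a = e[, 1], id_b = e[, 2],
                  q_norm = if (is.null(q)) rep(NA_real_, nrow(e)) else q)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param nodes character vector of all node names (the universe, including
#'   isolated nodes); defaults to the edge endpoints only.
#' @param chroms optional named vector giving each node's chromosome.
#' @return \code{read_edge_list}: an \code{igraph} network.
#' @export
read_edge_list <- function(path, nodes = NULL, chroms = NULL) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "character", "numeric"),
                         quote = "", comment.char = "")
  if (is.null(nodes)) nodes <- unique(c(d$id_a, d$id_b))
  g <- igraph::graph_from_data_frame(d, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  if (!is.null(chroms))
    g <- igraph::set_vertex_attr(g, "chrom",
                                 value = unname(chroms[igraph::V(g)$name]))
  g
}

#' Write a summary object as JSON
#'
#' @param x a list-like summary (e.g. a \code{network_summary}).
#' @param path output path.
#' @export
write_summary <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a gene-pair similarity table
#'
#' TSV columns \code{(gene_a, gene_b, score)}, scores in [0, 1] (e.g.
#' semantic-similarity summaries computed elsewhere).
#'
#' @param path file path.
#' @return data.frame with those three columns.
#' @export
read_similarity <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("gene_a", "gene_b", "score"),
                         colClasses = c("character", "character", "numeric"),
                         quote = "", comment.char = "")
  if (any(d$score < 0) || any(d$score > 1))
    abort("similarity scores must lie in [0, 1]")
  d
}

#' Read a synteny / ortholog table
#'
#' TSV columns \code{(region_id, chrom_a, start_a, end_a, chrom_b, start_b,
#' end_b, gene_a, gene_b)}: one row per ortholog pair, annotated with its
#' conserved-gene-order region in each species.
#'
#' @param path file path.
#' @return data.frame with those columns (class \code{"synteny_map"}).
#' @export
read_synteny <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         quote = "", comment.char = "",
                         stringsAsFactors = FALSE)
  need <- c("region_id", "chrom_a", "start_a", "end_a",
            "chrom_b", "start_b", "end_b", "gene_a", "gene_b")
  if (!all(need %in% names(d))) abort("synteny table missing columns")
  synteny_map(d[need])
}

#' @rdname read_synteny
#' @param d data.frame with the synteny columns.
#' @export
synteny_map <- function(d) {
  # ortholog mapping must be 1:1 within a region
  for (r in split(d, d$region_id)) {
    if (anyDuplicated(r$gene_a) || anyDuplicated(r$gene_b))
      abort("ortholog mapping not 1:1 in region %s", r$region_id[1])
  }
  class(d) <- c("synteny_map", "data.frame")
  d
}

#' @rdname read_synteny
#' @param path output path.
#' @export
write_synteny <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
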