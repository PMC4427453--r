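#' Build the segment interaction network (SIN)
#'
#' Thresholds a scored contact table into an undirected graph: segments are
#' nodes (the full segment universe, so isolated segments are retained) and
#' an edge connects two segments iff they lie on different chromosomes and
#' their normalized q-value is at or below \code{tau}. Monotone in
#' \code{tau}: a stricter cutoff yields a subgraph.
#'
#' @param stats a \code{contact_table} from \code{\link{score_all_pairs}}.
#' @param tau confidence cutoff on \code{q_norm} (> 0).
#' @param index the \code{segment_index} defining the node universe.
#' @return an \code{igraph} graph; vertex names are segment ids, vertex
#'   attribute \code{chrom} the chromosome, edge attribute \code{q_norm}.
#' @export
build_sin <- function(stats, tau, index) {
  if (!is_scalar_num(tau) || tau <= 0) abort("tau must be > 0")
  keep <- stats$q_norm <= tau & stats$chrom_a != stats$chrom_b
  e <- stats[keep, c("i", "j", "q_norm"), drop = FALSE]
  verts <- data.frame(name = as.character(index$id), chrom = index$chrom,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    data.frame(from = as.character(e$i), to = as.character(e$j),
               q_norm = e$q_norm),
    directed = FALSE, vertices = verts)
}

#' Assign genes to segments by maximal overlap
#'
#' Each gene is assigned to the segment holding the largest share of its
#' body; exact ties go to the lower-coordinate segment.
#'
#' @param genes a gene table (\code{gene_id, chrom, start, end}).
#' @param index a \code{segment_index}.
#' @return named integer vector: gene id -> segment id.
#' @export
assign_genes <- function(genes, index) {
  layout <- index_layout(index)
  bad <- !(genes$chrom %in% layout$chrom_names)
  if (any(bad)) abort("gene on unknown chromosome: %s", genes$chrom[bad][1])
  if (any(genes$start < 0) ||
      any(genes$end > layout$chrom_lengths[genes$chrom]))
    abort("gene outside chromosome bounds")
  bs <- layout$bin_size
  off <- attr(index, "offsets")
  out <- integer(nrow(genes))
  for (g in seq_len(nrow(genes))) {
    first <- floor(genes$start[g] / bs)
    last <- floor((genes$end[g] - 1) / bs)
    bins <- first:last
    ov <- pmin(genes$end[g], (bins + 1) * bs) - pmax(genes$start[g], bins * bs)
    out[g] <- off[genes$chrom[g]] + bins[which.max(ov)] + 1L
  }
  stats::setNames(as.integer(out), genes$gene_id)
}

# genes grouped by segment id (names of the split are segment ids)
genes_by_segment <- function(assignment) {
  split(names(assignment), assignment)
}

#' Expand the SIN into the gene interaction network (GIN)
#'
#' For every SIN edge (A, B), all genes assigned to A are connected to all
#' genes assigned to B (complete bipartite expansion). Edges whose segment
#' has no genes contribute nothing; gene pairs connected through more than
#' one segment-pair edge collapse into a single edge (simple graph). All
#' genes appear as nodes, so singleton fractions are well defined.
#'
#' @param sin the segment network from \code{\link{build_sin}}.
#' @param assignment gene-to-segment map from \code{\link{assign_genes}}.
#' @return an \code{igraph} graph over genes with vertex attribute
#'   \code{chrom} inherited from the host segment.
#' @export
build_gin <- function(sin, assignment) {
  bysec <- genes_by_segment(assignment)
  el <- igraph::as_edgelist(sin)
  pieces <- vector("list", nrow(el))
  for (r in seq_len(nrow(el))) {
    ga <- bysec[[el[r, 1]]]
    gb <- bysec[[el[r, 2]]]
    if (length(ga) && length(gb))
      pieces[[r]] <- cbind(rep(ga, each = length(gb)), rep(gb, length(ga)))
  }
  edges <- do.call(rbind, pieces)
  seg_chrom <- stats::setNames(igraph::V(sin)$chrom, igraph::V(sin)$name)
  verts <- data.frame(name = names(assignment),
                      chrom = unname(seg_chrom[as.character(assignment)]),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    if (is.null(edges)) data.frame(from = character(), to = character())
    else data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE, vertices = verts)
  igraph::simplify(g)
}

#' Spatial gene clusters
#'
#' One cluster per SIN edge whose two segments both carry at least one
#' gene: the union of the genes of the two contacting segments, a
#' candidate transcription-factory-like assembly.
#'
#' @inheritParams build_gin
#' @return list of clusters, each \code{list(seg_a, seg_b, genes)}.
#' @export
spatial_clusters <- function(sin, assignment) {
  bysec <- genes_by_segment(assignment)
  el <- igraph::as_edgelist(sin)
  out <- list()
  for (r in seq_len(nrow(el))) {
    ga <- bysec[[el[r, 1]]]
    gb <- bysec[[el[r, 2]]]
    if (length(ga) && length(gb))
      out[[length(out) + 1L]] <- list(seg_a = as.integer(el[r, 1]),
                                      seg_b = as.integer(el[r, 2]),
                                      genes = c(ga, gb))
  }
  out
}
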