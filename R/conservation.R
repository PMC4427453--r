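#' Cross-species conservation of gene contact networks
#'
#' For each region of conserved gene order, two gene sets are compared in
#' species-B coordinates: \code{H_M}, the contact partners of the region's
#' species-A genes transferred through the ortholog map, and \code{M}, the
#' measured contact partners of the region's species-B genes. Their
#' overlap, normalized by the smaller set, scores how well the region's
#' trans-contacts are conserved.
#'
#' @name conservation
NULL

# per-region gene id vectors, species A and B, from a synteny map
region_genes <- function(synteny) {
  list(a = split(synteny$gene_a, synteny$region_id),
       b = split(synteny$gene_b, synteny$region_id))
}

# neighbors in a gene network of any of the given genes, as a character set
partner_set <- function(gin, genes) {
  genes <- intersect(genes, igraph::V(gin)$name)
  if (!length(genes)) return(character(0))
  unique(unlist(lapply(
    igraph::adjacent_vertices(gin, genes),
    function(v) igraph::V(gin)$name[as.integer(v)]), use.names = FALSE))
}

#' Transfer species-A contacts into species-B gene space
#'
#' Collects the network partners of every species-A gene in the region and
#' maps them through the genome-wide ortholog table; partners without an
#' ortholog are dropped.
#'
#' @param gin_a species-A gene network.
#' @param genes_a_region species-A gene ids of one synteny region.
#' @param ortholog_map named character vector, species-A gene ->
#'   species-B gene.
#' @return character vector \code{H_M} of species-B gene ids.
#' @export
transfer_contacts <- function(gin_a, genes_a_region, ortholog_map) {
  partners <- partner_set(gin_a, genes_a_region)
  mapped <- ortholog_map[partners]
  unique(mapped[!is.na(mapped)])
}

#' Overlap score of two partner sets
#'
#' \code{|M intersect H_M| / min(|M|, |H_M|)}; 0 when either set is empty.
#'
#' @param m,h_m character vectors (species-B gene ids).
#' @return score in [0, 1].
#' @export
region_overlap <- function(m, h_m) {
  if (!length(m) || !length(h_m)) return(0)
  length(intersect(m, h_m)) / min(length(m), length(h_m))
}

#' Per-region conservation scores
#'
#' Regions with no gene on either side are excluded. A region "has
#' overlap" when the transferred and measured partner sets share at least
#' one gene.
#'
#' @param gin_a,gin_b gene networks of the two species.
#' @param synteny a \code{synteny_map}.
#' @return data.frame with \code{region_id}, \code{n_m}, \code{n_hm},
#'   \code{n_intersect}, \code{score}; attribute \code{n_overlapping}
#'   holds the count of regions with non-empty overlap.
#' @export
conservation_scores <- function(gin_a, gin_b, synteny) {
  rg <- region_genes(synteny)
  omap <- stats::setNames(synteny$gene_b, synteny$gene_a)
  ids <- names(rg$a)
  rows <- lapply(ids, function(rid) {
    ga <- rg$a[[rid]]
    gb <- rg$b[[rid]]
    if (!length(ga) || !length(gb)) return(NULL)
    hm <- transfer_contacts(gin_a, ga, omap)
    m <- partner_set(gin_b, gb)
    data.frame(region_id = rid, n_m = length(m), n_hm = length(hm),
               n_intersect = length(intersect(m, hm)),
               score = region_overlap(m, hm), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(region_id = character(), n_m = integer(),
                      n_hm = integer(), n_intersect = integer(),
                      score = numeric())
  attr(out, "n_overlapping") <- sum(out$n_intersect > 0)
  out
}

#' Region-shuffling null for conservation counts
#'
#' Permutes which species-B region is paired with which species-A region
#' and recounts regions with non-empty overlap; the observed count is
#' compared against this null (one-sided, more overlaps than expected).
#'
#' @param gin_a,gin_b gene networks of the two species.
#' @param synteny a \code{synteny_map}.
#' @param reps number of shuffles.
#' @param seed RNG seed.
#' @return list with \code{observed}, \code{null_counts},
#'   \code{null_mean}, \code{p} ((b+1)/(R+1) convention).
#' @export
shuffle_null <- function(gin_a, gin_b, synteny, reps = 1000, seed = 1L) {
  rg <- region_genes(synteny)
  omap <- stats::setNames(synteny$gene_b, synteny$gene_a)
  ids <- names(rg$a)
  keep <- vapply(ids, function(rid)
    length(rg$a[[rid]]) > 0 && length(rg$b[[rid]]) > 0, logical(1))
  ids <- ids[keep]
  hm <- lapply(ids, function(rid) transfer_contacts(gin_a, rg$a[[rid]], omap))
  m <- lapply(ids, function(rid) partner_set(gin_b, rg$b[[rid]]))
  n <- length(ids)
  count_overlaps <- function(perm)
    sum(vapply(seq_len(n), function(i)
      length(intersect(hm[[i]], m[[perm[i]]])) > 0, logical(1)))
  observed <- count_overlaps(seq_len(n))
  null_counts <- with_seed(seed, vapply(seq_len(reps), function(r)
    count_overlaps(sample.int(n)), numeric(1)))
  list(observed = observed,
       null_counts = null_counts,
       null_mean = mean(null_counts),
       p = (sum(null_counts >= observed) + 1) / (reps + 1))
}
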