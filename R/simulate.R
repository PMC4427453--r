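#' Specification of a synthetic trans-contact architecture
#'
#' Describes a small genome and the structure planted into its simulated
#' inter-chromosomal contacts: per-segment multiplicative biases (the
#' stand-in for GC content, mappability and fragment-length effects that a
#' fragment-level bias model would capture), a set of enriched segment
#' pairs, hub segments with many enriched partners, feature enrichment of
#' contacting segments, co-expression tied to planted proximity, and a
#' conserved fraction of contacts shared with a second synthetic species.
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: a 4-chromosome 53 Mb genome at 500 kb resolution (106 segments),
#' 20,000 reads per chromosome pair, lognormal biases (sigma 0.3), 20
#' planted pairs at 50-fold enrichment plus one 15-partner hub, and 43
#' expression samples.
#'
#' @param chrom_lengths named chromosome lengths (bp).
#' @param bin_size segment size (bp).
#' @param n_reads_per_chrom_pair reads simulated for every chromosome pair.
#' @param bias_sigma sdlog of the lognormal per-segment bias factors.
#' @param n_planted_contacts number of randomly placed enriched pairs.
#' @param planted_f enrichment factor (> 1) of planted pairs.
#' @param hub_partners partners of the planted hub segment (0 = no hub).
#' @param hub_f enrichment factor of hub edges.
#' @param feature_logodds log-odds shift of feature coverage in segments
#'   incident to planted contacts (0 = null).
#' @param coexpr_a latent-factor loading tying co-expression to planted
#'   contacts; 0 = null.
#' @param coexpr_sigma noise sd of the similarity scores.
#' @param n_samples expression samples.
#' @param genes_per_segment_mean Poisson mean of genes per segment.
#' @param conserved_fraction fraction of planted contacts replicated in
#'   the second species, in [0, 1].
#' @return a list of class \code{"architecture_spec"}.
#' @export
architecture_spec <- function(chrom_lengths = c(chr1 = 20e6, chr2 = 15e6,
                                                chr3 = 10e6, chr4 = 8e6),
                              bin_size = 5e5,
                              n_reads_per_chrom_pair = 20000,
                              bias_sigma = 0.3,
                              n_planted_contacts = 20,
                              planted_f = 50,
                              hub_partners = 15,
                              hub_f = 50,
                              feature_logodds = 3,
                              coexpr_a = 0.8,
                              coexpr_sigma = 0.1,
                              n_samples = 43,
                              genes_per_segment_mean = 5.5,
                              conserved_fraction = 0.5) {
  if (planted_f <= 1 || hub_f <= 1) abort("enrichment factors must be > 1")
  if (conserved_fraction < 0 || conserved_fraction > 1)
    abort("conserved_fraction must lie in [0, 1]")
  spec <- list(layout = genome_layout(chrom_lengths, bin_size),
               n_reads_per_chrom_pair = n_reads_per_chrom_pair,
               bias_sigma = bias_sigma,
               n_planted_contacts = n_planted_contacts,
               planted_f = planted_f,
               hub_partners = hub_partners,
               hub_f = hub_f,
               feature_logodds = feature_logodds,
               coexpr_a = coexpr_a,
               coexpr_sigma = coexpr_sigma,
               n_samples = n_samples,
               genes_per_segment_mean = genes_per_segment_mean,
               conserved_fraction = conserved_fraction)
  class(spec) <- "architecture_spec"
  spec
}

# draw the planted pair set (random inter-chromosomal pairs + hub edges)
draw_planted <- function(spec, index) {
  chrom <- index$chrom
  n_seg <- nrow(index)
  pairs <- data.frame(i = integer(), j = integer(), f = numeric(),
                      hub = logical())
  taken <- character(0)
  npc <- spec$n_planted_contacts
  while (npc > 0 && nrow(pairs) < npc) {
    a <- sample.int(n_seg, 1)
    b <- sample.int(n_seg, 1)
    if (chrom[a] == chrom[b]) next
    key <- pair_key(a, b)
    if (key %in% taken) next
    taken <- c(taken, key)
    pairs <- rbind(pairs, data.frame(i = min(a, b), j = max(a, b),
                                     f = spec$planted_f, hub = FALSE))
  }
  hub_id <- NA_integer_
  if (spec$hub_partners > 0) {
    hub_id <- sample.int(n_seg, 1)
    cand <- which(chrom != chrom[hub_id])
    partners <- sample(cand, min(spec$hub_partners, length(cand)))
    for (p in partners) {
      key <- pair_key(hub_id, p)
      if (key %in% taken) next
      taken <- c(taken, key)
      pairs <- rbind(pairs, data.frame(i = min(hub_id, p), j = max(hub_id, p),
                                       f = spec$hub_f, hub = TRUE))
    }
  }
  list(pairs = pairs, hub = hub_id)
}

#' Simulate binned inter-chromosomal contacts
#'
#' For every chromosome pair, baseline pair probabilities are proportional
#' to the product of the two segments' bias factors, normalized to sum to
#' one within the pair; planted pairs are multiplied by their enrichment
#' factor before renormalization, and read counts are drawn multinomially
#' (so the chromosome-pair total is exact). The emitted background stores
#' the \emph{un-enriched} probabilities, making the generator the oracle
#' for true significance: planted pairs are enriched relative to the
#' background the caller sees.
#'
#' @param spec an \code{\link{architecture_spec}}.
#' @param seed RNG seed; all outputs are deterministic in (spec, seed).
#' @return list with \code{counts} (\code{contact_counts}),
#'   \code{background} (\code{background_probs}), \code{index},
#'   \code{truth} (planted pair table with enrichment factors, hub id,
#'   per-segment biases).
#' @export
simulate_contacts <- function(spec, seed = 1L) {
  index <- segment_index(spec$layout)
  n_seg <- nrow(index)
  with_seed(seed, {
    biases <- stats::rlnorm(n_seg, meanlog = 0, sdlog = spec$bias_sigma)
    planted <- draw_planted(spec, index)
    fmap <- stats::setNames(planted$pairs$f,
                            pair_key(planted$pairs$i, planted$pairs$j))
    chroms <- spec$layout$chrom_names
    ci <- cj <- cnt <- bi <- bj <- bm <- list()
    piece <- 0
    for (a in seq_along(chroms)) for (b in seq_along(chroms)) {
      if (a >= b) next
      sa <- index$id[index$chrom == chroms[a]]
      sb <- index$id[index$chrom == chroms[b]]
      grid_i <- rep(sa, each = length(sb))
      grid_j <- rep(sb, length(sa))
      m0 <- biases[grid_i] * biases[grid_j]
      m0 <- m0 / sum(m0)
      f <- fmap[pair_key(grid_i, grid_j)]
      f[is.na(f)] <- 1
      if (any(f * m0 >= 1))
        abort("infeasible spec: enriched pair probability >= 1")
      m1 <- m0 * f
      m1 <- m1 / sum(m1)
      counts <- as.numeric(stats::rmultinom(1, spec$n_reads_per_chrom_pair,
                                            m1))
      piece <- piece + 1
      keep <- counts > 0 | f > 1
      ci[[piece]] <- grid_i[keep]
      cj[[piece]] <- grid_j[keep]
      cnt[[piece]] <- counts[keep]
      bi[[piece]] <- grid_i[keep]
      bj[[piece]] <- grid_j[keep]
      bm[[piece]] <- m0[keep]
    }
    counts <- contact_counts(unlist(ci), unlist(cj), unlist(cnt))
    counts <- counts[counts$count > 0, , drop = FALSE]
    class(counts) <- c("contact_counts", "data.frame")
    bg <- background_probs(unlist(bi), unlist(bj), unlist(bm))
    list(counts = counts, background = bg, index = index,
         truth = list(planted = planted$pairs, hub = planted$hub,
                      biases = biases))
  })
}

#' Simulate gene annotations
#'
#' Poisson number of genes per segment (uniform placement within disjoint
#' slots, so genes never overlap or cross a chromosome end).
#'
#' @param layout a \code{genome_layout}.
#' @param genes_per_segment_mean Poisson mean.
#' @param seed RNG seed.
#' @return gene table data.frame (\code{gene_id, chrom, start, end,
#'   strand}).
#' @export
simulate_genes <- function(layout, genes_per_segment_mean = 5.5, seed = 1L) {
  index <- segment_index(layout)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(index)), function(s) {
      g <- stats::rpois(1, genes_per_segment_mean)
      if (g == 0) return(NULL)
      width <- index$end[s] - index$start[s]
      slot <- width / g
      # one gene per slot keeps genes disjoint and inside the segment
      glen <- pmin(pmax(200, floor(stats::runif(g, 0.1, 0.6) * slot)),
                   floor(slot * 0.9))
      gstart <- index$start[s] + (seq_len(g) - 1) * slot +
        floor(stats::runif(g) * pmax(0, slot - glen))
      data.frame(gene_id = sprintf("g_%s_%d_%d", index$chrom[s], s,
                                   seq_len(g)),
                 chrom = index$chrom[s],
                 start = floor(gstart), end = floor(gstart) + glen,
                 strand = sample(c("+", "-"), g, replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(gene_id = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        strand = character())
    rownames(out) <- NULL
    out
  })
}

#' Simulate a feature track enriched in contacting segments
#'
#' Each segment gets one covering interval whose coverage fraction is
#' drawn on the logit scale: baseline log-odds plus \code{logodds} for
#' segments incident to a planted contact, plus Gaussian noise. With
#' \code{logodds = 0} the two segment classes are exchangeable.
#'
#' @param index a \code{segment_index}.
#' @param truth the \code{truth} element of
#'   \code{\link{simulate_contacts}} (or NULL for no planted structure).
#' @param logodds class separation on the logit scale.
#' @param seed RNG seed.
#' @param base_logodds baseline coverage log-odds (default -2, about 12
#'   percent coverage).
#' @param noise_sd per-segment logit noise.
#' @return feature track data.frame (\code{chrom, start, end, name}).
#' @export
simulate_features <- function(index, truth = NULL, logodds = 3, seed = 1L,
                              base_logodds = -2, noise_sd = 0.5) {
  trans <- if (is.null(truth) || !nrow(truth$planted)) integer(0)
  else unique(c(truth$planted$i, truth$planted$j))
  with_seed(seed, {
    lo <- base_logodds + logodds * (index$id %in% trans) +
      stats::rnorm(nrow(index), 0, noise_sd)
    frac <- stats::plogis(lo)
    width <- pmax(1, floor(frac * (index$end - index$start)))
    data.frame(chrom = index$chrom, start = index$start,
               end = index$start + width, name = "synthetic_feature",
               stringsAsFactors = FALSE)
  })
}

#' Simulate expression and gene-pair similarity with planted structure
#'
#' Genes hosted by a planted contact pair share a latent expression factor
#' with loading \code{a}, so their cross-pair co-expression rises with the
#' planting; all genes also get independent Gaussian noise. The similarity
#' table scores cross-segment gene pairs as \code{a} times the scaled rank
#' of the segment pair's true enrichment plus noise, clipped to [0, 1].
#'
#' @param genes gene table.
#' @param assignment gene-to-segment map.
#' @param truth planted-contact truth from \code{\link{simulate_contacts}}.
#' @param a structure strength (0 = null).
#' @param sigma_e similarity noise sd.
#' @param n_samples expression samples (default 43).
#' @param seed RNG seed.
#' @param n_null_pairs unplanted inter-chromosomal segment pairs added to
#'   the similarity table per planted pair (default 10).
#' @param index the \code{segment_index} (needed to draw null pairs).
#' @return list with \code{expression} (matrix) and \code{similarity}
#'   (data.frame \code{gene_a, gene_b, score}).
#' @export
simulate_expression <- function(genes, assignment, truth, index,
                                a = 0.8, sigma_e = 0.1, n_samples = 43,
                                seed = 1L, n_null_pairs = 10) {
  with_seed(seed, {
    G <- nrow(genes)
    expr <- matrix(stats::rnorm(G * n_samples), nrow = G,
                   dimnames = list(genes$gene_id, sprintf("s%d",
                                                          seq_len(n_samples))))
    bysec <- genes_by_segment(assignment)
    planted <- truth$planted
    for (r in seq_len(nrow(planted))) {
      z <- stats::rnorm(n_samples)
      gg <- c(bysec[[as.character(planted$i[r])]],
              bysec[[as.character(planted$j[r])]])
      gg <- intersect(gg, rownames(expr))
      for (g in gg) expr[g, ] <- expr[g, ] + a * z
    }
    # similarity over planted pairs plus random unplanted inter pairs
    chrom <- index$chrom
    pool_i <- integer(0); pool_j <- integer(0); pool_f <- numeric(0)
    if (nrow(planted)) {
      pool_i <- planted$i; pool_j <- planted$j; pool_f <- planted$f
    }
    want <- n_null_pairs * max(1, nrow(planted))
    taken <- pair_key(pool_i, pool_j)
    guard <- 0
    while (length(pool_i) < nrow(planted) + want && guard < 50 * want) {
      guard <- guard + 1
      x <- sample.int(nrow(index), 2)
      if (chrom[x[1]] == chrom[x[2]]) next
      key <- pair_key(x[1], x[2])
      if (key %in% taken) next
      if (!length(bysec[[as.character(x[1])]]) ||
          !length(bysec[[as.character(x[2])]])) next
      taken <- c(taken, key)
      pool_i <- c(pool_i, min(x)); pool_j <- c(pool_j, max(x))
      pool_f <- c(pool_f, 1)
    }
    r01 <- (rank(pool_f, ties.method = "average") - 1) /
      max(1, length(pool_f) - 1)
    sim <- lapply(seq_along(pool_i), function(p) {
      ga <- bysec[[as.character(pool_i[p])]]
      gb <- bysec[[as.character(pool_j[p])]]
      if (!length(ga) || !length(gb)) return(NULL)
      gp <- expand.grid(gene_a = ga, gene_b = gb,
                        stringsAsFactors = FALSE)
      gp$score <- pmin(1, pmax(0, a * r01[p] +
                                 stats::rnorm(nrow(gp), 0, sigma_e)))
      gp
    })
    sim <- do.call(rbind, sim)
    list(expression = expr,
         similarity = if (is.null(sim))
           data.frame(gene_a = character(), gene_b = character(),
                      score = numeric()) else sim)
  })
}

#' Simulate a synteny map and a partially conserved second species
#'
#' Species B reuses the species-A layout under a random segment
#' permutation: every gene-bearing species-A segment becomes one region of
#' conserved gene order whose genes map 1:1 to orthologs placed in the
#' permuted species-B segment. A fraction \code{conserved_fraction} of the
#' species-A planted contacts is replicated (through the permutation) in
#' species B; the remainder is replaced by random species-B pairs, so both
#' species carry the same number of planted contacts.
#'
#' @param index species-A \code{segment_index}.
#' @param genes species-A gene table.
#' @param assignment species-A gene-to-segment map.
#' @param truth species-A truth from \code{\link{simulate_contacts}}.
#' @param conserved_fraction fraction of planted contacts conserved.
#' @param seed RNG seed.
#' @return list with \code{synteny} (a \code{synteny_map}),
#'   \code{genes_b}, \code{assignment_b}, \code{perm} (A segment id -> B
#'   segment id), \code{truth_b} (planted table with
#'   \code{conserved} flag).
#' @export
simulate_synteny <- function(index, genes, assignment, truth,
                             conserved_fraction = 0.5, seed = 1L) {
  n_seg <- nrow(index)
  with_seed(seed, {
    perm <- sample.int(n_seg)            # A segment id -> B segment id
    # orthologs: one region per gene-bearing A segment
    bysec <- genes_by_segment(assignment)
    rows <- lapply(names(bysec), function(s) {
      ga <- bysec[[s]]
      s <- as.integer(s)
      b <- perm[s]
      data.frame(region_id = sprintf("r%d", s),
                 chrom_a = index$chrom[s], start_a = index$start[s],
                 end_a = index$end[s],
                 chrom_b = index$chrom[b], start_b = index$start[b],
                 end_b = index$end[b],
                 gene_a = ga, gene_b = paste0("m_", ga),
                 stringsAsFactors = FALSE)
    })
    syn <- synteny_map(do.call(rbind, rows))
    # species-B gene table: orthologs at the homologous offset
    gidx <- match(syn$gene_a, genes$gene_id)
    offs <- genes$start[gidx] - index$start[assignment[syn$gene_a]]
    lens <- genes$end[gidx] - genes$start[gidx]
    bstart <- pmin(syn$start_b + offs, syn$end_b - lens - 1)
    genes_b <- data.frame(gene_id = syn$gene_b, chrom = syn$chrom_b,
                          start = pmax(syn$start_b, bstart),
                          end = pmax(syn$start_b, bstart) + lens,
                          strand = "+", stringsAsFactors = FALSE)
    assignment_b <- stats::setNames(perm[assignment[syn$gene_a]], syn$gene_b)
    # conserved subset of planted contacts, mapped through the permutation
    planted <- truth$planted
    n_pl <- nrow(planted)
    n_cons <- round(conserved_fraction * n_pl)
    cons <- if (n_pl) sort(sample.int(n_pl, n_cons)) else integer(0)
    tb <- NULL
    if (n_pl) {
      bi <- perm[planted$i[cons]]
      bj <- perm[planted$j[cons]]
      tb <- data.frame(i = pmin(bi, bj), j = pmax(bi, bj),
                       f = planted$f[cons],
                       conserved = rep(TRUE, length(cons)))
      chrom <- index$chrom
      taken <- pair_key(tb$i, tb$j)
      while (nrow(tb) < n_pl) {
        x <- sample.int(n_seg, 2)
        if (chrom[x[1]] == chrom[x[2]]) next
        key <- pair_key(x[1], x[2])
        if (key %in% taken) next
        taken <- c(taken, key)
        tb <- rbind(tb, data.frame(i = min(x), j = max(x),
                                   f = planted$f[1], conserved = FALSE))
      }
    } else {
      tb <- data.frame(i = integer(), j = integer(), f = numeric(),
                       conserved = logical())
    }
    list(synteny = syn, genes_b = genes_b, assignment_b = assignment_b,
         perm = perm, truth_b = list(planted = tb),
         conserved_index = cons)
  })
}

#' Segment network implied by a planted-contact table
#'
#' Convenience for truth-level analyses: the graph whose edges are exactly
#' the given segment pairs, over the full segment universe.
#'
#' @param pairs data.frame with integer columns \code{i}, \code{j}.
#' @param index the \code{segment_index}.
#' @return an \code{igraph} graph shaped like a SIN.
#' @export
pairs_network <- function(pairs, index) {
  igraph::graph_from_data_frame(
    data.frame(from = as.character(pairs$i), to = as.character(pairs$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(index$id),
                          chrom = index$chrom))
}

#' Write a complete synthetic dataset to disk
#'
#' Emits the full external file set (chromosome sizes, contacts,
#' background, genes BED, feature BED, expression TSV, similarity TSV,
#' synteny TSV) plus a ground-truth JSON, all plain text.
#'
#' @param spec an \code{architecture_spec}.
#' @param dir output directory (created if needed).
#' @param seed RNG seed (per-stage seeds are derived from it).
#' @return invisibly, the list of generated objects.
#' @export
write_synthetic_dataset <- function(spec, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- spec$layout
  index <- segment_index(layout)
  sim <- simulate_contacts(spec, seed = seed)
  genes <- simulate_genes(layout, spec$genes_per_segment_mean,
                          seed = seed + 1)
  assignment <- assign_genes(genes, index)
  feats <- simulate_features(index, sim$truth, spec$feature_logodds,
                             seed = seed + 2)
  ex <- simulate_expression(genes, assignment, sim$truth, index,
                            a = spec$coexpr_a, sigma_e = spec$coexpr_sigma,
                            n_samples = spec$n_samples, seed = seed + 3)
  syn <- simulate_synteny(index, genes, assignment, sim$truth,
                          spec$conserved_fraction, seed = seed + 4)
  p <- function(f) file.path(dir, f)
  utils::write.table(data.frame(layout$chrom_names, layout$chrom_lengths),
                     p("chrom_sizes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  ct <- data.frame(index$chrom[sim$counts$i], index$start[sim$counts$i],
                   index$chrom[sim$counts$j], index$start[sim$counts$j],
                   sim$counts$count)
  utils::write.table(ct, p("contacts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bt <- data.frame(index$chrom[sim$background$i],
                   index$start[sim$background$i],
                   index$chrom[sim$background$j],
                   index$start[sim$background$j], sim$background$m)
  utils::write.table(bt, p("background.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(genes[c("chrom", "start", "end", "gene_id")],
                     p("genes.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(feats, p("features.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(gene = rownames(ex$expression),
                                ex$expression, check.names = FALSE),
                     p("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ex$similarity, p("similarity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_synteny(syn$synteny, p("synteny.tsv"))
  jsonlite::write_json(
    list(planted = sim$truth$planted, hub = sim$truth$hub,
         planted_b = syn$truth_b$planted,
         conserved_fraction = spec$conserved_fraction, seed = seed),
    p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(layout = layout, index = index, contacts = sim,
                 genes = genes, assignment = assignment, features = feats,
                 expression = ex, synteny = syn))
}
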