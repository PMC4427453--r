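# transnet

Network analysis of inter-chromosomal (trans) Hi-C contacts in R.

Hi-C read pairs spanning two chromosomes are sparse and noisy: most
apparent trans-contacts are ligation background, and read depth per locus
pair is far too low to work at fragment resolution. `transnet` implements
a segment-level statistical pipeline for this regime:

1. **Contact calling.** The genome is tiled into fixed-size segments
   (default 500 kb). For segments *a*, *b* on different chromosomes, with
   *k* observed reads, *n* total reads between the two chromosomes and a
   background contact probability *m* from an upstream bias model, the
   contact p-value is the binomial tail

   P(X ≥ k),  X ~ Binomial(n, m),

   computed separately per chromosome pair. Benjamini–Hochberg FDR control
   gives q-values, which are then length-normalized
   (q·(L̄/(L_A+L_B))^γ, with L̄ the mean summed length over all
   chromosome pairs) to remove the small-chromosome bias that per-pair
   testing induces.
2. **Networks.** Thresholding normalized q-values yields the segment
   interaction network (SIN); assigning each gene to the segment holding
   most of its body and expanding every SIN edge into a complete bipartite
   gene clique yields the gene interaction network (GIN). Each SIN edge
   with genes on both sides defines a *spatial cluster*.
3. **Null networks.** Matched random networks are built geometrically —
   nodes placed uniformly in the unit cube, the |E| closest pairs joined —
   then rewired by degree-preserving double-edge swaps accepted only when
   they raise transitivity toward the observed network's value, and
   re-populated with randomly drawn genes.
4. **Topology, enrichment, association, conservation.** Summary statistics
   (clustering coefficient, centralization, heterogeneity, path lengths,
   degree/length correlation, power-law fits), base-pair feature
   enrichment of trans-interacting segments, a 30-bin rank-binned
   permutation test linking spatial proximity to co-expression or
   functional similarity, and synteny-based scoring of cross-species
   contact conservation with a region-shuffling null.

A synthetic-data generator (`architecture_spec()`, `simulate_*()`) plants
known contacts, hubs, feature enrichment, co-expression structure and
conserved contacts, so the entire pipeline is testable end to end with no
external data.

The package is aimed at computational genomicists analysing binned trans
Hi-C contact matrices together with gene annotations, ENCODE-style
feature/TFBS tracks, expression matrices and ortholog tables.

## Worked example

```r
library(transnet)

spec <- architecture_spec()               # 4 chromosomes, 106 segments,
sim  <- simulate_contacts(spec, seed = 7) # 20 planted pairs (f = 50) + hub

st <- score_all_pairs(sim$counts, sim$background, sim$index)
sin <- build_sin(st, tau = 1e-3, sim$index)
summarize_network(sin)
#> network summary
#>   n_nodes                      106
#>   n_edges                      35
#>   connected_nodes              38
#>   isolated_nodes               68
#>   average_degree               0.6604
#>   max_degree                   16
#>   variance_over_mean           4.368
#>   heterogeneity                2.572
#>   clustering_coefficient       0
#>   centralization               0.1489
#>   characteristic_path_length   3.062
#>   diameter                     6
```

All 35 planted contacts (20 random pairs plus 15 hub edges) are recovered
at `q_norm <= 1e-3` with no false calls; the maximum-degree node (16) is
the planted hub, and the high `variance_over_mean` and `heterogeneity`
reflect its hub-dominated topology — the same degree-dispersion signature
that distinguishes real trans-contact networks from their randomized
counterparts (whose variance/mean sits near 1).

The remaining stages follow the same pattern; `run_pipeline()` chains them:

```r
genes <- simulate_genes(spec$layout, 5.5, seed = 8)
ex <- simulate_expression(genes, assign_genes(genes, sim$index),
                          sim$truth, sim$index, seed = 9)
res <- run_pipeline(sim$counts, sim$background, sim$index,
                    genes = genes, expr = ex$expression)
res$association$p       # permutation p of the binned proximity trend
```

## Scope

Fragment-level bias correction (hicpipe/Yaffe–Tanay style), GO semantic
similarity computation and synteny detection are upstream of this
package: background probabilities, similarity scores and ortholog tables
are consumed as inputs. Binary Hi-C formats (.hic/.cool) and
intra-chromosomal analysis are out of scope.
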