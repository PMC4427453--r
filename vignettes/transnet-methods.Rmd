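---
title: "Statistical methods behind transnet"
author: "transnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind transnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transnet)
```

## The problem

Inter-chromosomal ("trans") Hi-C contacts report which loci of different
chromosomes co-locate in nuclear space, but they sit at the bottom of the
Hi-C signal range: random ligation produces a large diffuse background,
and read depth per locus pair is orders of magnitude below what
intra-chromosomal analyses enjoy. `transnet` therefore works at a coarse,
fixed segment size (500 kb by default — fine enough to separate
functional neighborhoods, coarse enough that segment pairs accumulate
testable read counts) and treats contact detection as a per-pair
hypothesis test against an externally supplied background model.

## Contact significance

For segments $a, b$ on different chromosomes, let $k$ be the observed
read count for the pair, $n$ the total number of trans reads between the
two host chromosomes, and $m$ the background probability that a read of
this chromosome pair falls on $(a,b)$, as produced by an upstream
fragment-bias model and averaged over the segment pair. The p-value is
the binomial survival function

$$P(a,b) \;=\; \sum_{i=k}^{n} \binom{n}{i} m^i (1-m)^{n-i},$$

the probability of seeing at least $k$ reads by background alone. It is
evaluated through `pbinom`'s numerically stable tail, and the unit tests
hold it to within $10^{-12}$ of direct pmf enumeration for all $n \le
50$.

Conditioning $n$ on the chromosome *pair* (rather than the genome) keeps
$\sum_b m$ coherent with a multinomial read-allocation model, but has a
side effect: chromosome pairs with few reads produce systematically more
extreme p-values. After genome-wide Benjamini–Hochberg adjustment
(`p.adjust(method = "fdr")`, the conservative reading when the testing
universe is ambiguous), q-values are therefore rescaled by relative
chromosome-pair length:

$$q_{norm} = q \cdot \left( \frac{\bar L}{L_A + L_B} \right)^{\gamma},
\qquad \bar L = \underset{\{C,D\}}{\operatorname{mean}} (L_C + L_D),$$

with $\gamma = 1$ by default and $\gamma = 0$ switching the correction
off. The multiplicative form and the exponent are this package's own
construction — the requirement is only that pairs of short chromosomes be
penalized smoothly and monotonically, and the exponent is exposed so the
strength of the penalty can be tuned. Note $q_{norm}$ is a ranking and
thresholding quantity, not a probability; it may exceed 1.

Each scored pair also carries a *spatial proximity value*. The default is
the observed/expected ratio $k/(n m)$; $-\log_{10} q_{norm}$ is available
as a config switch. Both are monotone summaries of contact strength; the
ratio is preferred as default because it is independent of the testing
machinery that the proximity value is later correlated against.

Arbitrary region pairs (e.g. whole developmental gene clusters) are
tested by summing $k$ and $m$ over all segment pairs spanning the two
regions and applying the same tail probability.

## Networks

The segment interaction network (SIN) connects segments with
$q_{norm} \le \tau$ on different chromosomes; all segments remain nodes,
so isolated-node counts are meaningful. The gene interaction network
(GIN) assigns every gene to the segment holding the largest share of its
body (ties to the lower-coordinate segment) and expands each SIN edge
into a complete bipartite clique between the two gene sets. This
expansion deliberately over-connects — it asserts that *some* genes of
the two segments interact, not all — and the package keeps the graph
simple: gene pairs reachable through several segment edges collapse to
one edge. SIN edges with a gene-less endpoint vanish in the GIN, which is
why gene-level and segment-level connectivity can differ qualitatively.

## Randomization

The null model mirrors the spatial character of the data rather than
using a pure configuration model: nodes are scattered uniformly in
$[0,1]^3$ and the $|E|$ closest pairs are connected, with distance ties
broken lexicographically by node id so the construction is deterministic
given positions. The graph is then rewired by degree-preserving
double-edge swaps — $10 |E|$ attempts by default — accepting a swap only
if it strictly increases the number of triangles without pushing global
transitivity above the observed network's value. Because degree-preserving
swaps leave the connected-triple count invariant, the transitivity
comparison reduces to integer triangle counts, which the implementation
tracks incrementally (the gain of a proposed swap is counted on the graph
with both old edges already removed, so triangles through a deleted edge
are never credited). Degree-preserving swaps are one reading of
"exchanging edges between neighbors"; an endpoint-rewiring variant would
relax the degree constraint, and the acceptance cap makes either variant
conservative. The randomized GIN then draws, for each segment, as many
genes as it originally held, without replacement from the full gene pool.

## Network statistics

The summary suite matches the conventions of standard network-analysis
tools: per-node clustering $C_n = 2e_n/(k_n(k_n-1))$ averaged over *all*
nodes with $C_n = 0$ for degree $< 2$ (so singleton-rich networks are not
credited with clustering); degree centralization
$\frac{N}{N-2}\frac{\max(k)-\overline{k}}{N-1}$ (the approximate form
$\max(k)/N - \overline{k}/(N-1)$ is also emitted); heterogeneity
$\sqrt{\operatorname{var}(k)}/\overline{k}$ with the population variance
— the square-root form is the one consistent with the identity
$\text{het} = \sqrt{(\operatorname{var}/\overline{k})/\overline{k}}$
relating it to the variance/mean ratio, and both quantities are
reported; characteristic path length and diameter over connected node
pairs only (restriction to the largest component is a config switch,
since either convention appears in practice); and a least-squares
power-law fit on the log-log degree histogram, reporting slope and
absolute fit correlation. Degree/length correlation is the Pearson $r$
of log mean degree per chromosome against log chromosome length, with
zero-degree chromosomes dropped and an exclusion list for chromosomes
dominated by single hubs.

## Feature enrichment

Trans-interacting segments (SIN degree $\ge 1$) are compared with the
remainder, optionally excluding sex chromosomes to avoid an
inactive-chromatin bias. Feature content is measured as merged base-pair
coverage — tracks are reduced before intersection, so fragmented or
duplicated intervals cannot double-count — and transcription-factor
binding as whole-interval site counts per segment. A gene counts as
"bound" if any site overlaps its body; no promoter window is imposed,
since the appropriate window is assay-dependent.

## Binned association

Raw per-pair correlations between spatial proximity and functional
similarity are expected to be near zero: Hi-C averages over millions of
cells and chromosome positions fluctuate with Brownian motion. The
rank-binning procedure sorts the $N$ (proximity, response) tuples by
proximity (stable sort; remainder tuples go to the earliest bins), forms
30 equal-count bins, and correlates the per-bin means. Binning inflates
correlation magnitude by construction, so the correlation is never
interpreted directly; significance comes from 1000 random re-pairings of
x and y, with the one-sided p-value read from the null cumulative
distribution (the raw exceedance fraction by default; the $(b+1)/(R+1)$
convention is a switch). The co-expression response for a segment pair is
the mean Pearson correlation over all cross-pair gene profiles
(constant profiles skipped); the mean is config-isolated so a median or
Fisher-z variant can be swapped in without touching the binning.

## Conservation

For each region of conserved gene order between two species, the
species-A contact partners of the region's genes are transferred through
the ortholog map ($H_M$) and compared with the measured species-B
partner set ($M$) as $|M \cap H_M| / \min(|M|, |H_M|)$ — normalizing by
the smaller set keeps the score meaningful when coverage differs between
species. Regions lacking genes on either side are excluded. The null
permutes the region correspondence (which B-region is compared with
which A-region) and recounts regions with non-empty overlap.

## The synthetic-data generator

The generator emulates exactly the statistical structure the pipeline
assumes, at a deliberately modest scale so the full suite runs in
seconds: a 4-chromosome, 53 Mb genome at 500 kb resolution (106
segments), 20,000 reads per chromosome pair, lognormal per-segment biases
(sdlog 0.3, a simple stand-in for GC/mappability/fragment-length
effects), 20 planted contact pairs at 50-fold enrichment plus one
15-partner hub, Poisson 5.5 genes per segment and 43 expression samples
— genes-per-segment and sample counts chosen to match the scale of
published trans-contact analyses, read counts and enrichment set high
enough that a calibrated caller should recover essentially all planted
pairs. Counts are drawn multinomially per chromosome pair, so totals are
exact and the binomial conditioning is faithful; the emitted background
holds the *pre-enrichment* probabilities, making planted pairs truly
significant against it and the generator an oracle for sensitivity and
FDR. Features, expression and similarity get their planted structure
through a logit shift, a shared latent factor (loading 0.8, noise 0.1)
and a scaled-rank score respectively; a second species reuses the layout
under a random segment permutation with a configurable fraction of
planted contacts conserved.

What the generator does **not** emulate: distance decay and domain
structure within chromosomes (out of scope — the pipeline ignores cis
pairs), copy-number and translocation artifacts, mappability holes, and
fragment-level bias correlations. Passing tests therefore demonstrate
the statistical machinery is correct and calibrated under the stated
model, not that any particular biological dataset satisfies that model.

## Numerical and design notes

* Binomial tails via the survival function, never by summing pmf terms in
  user code; enumeration appears only as a test oracle.
* All coordinates are 0-based half-open internally; BED enters natively,
  GTF is converted at the boundary. Strand is read and ignored.
* Duplicate contact rows are summed (triangular and full dumps load
  identically); duplicate background rows must agree.
* Zero-count pairs are implicitly $p = 1$ and never materialized.
* Every stochastic routine takes an explicit seed and restores the
  caller's RNG state; the pipeline uses per-stage seeds so stages can be
  re-run in isolation.
* BH adjustment is order-preserving and dominates the input, but is not
  idempotent — re-adjusting adjusted values changes them — so the tests
  assert monotonicity rather than a fixed point.
* Degenerate cases: empty networks summarize to zeros with $N$ set;
  constant bin means make the binned correlation `NA` with a warning;
  centralization requires $N > 2$; the power-law fit requires two
  distinct degrees.

## Problem sizes

The bundled test and acceptance workloads use the generator defaults
above (106 segments, ~4,000 scored pairs per run), 1,000 association
permutations, 500 conservation shuffles and a 2,000-node randomized
network — sizes chosen so the complete validation executes in about a
minute on one CPU while leaving every statistical check well-powered.

## Known limitations

The length normalization is a declared stand-in for an under-specified
published procedure; with $\gamma$ fixed at 1 it removes the first-order
chromosome-length bias but is not calibrated against any dataset.
Segment-level GIN expansion over-connects by design. The geometric null
discards chromosome labels, so per-chromosome statistics of randomized
networks are not meaningful. The binned permutation p-value has
resolution $1/R$; reported zeros mean $p < 1/R$.
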