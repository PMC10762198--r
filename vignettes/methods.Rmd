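---
title: "Sample-specific subnetworks of the pelagic microbial interactome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample-specific subnetworks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelagicnets)
```

## The problem

Association networks inferred from marker-gene abundance tables summarize
putative ecological interactions among marine microbes. A single network
built from hundreds of samples spanning several ocean regions and the whole
water column mixes cosmopolitan, regional, and depth-restricted
associations. `pelagicnets` implements the machinery to disentangle them:
it carves a *sample-specific subnetwork* out of the static network for every
sample, quantifies where each association recurs, classifies associations
into spatial prevalence classes, profiles their vertical connectivity, and
compares subnetworks by topology alone.

## The subnetwork model

Let $e = \{A, B\}$ be an edge of the single static network and $s_{RL}$ a
sample from region $R$ and depth layer $L$. The edge belongs to the
subnetwork $N_s$ iff

1. $e$ is a static-network edge,
2. both $A$ and $B$ have counts $> 0$ in $s$, and
3. the region- and layer-specific Jaccard index
   $J_{RL} = \frac{|\text{samples of } (R,L) \text{ with both}|}
   {|\text{samples of } (R,L) \text{ with at least one}|}$
   is strictly above the threshold (default 20%; an edge at exactly 20% is
   removed, and an undefined $J_{RL}$ — empty union — fails the condition).

Nodes are the endpoints of retained edges, so no subnetwork contains
isolated nodes. `subsample_robustness()` repeats condition 3 on random
10–90% subsets of each group (sizes rounded up so no subset is empty;
single-sample groups are skipped) to show how stable the kept edge set is.

## Spatial classes

Prevalence is the fraction of subnetworks of a grouping that contain an
edge. Within a layer, the hierarchy over the per-region prevalences $p_r$
is: *global* if $\min_r p_r > 0.7$; else *prevalent* if $\min_r p_r > 0.5$;
else *low-frequency* if $\min_r p_r > 0.2$; else *regional* if the edge
appears in exactly one region of the layer; else *other*. Edges absent from
a layer but present in another are *absent* (kept separate from edges never
seen anywhere). All thresholds are strict. Two interpretive choices are
worth making explicit:

* The published band notation ("prevalent: ≤ 70% and > 50%") is realized by
  the hierarchy as "min over regions inside the band", which coincides with
  the banded reading.
* The threshold classes are evaluated both with all regions and with the
  enclosed sea excluded, but *regional* status is always judged against all
  sampled regions of the layer. This is what makes the published per-layer
  accounting identity (threshold classes + regional + other = present) hold
  in both modes with a single regional block, and it is how the bundled
  table's sums do in fact reconcile.
* Regional eligibility requires a sampled region; cells that were never
  sampled do not count as "absent elsewhere".
* Epipelagic samples that belong to neither the surface nor the DCM
  sublayer can be tagged `EPI_OTHER`: they receive subnetworks (their
  Jaccard group is their own) but are excluded from per-layer
  classification.

The vertical profile of a region records, per edge, presence (prevalence
> 0) across the ordered layers and the earliest layer of appearance;
layers never sampled in a region are "not assessable", distinct from
absent.

## Environmentally-driven edges

An association can reflect a shared environmental response rather than an
interaction. For each environmental factor $E$ (evaluated independently,
using only samples where the factor is measured), the package combines two
verdicts on each edge:

* **Interaction information.** $II = \mathrm{CMI}(A;B\mid E) -
  \mathrm{MI}(A;B)$ on equal-frequency-discretized vectors; a negative
  value means the factor explains part of the pairwise association. A
  permutation test (factor permuted across samples; one-sided, add-one
  corrected) assesses it. The plug-in CMI estimator is biased upward by
  roughly (number of extra cells)/(2n) nats, so the raw II of an unrelated
  triplet sits above zero; the same permutation replicates estimate that
  null level, and the sign gate is applied to the bias-corrected
  $II - \overline{II_{\text{perm}}}$. This keeps the "negative means
  environmentally explained" reading, leaves synergistic (XOR-like)
  triplets unflagged, and makes the test reject at the nominal rate under
  the null — the uncorrected sign gate would reject nothing at realistic
  sample sizes.
* **Data-processing inequality.** The edge is flagged when
  $\mathrm{MI}(A;B)$ is strictly the smallest of the triplet
  $\{\mathrm{MI}(A;B), \mathrm{MI}(A;E), \mathrm{MI}(B;E)\}$; ties are
  kept.

An edge is removed when *both* verdicts agree for at least one factor; the
removed set is the union over factors, and each factor derives its own RNG
stream from the master seed so adding a factor never changes another
factor's verdicts (removal grows monotonically).

Two numerical choices matter here. *Binning*: a small fixed number of
equal-frequency bins (default 4) is used rather than a
$\lceil\log_2 n\rceil$-style rule; at $n \approx 300$ the latter gives ~10
bins and a conditional-MI bias (~1.4 nats) that swamps the signal
entirely. Binning is rank-based so that a heavy tie (structural zeros)
occupies one bin instead of straddling a quantile break. *Input scale*:
the removal stage runs on depth-normalized (relative) abundances per
domain table. Raw counts of same-table ASVs share the sample's sequencing
depth as a common multiplicative factor, which inflates $\mathrm{MI}(A;B)$
and defeats the DPI ordering; dividing by the per-sample total removes
that channel while preserving zeros. The CLR scale is *not* used here: its
per-sample centering couples the pair through the co-varying mean of all
planted responders, which empirically made the confound worse.

## Topology comparison

Eight global metrics are computed per subnetwork (node and edge counts,
edge density, average path length over connected pairs only, transitivity,
degree assortativity, Euk–Prok nominal assortativity, and the mean positive
association score); any metric that is undefined on a degenerate input is
reported as missing, never as 0.

Label-free dissimilarity uses graphlets: exact per-node counts of the 15
automorphism orbits of the connected graphlets with up to 4 nodes (by
connected-subgraph enumeration that visits each induced subset exactly
once), Spearman correlations among the 11 non-redundant orbits (a dummy
node with unit counts keeps constant columns defined), and the Euclidean
norm of the difference between the two graphs' correlation matrices. This
satisfies the required contract — non-negative, zero for identical
topologies, symmetric, invariant under node relabeling — while the exact
formula used in the original analysis chain is configurable behind the
same interface. Near-complete graphs are a known weak spot: with almost no
sparse-graphlet mass, the orbit correlations become unstable, so distances
within a family of near-cliques are noisier than within sparser families.

The network-similarity network (NSN) is the complete graph over
subnetworks weighted by dissimilarity; its minimum spanning tree is built
with Kruskal's algorithm under a lexicographic (weight, endpoint,
endpoint) ordering, so equal-weight ties always resolve identically.

Clustering of the subnetworks embeds the dissimilarity matrix into 10
dimensions by classical multidimensional scaling and applies a
density-based scan on the embedding: points with at least 3 neighbours
within `eps` are cores, clusters are `eps`-connected components, border
points join the first-reached core's cluster, clusters smaller than 5 are
dissolved into noise. The default `eps` is twice the median distance to
the 3rd nearest neighbour; the whole procedure is deterministic, with no
random state at all. This stage makes no claim of reproducing any specific
embedding algorithm — it delivers the stated contract (10-dimensional
metric embedding, density clustering with minimum cluster size 5, noise
allowed, deterministic).

## The synthetic study

`generate_dataset()` emulates the sampling design the pipeline assumes, at
desk scale: 6 regions × 4 ordered layers × 12 samples per cell (288
samples; the real survey had 397 unevenly spread), 120 + 80 ASVs (the real
study kept ~2500 per domain — orders of magnitude more pairs than a
from-scratch run can test), read depths uniform in 5000–50000, and
environmental gradients (temperature decreasing with depth, nutrients
increasing, a fluorescence maximum at the DCM) with the enclosed sea given
a warm (≈13.8 °C), salty bathypelagic and a few percent of missing
environmental values.

Planted pairs share a latent Gaussian factor scaled by
`co_occurrence_strength` (default 0.9); a member is present when its
latent exceeds the occupancy threshold (0.97 marginal occupancy for
co-occurring pairs), so the Jaccard condition sees the co-occurrence
directly. Regional and layer-specific pairs are structurally absent
outside their scope. Environmentally-driven pairs replace the shared
factor by a standardized environmental gradient with *independent*
residuals — conditionally independent given the factor, exactly the
construct the II + DPI filter is meant to remove. Negative pairs load on
the shared factor with opposite signs at 0.35 occupancy, so their rare
joint presences stay below any co-occurrence condition. Background ASVs
get independent occupancies drawn from 0.45–0.70: cosmopolitan enough
that background decoy edges do not imitate one-region (regional) patterns
at 12 samples per cell, which would otherwise contaminate the
planted-truth evaluation with chance regionals. Counts are multinomial
per domain table at the drawn read depth, followed by independent dropout
(2%) — dropout hits joint presence quadratically, which bounds how much
zero-inflation the planted contracts can carry.

Within its home layer, a layer-specific pair spans all regions at high
prevalence, so the per-layer classifier *correctly* calls it global there;
the recovery metric therefore expects it as global in its home layer.
Environmentally-driven pairs are scored only by the removal metric
(removed set against planted env pairs) and are excluded from the spatial
scoring universe, because their expected spatial class depends on whether
the filter already caught them.

What passing these tests shows — and does not. The generator produces
presence/absence co-occurrence, compositional counts, depth structure and
environmental confounding, so it exercises every decision rule in the
pipeline. It does not emulate taxon-correlated sequencing error, spatial
autocorrelation within regions, particle-associated niches, or the
uneven sampling effort of real expeditions; recovery rates on this fixture
are upper bounds, not field performance.

## Problem sizes and determinism

Default analysis runs use 288 samples, ~125 static edges, 999 permutations
per interaction-information test and 200 robustness replicates — sizes at
which the full pipeline completes in a couple of minutes while every rate
estimate stays two-sided testable. The published study's scale (5448 nodes,
29118 edges, 10000 permutations) is reachable with the same code but is
not what the bundled analyses run. Every stochastic stage takes a single
master seed and derives per-factor, per-group streams from it by hashing
the stage labels, so results are identical under any evaluation order and
rerunning a configuration reproduces every output checksum.

## Known limitations

* The stand-in inference (`infer_standin_network()`) is a correlation
  screen with a pooled permutation null and BH control — a placeholder for
  a proper conditional-independence method, and clearly not equivalent to
  one; the canonical entry point for real data is `import_network()`.
* Interaction information is estimated on 4 equal-frequency bins; very
  nonlinear confounders, or factors measured on few samples, can slip
  through. The low-confidence flag (< bins² usable samples) marks the
  worst cases.
* The graphlet correlation distance treats subnetworks as unweighted
  simple graphs; association signs and strengths do not enter the
  topology comparison (they do enter the metrics table).
* Published-table checks validate the reporting arithmetic, not the
  full-scale inference: the study's headline network is not reproducible
  from scratch without its raw sequence data and external inference tool.
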