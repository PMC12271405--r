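---
title: "Methods: spatial interaction communities and niche signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial interaction communities and niche signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichescape)
```

## What the package computes

`nichescape` implements a pipeline for asking whether two groups of patients
differ in how cell phenotypes are *spatially organized* in their tumors, and
whether that organization matters clinically. It operates on two data
modalities:

* **Imaging mass cytometry (IMC)-style data**: per-cell protein intensities
  and centroid positions, grouped into regions of interest (ROIs) nested in
  patients.
* **Visium-style spatial transcriptomics (ST)**: gene-by-spot counts on a
  barcoded capture lattice.

The chain is: phenotype cells (K-means on normalized protein intensities),
quantify spatial adjacency of each phenotype pair against a within-ROI
shuffled-label null (Delaunay graph, permutation z-score), identify
group-differential interactions with a random-intercept mixed model, assemble
significant interactions into *communities* (connected components of the
interaction graph, pruned), score patients by summing the interaction
z-scores of a community's edges, and relate those scores to survival.
On the ST side, the protein markers of a community become a gene *query*:
the per-spot query co-localization score (QCS) and its permutation null
locate the community's niche, a mutual-rank silhouette statistic quantifies
its spatial coherence, differential expression between community-high and
community-low spots yields extended signature genes (ESGs), and the ESGs
feed cell-type projection and a ligand-receptor interaction network.

## Models and statistics

### Protein normalization and phenotyping

Raw intensities are `log1p`-transformed, z-scored per marker across cells,
then z-scored per cell across markers, in that order. The second z-score
removes per-cell staining intensity differences; zero-variance vectors map
to zeros by convention so constant markers drop out silently. The ordering
of the two z-scoring passes is a genuine interpretation choice (the reverse
order is defensible); we fix marker-then-cell and treat it as part of the
method's definition.

Phenotyping is Lloyd's K-means with many random restarts, keeping the
restart with minimal within-cluster sum of squares. The default K = 20
matches the resolution a ~26-marker panel supports. The restart default is
1,000; restarts only ever improve the optimum, and on data of the sizes
used in the tests the optimum stabilizes far below that.

A marker is *differential* for a cluster when one-vs-one Welch t-tests
against the other K−1 clusters are significant (p ≤ 0.05) with the higher
mean in that cluster in at least ⌈(K−1)·17/19⌉ comparisons (17 of 19 at
K = 20; the ratio is preserved for other K). Welch's test is used because
cluster sizes are very unequal. Directionality (higher mean) is required so
that marker lists can name clusters.

### Spatial proximity enrichment

Each ROI's cells are Delaunay-triangulated (`deldir`); the interaction
statistic for an unordered cluster pair is the number of graph edges joining
the two clusters. The null distribution comes from shuffling cluster labels
within the ROI (1,000 permutations by default), which conditions on both the
spatial graph and the cluster abundances; the z-score is
(observed − null mean)/null sd, set to 0 when the null sd is 0. Shuffling
within ROI only is essential: it makes z-scores comparable across ROIs with
different cellularity.

### Group-differential interactions

Per cluster pair, the per-ROI z-scores are modeled as
`z ~ group + (1 | patient)` against the null `z ~ 1 + (1 | patient)`, both
by maximum likelihood (`lme4`), compared with a likelihood-ratio test and
Benjamini-Hochberg adjusted across pairs. The random intercept absorbs the
repeated ROIs per patient; with exactly one ROI per patient the fit
degrades gracefully to ordinary regression (the package relaxes `lme4`'s
observation-count checks for this reason, and the test suite asserts
agreement with `lm` to 1e-6). A one-sided p (halving when the sign matches)
is reported alongside, since directional enrichment in a named group is the
usual question. Stability is assessed by leave-2-patient-out subsampling
(100 refits by default) summarized as a 2.5/97.5 percentile interval.

### Communities

Pairs passing q ≤ 0.20 with the focal-group sign form an undirected graph;
communities are its connected components after two pruning rules: a
single-node component carrying only a self-interaction is removed, and
bridge edges whose removal splits a component into two sub-components of at
least two nodes each are removed iteratively (lexicographically smallest
qualifying bridge first, making the result deterministic and independent of
edge input order). A pendant edge is never pruned because one side would be
a singleton. The permissive 0.20 cutoff is deliberate: community detection
is an expansion step, and spurious single edges are subsequently pruned or
land in small communities.

Communities found in independent cohorts are matched by the overlap of
their member clusters' differential-marker unions. The assignment maximizes
the total match score exactly (enumeration over the smaller side; detected
communities are few), with ties broken toward larger communities and then
lexicographic ids; the top-scoring match is "community 1". With only two
cohorts available, union/split ambiguities resolve toward the highest total
score.

### Patient scores and survival

A patient's per-community score is the sum over the community's edges of the
patient's mean per-ROI z for that pair; the community-all score sums over
the group's communities. Averaging over ROIs (rather than summing) avoids
rewarding patients contributing more ROIs. Patients are stratified high/low
by the cohort mean of the community-all score. Stratified survival is
compared by Kaplan-Meier curves with a one-tailed log-rank test (direction:
high score, worse survival), and by Cox proportional hazards (partial
likelihood, Efron ties) univariately and adjusted for covariates, with
one-sided Wald tests. Ordinal covariates such as stage enter numerically as
provided.

### QCS and the spatial-clustering statistic

ST counts are library-scaled to the median spot total, `log1p`-transformed,
and z-scaled per gene across spots. "Scaled" is read as per-gene scaling
(the alternative, per-spot scaling, would let spot-wide activation dominate
the query signal). The QCS of a spot is the mean of the scaled expression
over the query genes; query genes absent from the panel are dropped and the
divisor counts retained genes. The null permutes each query gene's
expression independently across in-tissue spots, destroying inter-gene
dependence while preserving marginals; a spot is significant when its
empirical permutation p (with the +1 correction) falls below α = 0.05
against its own null. The per-spot (rather than pooled or max-over-spots)
null treats each spot's score as its own test statistic; under a null data
set it rejects at ≈ α per spot, which the tests verify.

Spatial coherence of the significant-spot mask is a silhouette-style
statistic δ: for each significant spot, the mean transformed distance to
background spots (m) and to the other significant spots (n) are combined as
(m − n)/max(m, n) and averaged. The transformed distance is
`1 − q^(mutual_rank − 1)` with q = 0.95, where the mutual rank of two spots
is the geometric mean of the rank of each in the other's Euclidean distance
ordering — the standard mutual-rank convention. This is the most
consequential convention choice in the ST half: other rank combinations
(minimum, arithmetic mean) would rescale δ. The transform
saturates quickly, so δ measures *local* cohesion: a compact disc scores
high, the same number of spots scattered scores near zero. The self-term is
excluded from n (its transformed self-distance is not zero). Distance ranks
use average ties; coordinates are array row/column by default.

### ESGs, cell-type projection, ligand-receptor network

Community-high and community-low spot sets are the top and bottom deciles
by QCS (stable order for ties). Per-sample ESGs are genes with a
Wilcoxon rank-sum q ≤ 0.05 (BH across genes) between high and low spots on
the log layer and a log2 fold change ≥ 0.25 on the library-normalized layer
(pseudocount 1e-9; z-scaled values can be negative, so fold changes are
always computed on the non-negative layer). A gene is a *recurrent* ESG of a
group when present in at least half of that group's per-sample lists and
strictly more often than in the other group; the two directions are
therefore disjoint by construction.

Cell-type projection multiplies the reference mean expression of a gene per
cell type by the gene's niche term (mean over niche spots minus mean over
all spots), where the niche is the community-high spot set. The
ligand-receptor network keeps pairs with both genes in the ESG set;
each retained pair distributes one unit of mass over the ordered cell-type
pairs expressing ligand (sender) and receptor (receiver) above threshold,
so the matrix total equals the number of retained pairs. "Expressed"
defaults to exceeding the gene's median across cell types — the source
procedure never defines it, so the threshold is exposed. Both the ordered
(ligand × receptor) and symmetrized matrices are reported.

Validation-style summaries are provided: per-gene log2 high/low fold
changes compared across groups by paired one-sided t-test over genes,
region-level gene-set scores (summed log-normalized expression) compared by
Welch t, and upper-tail hypergeometric overlap tests against external
signatures with the measured gene universe as default background.

## The synthetic-data generator

Every stage is tested against cohorts with planted ground truth, generated
by `gen_imc_cohort()`, `gen_st_cohort()`, `gen_reference_and_lr()` and
`gen_survival()` from a single validated `sim_config()`. The generators are
pure functions of the config (one seed stream split per patient/ROI/sample),
so identical configs give byte-identical cohorts.

* **IMC cohorts**: two abstract groups ("groupA"/"groupB"), 600×600 micron
  square ROIs, ~500 cells per ROI, cluster archetypes with two elevated
  markers each and log-normal intensity noise (sdlog 0.4, +1.5 log-units for
  archetype markers). A planted pair (a, b, group, strength) relocates each
  cluster-b cell, with probability `strength`, to within half the mean
  nearest-neighbor spacing of a random cluster-a cell — i.e. inside one
  Delaunay neighborhood — in that group's ROIs only. Strength 0 is exactly
  the null.
* **ST cohorts**: negative-binomial counts (dispersion 2) with log-normal
  gene baselines shared across samples. In groupA the planted query and ESG
  genes are multiplied by `exp(niche_effect)` inside a random disc of
  radius 7 spots on the default 40×40 lattice — about 10% of the array,
  chosen to match the top-decile community-high convention; in groupB the
  same genes are elevated at uniformly scattered spots of equal count, so
  the two groups differ in spatial arrangement, not signal mass. A
  consequence worth knowing: because both groups elevate the same genes,
  the strict cross-group ESG recurrence rule correctly returns an empty set
  on these cohorts — the discriminating statistic between the groups is the
  spatial-clustering δ of the significant spots, not ESG identity.
* **Queries**: the canonical test conditions use a 15-gene planted query
  and 25 planted ESGs, the size of a community-derived marker query in
  practice.
* **Survival**: event times are exponential with hazard
  `h0 · HR^z` (z the standardized score, `h0 = log(2)/36` months);
  censoring is independent exponential with per-subject rate
  `rate · c/(1 − c)`, giving expected censored fraction c exactly.

What the generator does **not** emulate: tissue morphology, segmentation
error, spot deconvolution mixtures, marker spillover, batch effects between
cohorts, and informative censoring. Passing tests therefore demonstrate the
statistical machinery is correct and calibrated under clean planted
structure, not that the pipeline is robust to those artifacts in real data.

## Numerical choices and degenerate inputs

* Duplicate cell coordinates are jittered by 1e-6 (deterministically, seeded
  from the ROI id) before triangulation; fewer than 3 cells or collinear
  cells raise an error naming the ROI.
* Proximity z is 0 whenever the null sd is 0 (e.g. one cluster in an ROI).
* Degenerate mixed-model fits (constant response) report p = 1.
* Pairs observed in fewer than 3 ROIs are skipped with a warning.
* Spots with zero total counts are dropped with a warning before
  normalization; zero-variance genes give z-rows of zeros and are skipped in
  differential testing.
* The pixel co-localization threshold is strict (`< 40` pixels; a pair at
  exactly 40 does not count).
* Stratification ties are broken by stable spot order; patients scoring
  exactly the cohort mean fall in the "low" stratum.

## Problem sizes used in the tests

The suite and the acceptance script run at desk scale, chosen so the full
suite completes in a couple of minutes while keeping every statistical check
at the sizes its calibration bounds assume: 50 ROIs of 500 cells for
permutation calibration; 10 patients per group × 2 ROIs for the mixed model
(50 planted replicates, 200 null replicates); 40×40-spot arrays with 500
genes and 1,000 permutations for QCS; 100 random graphs of up to 12 nodes
for community pruning; n = 60 patients and 100 replicates for survival
power. The methods themselves have no size-dependent constants.

## Known limitations

* The likelihood-ratio test for the group effect is asymptotic; with very
  few patients its type-I rate drifts above nominal (the tests pin it
  within [0.02, 0.09] at 10 patients per group).
* QCS significance is per-spot and unadjusted across spots by design; the
  per-sample count of significant spots inherits the per-spot false-positive
  rate (~α of background spots), which matters when niches are small.
* Exact community matching enumerates assignments and is exponential in the
  number of communities; it falls back to greedy beyond 8 per side.
* The mutual-rank silhouette requires at least two spots on each side of
  the mask and is O(n²) memory in spots.
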