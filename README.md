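# nichescape

Tools for discovering **group-associated cell–cell interaction communities**
in single-cell spatial proteomics (imaging mass cytometry, IMC) and for
locating and extending those communities in **spatial transcriptomics**
(Visium-style arrays), with survival association of community scores.

The scientific question it serves: two patient groups may carry tumors whose
cell *types* look alike but whose cells are *arranged* differently. The
pipeline quantifies spatial adjacency of phenotype pairs, finds the pairs
that differ between groups, assembles them into multicellular communities,
asks whether a community's presence predicts survival, and then uses the
community's markers as a gene query to find and characterize the matching
niche in spatial transcriptomics — spatial coherence, extended signature
genes (ESGs), cell-type composition, and ligand–receptor structure.

## The statistics at the core

* **Proximity enrichment.** For each ROI, a Delaunay graph over cell
  centroids; for clusters *a, b* the statistic is the number of edges
  joining them, and the null is obtained by shuffling cluster labels within
  the ROI (graph and abundances fixed):
  `z = (obs − mean_null) / sd_null`.
* **Differential interactions.** Per pair, a random-intercept mixed model
  `z ~ group + (1|patient)` vs `z ~ 1 + (1|patient)` (ML), likelihood-ratio
  tested, BH-adjusted; communities are connected components of the q ≤ 0.20
  graph after pruning self-loop singletons and bridges.
* **Patient scores.** Mean per-ROI z per pair, summed over a community's
  edges, summed over communities; high/low strata by the cohort mean;
  one-tailed log-rank and Cox proportional hazards (Efron ties).
* **Query co-localization score.** Per spot,
  `QCS_x = (1/|Q|) Σ_{q∈Q} Expr_x(q)` on scaled, log-normalized expression;
  significance against a per-spot null that permutes each query gene
  independently across in-tissue spots; `QCS_A` counts significant spots.
* **Spatial clustering.** A silhouette statistic
  `δ = mean_{i∈L1} (m_i − n_i)/max(m_i, n_i)` on the mutual-rank transformed
  distance `r(i,j) = 1 − q^(rank_d(i,j) − 1)`, q = 0.95.
* **ESGs and the ligand–receptor network.** Top/bottom QCS deciles per
  sample, Wilcoxon + BH + log2-fold-change floor, 50% recurrence with strict
  cross-group dominance; cell-type projection
  `Expr_{g,c,N} = AvgExpr_{g,c} · V_{g,N}`; LR pairs within the ESGs scored
  as `CI(c1,c2) = Σ_LR I(LR,c1,c2)/N(LR)`.

A synthetic-data generator (`sim_config()` + `gen_*`) plants spatially
adjacent cluster pairs, compact expression niches, and score-linked hazards,
so every stage is testable against ground truth. See the methods vignette
(`vignettes/spatial-niche-methods.Rmd`) for model details and design
choices.

## Worked example

Simulate a two-group IMC cohort in which clusters 1 and 2 are spatially
adjacent in groupA only, run the discovery chain, and test survival:

```r
library(nichescape)

cfg <- sim_config(seed = 42, n_patients_per_group = 10, rois_per_patient = 2,
                  cells_per_roi = 300, n_markers = 12, n_clusters = 5,
                  planted_pairs = list(list(a = 1, b = 2, group = "groupA",
                                            strength = 0.8)),
                  hazard_ratio = 3, censoring_fraction = 1/3)
cohort <- gen_imc_cohort(cfg)

mat   <- normalize_expression(cohort$intensities)
model <- cluster_cells(mat, k = 5, n_restarts = 50, seed = 1)
model <- differential_markers(model, mat)

it <- interaction_table(cohort$cells, model$labels, n_perm = 500, seed = 2)
di <- differential_interactions(it, cohort$roi_meta, ref_group = "groupA")
head(di[order(di$q), c("cluster_a", "cluster_b", "coef", "p", "q")], 3)
#>    cluster_a cluster_b  coef        p        q
#> 13         3         5  2.58 1.25e-08 1.87e-07
#> 12         2         5 -2.16 4.61e-08 3.45e-07
#> 6          3         3 -1.87 1.75e-07 8.76e-07

comms <- detect_communities(di, fdr = 0.20,
                            markers = setNames(model$markers, 1:5))
comms
#> community community1: nodes {1, 2, 4}, 6 edges, 6 markers
#> community community2: nodes {3, 5}, 1 edges, 4 markers

scores <- score_patients(it, comms, cohort$roi_meta)
surv   <- gen_survival(setNames(scores$score, scores$patient_id), cfg)
km_logrank(scores, surv)$p_one_sided
#> 0.015
cox_ph(transform(scores, score = as.vector(scale(score))), surv)
#>        model  term   hr p_one_sided
#> 1 univariate score 3.52     0.00332
```

The mixed model flags several pairs whose adjacency differs between groups
(planting one adjacency perturbs the whole spatial layout, so neighboring
pairs shift too); the pruned interaction graph yields two communities, one
containing the planted pair under its K-means labels. Patients with high
community-all scores die faster: the one-tailed log-rank p is 0.015 and the
Cox hazard ratio per score standard deviation is 3.5, close to the planted
hazard ratio of 3.

On the spatial-transcriptomics side, `normalize_st()` + `qcs()` recover a
planted 10%-of-array niche with Jaccard ≈ 0.9 at a 1.5 log-unit effect, and
`spatial_clustering()` separates compact from scattered arrangements of the
same signal mass (see the acceptance script output).

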