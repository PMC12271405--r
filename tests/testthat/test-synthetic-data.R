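test_that("generators are deterministic in the seed and honor the config", {
  cfg <- sim_config(seed = 3, n_patients_per_group = 5, rois_per_patient = 2,
                    cells_per_roi = 100, n_markers = 8, n_clusters = 4,
                    n_genes = 60, st_grid = c(12L, 12L), niche_radius = 3,
                    planted_query_genes = sprintf("g%04d", 1:4))
  co1 <- gen_imc_cohort(cfg)
  co2 <- gen_imc_cohort(cfg)
  expect_identical(co1, co2)
  expect_equal(nrow(co1$metadata), 10)
  expect_equal(length(unique(co1$cells$roi_id)), 20)
  expect_equal(nrow(co1$cells), 10 * 2 * 100)
  expect_true(all(co1$cells$x >= 0 & co1$cells$x <= 600))

  st1 <- gen_st_cohort(cfg)
  st2 <- gen_st_cohort(cfg)
  expect_identical(st1, st2)
  expect_equal(ncol(st1$samples[[1]]$counts), 144)
  expect_equal(length(st1$samples), 10)

  rl1 <- gen_reference_and_lr(cfg)
  rl2 <- gen_reference_and_lr(cfg)
  expect_identical(rl1, rl2)
})

test_that("config validation rejects bad planted structure", {
  expect_error(sim_config(planted_pairs = list(list(a = 1, b = 2,
                                                    group = "groupA",
                                                    strength = 1.5))),
               "strength")
  expect_error(sim_config(n_clusters = 4,
                          planted_pairs = list(list(a = 1, b = 9,
                                                    group = "groupA",
                                                    strength = 0.5))),
               "beyond")
  expect_error(sim_config(n_genes = 10,
                          planted_query_genes = "g9999"), "universe")
  expect_error(sim_config(hazard_ratio = 0), "positive")
  expect_error(sim_config(st_grid = c(10L, 10L), niche_radius = 6), "half")
  expect_error(gen_imc_cohort(sim_config(cells_per_roi = 15, n_clusters = 4)),
               "10 \\* n_clusters")
})

test_that("zero adjacency strength leaves planted pairs at the null", {
  mk <- function(strength, seed) {
    cfg <- sim_config(seed = seed, n_patients_per_group = 5,
                      rois_per_patient = 2, cells_per_roi = 200,
                      n_markers = 8, n_clusters = 4,
                      planted_pairs = list(list(a = 1, b = 2, group = "groupA",
                                                strength = strength)))
    co <- gen_imc_cohort(cfg)
    it <- interaction_table(co$cells, co$truth$labels, n_perm = 300, seed = seed)
    it
  }
  it0 <- mk(0, 42)
  z_planted <- it0$z[it0$cluster_a == 1 & it0$cluster_b == 2]
  z_other <- it0$z[!(it0$cluster_a == 1 & it0$cluster_b == 2)]
  # strength 0: planted-pair z indistinguishable from the other pairs
  expect_gt(stats::t.test(z_planted, z_other)$p.value, 0.01)

  # strong planted adjacency separates the designated group clearly
  it1 <- mk(0.8, 43)
  sel <- it1$cluster_a == 1 & it1$cluster_b == 2
  z1A <- it1$z[sel & grepl("^P_A", it1$roi_id)]
  z1B <- it1$z[sel & grepl("^P_B", it1$roi_id)]
  expect_lt(stats::t.test(z1A, z1B)$p.value, 0.01)
  expect_gt(mean(z1A) - mean(z1B), 1)
})

test_that("ST generator plants a compact niche in one group and scatter in the other", {
  qg <- sprintf("g%04d", 1:5)
  cfg <- sim_config(seed = 9, n_patients_per_group = 2, n_genes = 80,
                    st_grid = c(16L, 16L), niche_radius = 4,
                    planted_query_genes = qg, niche_effect = 1.5)
  st <- gen_st_cohort(cfg)
  mA <- st$truth$niche_mask[["S_A_01"]]
  mB <- st$truth$niche_mask[["S_B_01"]]
  expect_equal(sum(mA) > 0, TRUE)
  # same total planted mass in both groups
  expect_equal(sum(mB), sum((expand.grid(r = 0:15, c = 0:15)$r - 8)^2 +
                            (expand.grid(r = 0:15, c = 0:15)$c - 8)^2 <= 16))
  s <- normalize_st(st$samples[["S_A_01"]])
  # planted genes really are elevated inside the disc
  lfc <- mean(s$lognorm[qg, mA]) - mean(s$lognorm[qg, !mA])
  expect_gt(lfc, 0.5)
  # niche_effect = 0 carries no signal
  cfg0 <- sim_config(seed = 9, n_patients_per_group = 1, n_genes = 80,
                     st_grid = c(16L, 16L), niche_radius = 4,
                     planted_query_genes = qg, niche_effect = 0)
  st0 <- gen_st_cohort(cfg0)
  s0 <- normalize_st(st0$samples[["S_A_01"]])
  m0 <- st0$truth$niche_mask[["S_A_01"]]
  pv <- stats::t.test(as.vector(s0$lognorm[qg, m0]),
                      as.vector(s0$lognorm[qg, !m0]))$p.value
  expect_gt(pv, 0.01)
})

test_that("planted disc masks are more spatially clustered than scattered masks", {
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, n_patients_per_group = 1, n_genes = 30,
                      st_grid = c(16L, 16L), niche_radius = 4)
    st <- gen_st_cohort(cfg)
    coords <- as.matrix(st$samples[[1]]$coords[, c("array_row", "array_col")])
    d_disc <- spatial_clustering(coords, st$truth$niche_mask[["S_A_01"]])
    d_scat <- spatial_clustering(coords, st$truth$niche_mask[["S_B_01"]])
    expect_gt(d_disc, d_scat)
  }
})

test_that("reference markers peak in their own cell type and LR table is unique", {
  cfg <- sim_config(seed = 4, n_genes = 200, n_lr_pairs = 50,
                    planted_esg_genes = sprintf("g%04d", 50:69))
  rl <- gen_reference_and_lr(cfg)
  for (ty in colnames(rl$reference))
    for (g in rl$markers[[ty]])
      expect_equal(colnames(rl$reference)[which.max(rl$reference[g, ])], ty)
  expect_equal(nrow(rl$lr), 50)
  expect_equal(nrow(unique(rl$lr)), 50)
  # the planted subset sits inside the planted ESGs
  expect_true(all(unlist(rl$planted_lr) %in% cfg$planted_esg_genes))
})

test_that("survival generator respects censoring and recovers the planted hazard", {
  cfg0 <- sim_config(seed = 5, censoring_fraction = 0)
  sv0 <- gen_survival(stats::setNames(stats::rnorm(50), paste0("p", 1:50)), cfg0)
  expect_true(all(sv0$event == 1))
  expect_error(gen_survival(c(a = 1, b = NaN), cfg0), "finite")

  ok <- 0
  for (i in 1:100) {
    cfg <- sim_config(seed = 700 + i, hazard_ratio = 3, censoring_fraction = 1/3)
    sc <- stats::setNames(stats::rnorm(60), sprintf("p%02d", 1:60))
    sv <- gen_survival(sc, cfg)
    fit <- survival::coxph(survival::Surv(time, event) ~ z,
                           data = data.frame(sv, z = as.vector(scale(sc))))
    ok <- ok + (abs(stats::coef(fit) - log(3)) < 0.5)
  }
  expect_gte(ok / 100, 0.8)
})

test_that("null hazard gives uniform one-tailed log-rank p-values", {
  ps <- vapply(1:200, function(i) {
    cfg <- sim_config(seed = 4000 + i, hazard_ratio = 1, censoring_fraction = 0.2)
    sc <- stats::setNames(stats::rnorm(40), sprintf("p%02d", 1:40))
    sv <- gen_survival(sc, cfg)
    scores <- data.frame(patient_id = names(sc), score = sc,
                         stratum = ifelse(sc > mean(sc), "high", "low"))
    km_logrank(scores, sv)$p_one_sided
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("cohort and Visium writers round-trip through disk", {
  cfg <- sim_config(seed = 8, n_patients_per_group = 2, rois_per_patient = 1,
                    cells_per_roi = 60, n_markers = 6, n_clusters = 3,
                    n_genes = 40, st_grid = c(8L, 8L), niche_radius = 2)
  co <- gen_imc_cohort(cfg)
  d <- withr::local_tempdir()
  write_imc_cohort(co, d)
  back <- read_imc_cells(file.path(d, "cells.tsv"))
  expect_equal(unname(back$intensities), unname(co$intensities),
               tolerance = 1e-8)
  st <- gen_st_cohort(cfg)
  write_visium(st$samples[[1]], file.path(d, "v1"))
  s2 <- read_visium(file.path(d, "v1"), "S_A_01", "groupA")
  expect_equal(unname(s2$counts), unname(st$samples[[1]]$counts))
  expect_equal(s2$coords$array_row, st$samples[[1]]$coords$array_row)
  # GMT round trip
  sets <- list(a = c("g1", "g2"), b = c("g3"))
  write_gmt(sets, file.path(d, "sets.gmt"))
  expect_equal(read_gmt(file.path(d, "sets.gmt")), sets)
})
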