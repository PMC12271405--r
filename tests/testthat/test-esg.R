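test_that("spot stratification takes the extreme deciles with stable ties", {
  set.seed(1)
  q <- seq_len(100)                     # monotone QCS
  s <- stratify_spots(q)
  expect_equal(s$high, 91:100)
  expect_equal(s$low, 1:10)
  expect_length(s$high, 10)
  expect_equal(eval(formals(stratify_spots)$top), 0.10)
  expect_error(stratify_spots(1:10), "at least 20")
  expect_error(stratify_spots(1:25, top = 0.6, bottom = 0.6), "overlap")
})

test_that("per-sample ESGs select genes up in high spots", {
  set.seed(2)
  n_spots <- 60
  counts <- matrix(rpois(40 * n_spots, 20), 40, n_spots,
                   dimnames = list(sprintf("g%02d", 1:40), NULL))
  high <- 1:10; low <- 51:60
  counts["g01", high] <- counts["g01", high] + 60   # up in high: selected
  counts["g02", low] <- counts["g02", low] + 60     # up in low: not selected
  coords <- data.frame(barcode = paste0("b", 1:n_spots), in_tissue = 1L,
                       array_row = 0:(n_spots - 1), array_col = 0L,
                       pxl_row_in_fullres = 0L, pxl_col_in_fullres = 0L)
  s <- normalize_st(st_sample("t", "groupA", counts, coords))
  esg <- per_sample_esg(s, high, low)
  expect_true("g01" %in% esg$gene)
  expect_false("g02" %in% esg$gene)
  expect_error(per_sample_esg(s, 1:3, low), "at least 5")
})

test_that("permuted strata select almost nothing", {
  picks <- 0
  for (i in 1:10) {
    set.seed(i)
    counts <- matrix(rpois(50 * 40, 15), 50, 40,
                     dimnames = list(sprintf("g%02d", 1:50), NULL))
    coords <- data.frame(barcode = paste0("b", 1:40), in_tissue = 1L,
                         array_row = 0:39, array_col = 0L,
                         pxl_row_in_fullres = 0L, pxl_col_in_fullres = 0L)
    s <- normalize_st(st_sample("t", "groupA", counts, coords))
    idx <- sample(40)
    picks <- picks + nrow(per_sample_esg(s, idx[1:6], idx[35:40]))
  }
  expect_lte(picks / 10, 0.05 * 50 * 2)
})

test_that("recurrence needs a strict majority of the focal group and dominance", {
  lists <- list(s1 = c("x", "y"), s2 = c("x"), s3 = c("x", "z"), s4 = "y",
                s5 = c("x", "y"), s6 = "q", s7 = "x", s8 = character(),
                s9 = "y", s10 = "x")
  groups <- rep(c("BA", "WA"), each = 5)
  es <- recurrent_esgs(lists, groups, focal = "BA")
  # x: 4/5 focal vs 2/5 other -> kept; y: 3/5 vs 1/5 -> kept; z: 1/5 -> no
  expect_setequal(es$recurrent, c("x", "y"))
  # 50% with equal fractions is dropped (strict dominance)
  l2 <- list(a = "g", b = "g", c = "q", d = "q", e = "g", f = "g")
  expect_length(recurrent_esgs(l2[1:4], c("BA", "BA", "WA", "WA"), "BA")$recurrent, 1)
  tie <- recurrent_esgs(list(a = "g", b = character(), c = "g", d = character()),
                        c("BA", "BA", "WA", "WA"), "BA")
  expect_length(tie$recurrent, 0)   # 1/2 vs 1/2: not strictly higher
})

test_that("recurrence equals brute-force enumeration and directions are disjoint", {
  for (i in 1:20) {
    set.seed(i)
    genes <- sprintf("g%02d", 1:15)
    lists <- lapply(1:8, function(j) sample(genes, sample(0:10, 1)))
    names(lists) <- paste0("s", 1:8)
    groups <- rep(c("A", "B"), each = 4)
    esA <- recurrent_esgs(lists, groups, "A")
    # brute force
    want <- character()
    for (g in genes) {
      fa <- mean(vapply(lists[1:4], function(l) g %in% l, TRUE))
      fb <- mean(vapply(lists[5:8], function(l) g %in% l, TRUE))
      if (fa >= 0.5 && fa > fb) want <- c(want, g)
    }
    expect_setequal(esA$recurrent, want)
    esB <- recurrent_esgs(lists, groups, "B")
    expect_length(intersect(esA$recurrent, esB$recurrent), 0)
  }
})

test_that("cell-type niche expression matches the hand oracle and is linear", {
  # 4 spots, 2 genes, 2 cell types
  ln <- matrix(c(1, 2, 3, 4,
                 2, 2, 4, 4), 2, 4, byrow = TRUE,
               dimnames = list(c("gA", "gB"), paste0("s", 1:4)))
  s <- make_st_from_normalized(ln)
  ref <- matrix(c(2, 5, 3, 1), 2, 2,
                dimnames = list(c("gA", "gB"), c("c1", "c2")))
  niche <- c(3, 4)
  out <- celltype_niche_expression(c("gA", "gB"), ref, s, niche)
  # hand: V(gA) = mean(3,4) - mean(1..4) = 1; V(gB) = 4 - 3 = 1
  expect_equal(unname(out$v), c(1, 1), tolerance = 1e-12)
  expect_equal(out$expr["gA", "c1"], 2 * 1, tolerance = 1e-12)
  expect_equal(out$expr["gB", "c2"], 1 * 1, tolerance = 1e-12)
  # niche mean equal to global mean: projection vanishes
  out0 <- celltype_niche_expression("gB", ref, s, c(1, 3))
  expect_equal(unname(out0$expr), matrix(0, 1, 2), tolerance = 1e-12)
  # doubling the reference doubles the projection
  out2 <- celltype_niche_expression(c("gA", "gB"), 2 * ref, s, niche)
  expect_equal(out2$expr, 2 * out$expr, tolerance = 1e-12)
  # gene measured in the sample but absent from the reference is omitted
  expect_message(celltype_niche_expression(c("gA", "gB"),
                                           ref["gA", , drop = FALSE], s, niche),
                 "omitted")
})

test_that("validation fold changes follow the log2 ratio and are antisymmetric", {
  libn <- matrix(c(4, 4, 2, 2,
                   3, 3, 3, 3), 2, 4, byrow = TRUE,
                 dimnames = list(c("up", "flat"), paste0("s", 1:4)))
  s <- make_st_from_normalized(log1p(libn))
  s$lognorm <- log1p(libn)
  lfc <- validation_lfc(s, high = 1:2, low = 3:4)
  expect_equal(unname(lfc["up"]), 1, tolerance = 1e-6)
  expect_equal(unname(lfc["flat"]), 0, tolerance = 1e-6)
  lfc_sw <- validation_lfc(s, high = 3:4, low = 1:2)
  expect_equal(lfc_sw, -lfc, tolerance = 1e-6)
})

test_that("paired group test on fold changes has one-sided power", {
  hits <- 0
  for (i in 1:100) {
    set.seed(i)
    lfcs <- cbind(matrix(rnorm(10 * 3, 0.5, 0.3), 10),   # focal samples
                  matrix(rnorm(10 * 3, 0.0, 0.3), 10))
    res <- validation_group_test(lfcs, rep(c("BA", "WA"), each = 3), "BA")
    hits <- hits + (res$p_value < 0.05)
  }
  expect_gte(hits / 100, 0.9)
})

test_that("region scores sum the gene set and ignore all-zero genes", {
  expr <- matrix(c(1, 2, 0, 3, 4, 0), 2, 3, byrow = TRUE,
                 dimnames = list(c("r1", "r2"), c("gA", "gB", "gZ")))
  expect_equal(unname(geomx_score(expr, "gA")), c(1, 3))
  expect_equal(geomx_score(expr, c("gA", "gB", "gZ")),
               geomx_score(expr, c("gA", "gB")))
  expect_error(geomx_score(expr, "absent"), "no genes")
  x <- geomx_score(expr, c("gA", "gB"))
  tstat <- compare_groups(c(x, x + 2), rep(c("a", "b"), each = 2), "t")$statistic
  hand <- (mean(x) - mean(x + 2)) / sqrt(var(x) / 2 + var(x + 2) / 2)
  expect_equal(tstat, hand, tolerance = 1e-12)
})

test_that("hypergeometric overlap matches direct tail summation", {
  p_pkg <- overlap_test(paste0("a", 1:20), c(paste0("a", 1:5), paste0("b", 1:25)),
                        universe_size = 1000)
  expect_equal(p_pkg$overlap, 5)
  # direct summation over the hypergeometric pmf
  direct <- sum(vapply(5:20, function(k)
    choose(20, k) * choose(980, 30 - k) / choose(1000, 30), 0))
  expect_equal(p_pkg$p_value, direct, tolerance = 1e-12)
  # disjoint small sets in a huge universe
  far <- overlap_test(paste0("x", 1:5), paste0("y", 1:5), 10000)
  expect_gt(far$p_value, 0.95)
  # complete overlap is the minimal attainable p for the configuration
  same <- overlap_test(paste0("a", 1:10), paste0("a", 1:10), 100)
  expect_equal(same$overlap, 10)
  expect_equal(same$p_value, 1 / choose(100, 10), tolerance = 1e-12)
  expect_error(overlap_test(paste0("a", 1:10), "b", 5), "universe")
})
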