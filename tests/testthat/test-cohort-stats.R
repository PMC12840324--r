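test_that("macro and micro recall differ exactly as the arithmetic says", {
  nodes <- tibble::tibble(
    scan_id = c(rep("a", 2), rep("b", 8)),
    sad_mm = rep(6, 10),
    sensitivity = c(rep(1, 2), rep(0, 8)),
    localized = c(TRUE, TRUE, rep(FALSE, 8)),
    metastatic = FALSE
  )
  sm <- tibble::tibble(
    scan_id = c("a", "b"), n_gt = c(2L, 8L), n_pred = c(2L, 0L),
    n_localized = c(2L, 0L), recall = c(1, 0), precision = c(1, NA),
    f1 = c(1, NA), fps = c(0L, 0L), fps_ge10 = c(0L, 0L),
    fp_sads_mm = list(numeric(0), numeric(0)),
    global_dice = c(1, NA), avg_hausdorff_mm = c(0, NA)
  )
  suppressWarnings(rep <- aggregate_cohort(nodes, sm))
  expect_equal(rep$summary$recall_macro, 0.5)
  expect_equal(rep$summary$recall_micro, 0.2)
  expect_error(aggregate_cohort(nodes, sm[0, ]), "empty")
})

test_that("stratified counts sum to totals and micro recall is the weighted mean", {
  set.seed(33)
  nodes <- tibble::tibble(
    scan_id = sample(paste0("s", 1:10), 400, TRUE),
    sad_mm = exp(rnorm(400, log(7), 0.6)),
    sensitivity = runif(400),
    metastatic = runif(400) < 0.2
  )
  nodes$localized <- nodes$sensitivity >= 0.4
  strata <- stratify_nodes(nodes)
  wide <- tidyr::pivot_wider(strata[, c("status", "sad_bin", "n_nodes")],
                             names_from = "status", values_from = "n_nodes")
  expect_equal(wide$all, wide$`non-mets` + wide$mets)
  per_bin <- strata[strata$status == "all" & strata$sad_bin != "all", ]
  total <- strata[strata$status == "all" & strata$sad_bin == "all", ]
  expect_equal(sum(per_bin$n_nodes), total$n_nodes)
  expect_equal(pooled_recall(per_bin$n_nodes, per_bin$recall), total$recall,
               tolerance = 1e-12)

  # the wide rendering preserves the sums
  tab <- render_cohort_table(strata)
  num <- tab[tab$measure == "number_of_nodes", ]
  expect_equal(num$all, rowSums(num[, c("<5", "5-10", "10-15", ">15")]))
})

test_that("Kruskal-Wallis wrapper matches the textbook statistic", {
  # ties-free 9-value example across three groups
  vals <- c(27, 2, 4, 18, 7, 9, 1, 22, 13)
  grp <- rep(c("a", "b", "c"), each = 3)
  res <- compare_groups_kw(vals, grp)
  expect_equal(res$statistic, kw_h_oracle(vals, grp), tolerance = 1e-12)
  expect_equal(res$p_value, 1 - pchisq(res$statistic, 2), tolerance = 1e-12)

  # identical group distributions: no evidence of a difference
  same <- compare_groups_kw(c(1:50, 1:50), rep(c("x", "y"), each = 50))
  expect_gt(same$p_value, 0.9)

  # strongly shifted groups are detected at alpha = 0.01
  set.seed(4)
  shifted <- compare_groups_kw(c(rnorm(100), rnorm(100, 5)),
                               rep(c("x", "y"), each = 100))
  expect_lt(shifted$p_value, 0.01)
  expect_true(shifted$significant)

  expect_error(compare_groups_kw(1:5, rep("a", 5)), "2 groups")
  expect_warning(res0 <- compare_groups_kw(c(1, 2, 3), c("a", "a", "b")),
                 "skipped")
  expect_equal(nrow(res0), 0)
})

test_that("post hoc pairwise comparisons isolate the deviant group", {
  set.seed(11)
  vals <- c(rnorm(160), rnorm(40, 6))
  grp <- c(rep(c("a", "b", "c", "d"), each = 40), rep("e", 40))
  ph <- posthoc_pairwise(vals, grp)
  expect_equal(nrow(ph), choose(5, 2))
  with_e <- grepl("e", ph$groups)
  expect_true(all(ph$significant[with_e]))
  expect_false(any(ph$significant[!with_e]))

  # four identical groups: nothing significant
  ph0 <- posthoc_pairwise(rep(1:25, 4), rep(c("a", "b", "c", "d"), each = 25))
  expect_false(any(ph0$significant))

  # Holm correction never lowers a p-value
  ph_h <- posthoc_pairwise(vals, grp, p_adjust = "holm")
  expect_true(all(ph_h$p_value >= ph$p_value - 1e-12))

  expect_error(posthoc_pairwise(1:10, rep(c("a", "b"), 5)), ">= 3 groups")
})

test_that("normality screen flags uniform data and passes normal data", {
  set.seed(2)
  u <- normality_screen(runif(500))
  expect_lt(u$p_value, 0.01)
  n <- normality_screen(rnorm(500))
  expect_gt(n$p_value, 0.01)
  # n > 5000 uses a deterministic subsample rather than failing
  big <- normality_screen(rnorm(8000))
  expect_equal(big$n, 5000L)
  expect_error(normality_screen(c(1, 2)), "n >= 3")
  expect_error(normality_screen(rep(1, 10)), "constant")
})

test_that("SAD-sensitivity correlation behaves on canonical inputs", {
  lin <- tibble::tibble(sad_mm = 1:20, sensitivity = seq(1, 0.05, length.out = 20))
  expect_equal(sad_sensitivity_correlation(lin)$statistic, -1)

  set.seed(9)
  ind <- tibble::tibble(sad_mm = runif(1000, 4, 30), sensitivity = runif(1000))
  expect_lt(abs(sad_sensitivity_correlation(ind)$statistic), 0.1)

  r10 <- sad_sensitivity_correlation(ind, sad_min = 10)
  expect_equal(r10$n, sum(ind$sad_mm > 10))

  expect_error(sad_sensitivity_correlation(
    tibble::tibble(sad_mm = rep(5, 10), sensitivity = runif(10))), "variance")
})

test_that("reference summary arithmetic is internally consistent", {
  ref <- hn_reference_summary()
  for (st in c("all", "non-mets", "mets")) {
    bins <- ref[ref$status == st & ref$sad_bin != "all", ]
    tot <- ref[ref$status == st & ref$sad_bin == "all", ]
    expect_equal(sum(bins$n_nodes), tot$n_nodes)
  }
  counts <- hn_reference_counts()
  audit <- audit_ground_truth(counts$initial_predictions, counts$rejected,
                              counts$added, counts$n_scans)
  expect_equal(audit$n_ground_truth,
               ref$n_nodes[ref$status == "all" & ref$sad_bin == "all"])
})
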