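# compact cohort for mechanics tests: the metastatic size maximum is
# lowered so the largest nodes still fit the reduced grid
small_cfg <- function(...) {
  cohort_config(n_scans = 2, nodes_per_scan_mean = 8,
                grid_dim = c(64, 64, 32), sad_max_mets = 22, ...)
}

test_that("generated nodes realise their sampled SADs", {
  cfg <- small_cfg()
  devs <- ok <- c()
  for (s in 1:6) {
    scan <- sample_gt_scan(cfg, s)
    counts <- table(scan$gen_nodes$node_id)
    solo <- as.integer(names(counts)[counts == 1])
    m <- merge(scan$gen_nodes[scan$gen_nodes$node_id %in% solo, ],
               scan$instances, by = "node_id")
    devs <- c(devs, m$sad_mm - m$target_sad_mm)
    ok <- c(ok, abs(m$sad_mm - m$target_sad_mm) <=
              ifelse(m$target_sad_mm >= 6, 1, 1.5) + 1e-9)
  }
  expect_true(all(ok))
  # every measured SAD clears the hard digitization floor
  expect_true(all(devs > -1.5))
})

test_that("the measured-SAD floor keeps all nodes above the size filter", {
  cfg <- small_cfg()
  for (s in 1:4) {
    scan <- sample_gt_scan(cfg, s)
    expect_true(all(scan$instances$sad_mm >= cfg$sad_floor_mm))
  }
})

test_that("clustered nodes merge into one instance by construction", {
  cfg <- small_cfg(cluster_probability = 1)
  scan <- sample_gt_scan(cfg, 5)
  expect_gt(nrow(scan$gen_nodes), 1)
  # every node chains onto the previous one, so the scan is one instance
  # (up to cluster placements that fell back to free placement)
  n_chained <- sum(scan$gen_nodes$clustered)
  expect_equal(nrow(scan$instances), nrow(scan$gen_nodes) - n_chained)
  expect_lt(nrow(scan$instances), nrow(scan$gen_nodes))
  # merged instance metadata is the union of its members
  merged <- scan$gen_nodes$node_id[duplicated(scan$gen_nodes$node_id)]
  for (id in unique(merged)) {
    members <- scan$gen_nodes[scan$gen_nodes$node_id == id, ]
    meta <- scan$instance_meta[scan$instance_meta$node_id == id, ]
    expect_equal(meta$metastatic, any(members$metastatic))
  }
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_cfg()
  a <- sample_gt_scan(cfg, 99)
  b <- sample_gt_scan(cfg, 99)
  expect_identical(a$gt$voxels, b$gt$voxels)
  expect_identical(a$gen_nodes, b$gen_nodes)
  co1 <- simulate_cohort(cfg, no_degradation(), seed = 7)
  co2 <- simulate_cohort(cfg, no_degradation(), seed = 7)
  expect_identical(co1$scans[[2]]$pred$voxels, co2$scans[[2]]$pred$voxels)
})

test_that("identity degradation reproduces the ground truth exactly", {
  scan <- sample_gt_scan(small_cfg(), 12)
  pred <- degrade_to_prediction(scan, no_degradation(), 3)
  expect_identical(pred$voxels, scan$gt$voxels)
  ev <- evaluate_scan(scan$gt, pred, meta = scan$instance_meta)
  expect_equal(ev$metrics$recall, 1)
  expect_equal(ev$metrics$global_dice, 1)
  expect_equal(ev$metrics$fps, 0)
  expect_equal(ev$metrics$avg_hausdorff_mm, 0)
})

test_that("certain miss empties the prediction", {
  scan <- sample_gt_scan(small_cfg(), 12)
  dcfg <- degradation_config(miss_probability = rep(1, 4), fp_rate = 0,
                             erosion_probability = 0, dilation_probability = 0)
  pred <- degrade_to_prediction(scan, dcfg, 3)
  expect_true(all(pred$voxels == 0L))
  ev <- evaluate_scan(scan$gt, pred, meta = scan$instance_meta)
  expect_equal(ev$metrics$recall, 0)
})

test_that("false positive counts follow the configured Poisson rate", {
  cfg <- small_cfg()
  dcfg <- degradation_config(miss_probability = rep(0, 4),
                             erosion_probability = 0,
                             dilation_probability = 0,
                             necrosis_dropout_probability = 0)
  fps <- vapply(1:40, function(s) {
    scan <- sample_gt_scan(cfg, 1000 + s)
    pred <- degrade_to_prediction(scan, dcfg, 2000 + s)
    ev <- evaluate_scan(scan$gt, pred)
    ev$metrics$fps
  }, numeric(1))
  se <- sqrt(6.5 / 40)
  expect_lt(abs(mean(fps) - 6.5), 3 * se)
})

test_that("analytic expectations mirror the configuration", {
  em <- expected_metrics(degradation_config())
  expect_equal(em$per_bin$expected_recall, c(0.72, 0.79, 0.67, 0.36))
  expect_equal(em$fps_per_scan, 6.5)
  em0 <- expected_metrics(no_degradation())
  expect_equal(em0$per_bin$expected_recall, rep(1, 4))
  expect_equal(em0$fps_per_scan, 0)
  em1 <- expected_metrics(degradation_config(
    miss_probability = c(0, 0.3, 0, 0), fp_rate = 0))
  expect_equal(em1$per_bin$expected_recall[2], 0.7)
})

test_that("a size-independent miss rate gives flat recall across bins", {
  cfg <- cohort_config(n_scans = 12)
  dcfg <- degradation_config(miss_probability = rep(0.25, 4), fp_rate = 0,
                             erosion_probability = 0, dilation_probability = 0,
                             necrosis_dropout_probability = 0)
  ev <- suppressWarnings(evaluate_cohort(simulate_cohort(cfg, dcfg, seed = 5)))
  bins <- ev$report$strata
  bins <- bins[bins$status == "all" & bins$sad_bin != "all", ]
  for (i in seq_len(nrow(bins))) {
    se <- sqrt(0.75 * 0.25 / bins$n_nodes[i])
    expect_lt(abs(bins$recall[i] - 0.75), max(3 * se, 0.02))
  }
  kw <- ev$report$stats$kw_recall_by_bin
  expect_false(kw$significant)
})

test_that("generated cohorts separate metastatic and non-metastatic sizes", {
  cfg <- cohort_config(n_scans = 8)
  ev <- suppressWarnings(evaluate_cohort(simulate_cohort(cfg, no_degradation(), seed = 3)))
  res <- compare_groups_kw(ev$nodes$sad_mm,
                           ifelse(ev$nodes$metastatic, "mets", "non-mets"))
  expect_lt(res$p_value, 0.01)
  # status-conditional means sit near their calibration targets
  expect_lt(abs(mean(ev$nodes$sad_mm[!ev$nodes$metastatic]) - 5.0), 0.6)
  expect_lt(abs(mean(ev$nodes$sad_mm[ev$nodes$metastatic]) - 11.3), 2.0)
})

test_that("a cohort written to disk evaluates identically to the in-memory one", {
  cfg <- small_cfg()
  co <- simulate_cohort(cfg, degradation_config(), seed = 21)
  dir <- tempfile("cohort_")
  write_synthetic_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_true(file.exists(file.path(dir, "config.json")))
  ev_mem <- suppressWarnings(evaluate_cohort(co))
  ev_dsk <- suppressWarnings(
    evaluate_cohort(file.path(dir, "gt"), file.path(dir, "pred"),
                    file.path(dir, "metadata.csv")))
  expect_equal(ev_dsk$scan_metrics$recall, ev_mem$scan_metrics$recall)
  expect_equal(ev_dsk$scan_metrics$global_dice, ev_mem$scan_metrics$global_dice)
  expect_equal(sum(ev_dsk$nodes$metastatic), sum(ev_mem$nodes$metastatic))
})
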