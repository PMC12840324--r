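test_that("per-node sensitivity is the covered voxel fraction", {
  # hand-built 6x6x3 pair: GT node of 10 voxels, 4 covered
  gt <- array(0L, c(6, 6, 3))
  gt[2:6, 2, 1] <- 1L   # 5 voxels
  gt[2:6, 2, 2] <- 1L   # 5 voxels
  pred <- array(0L, c(6, 6, 3))
  pred[2:5, 2, 1] <- 1L # covers 4 of 10
  gtv <- label_volume(gt, c(1, 1, 1), "instance")
  expect_equal(node_sensitivity(gtv, make_vol(pred)), 0.4)

  expect_equal(node_sensitivity(gtv, make_vol(gt)), 1.0)
  expect_equal(node_sensitivity(gtv, make_vol(array(0L, dim(gt)))), 0.0)
  expect_error(node_sensitivity(gtv, make_vol(array(0L, c(5, 6, 3)))),
               "mismatch")
})

test_that("localization uses sensitivity >= tau, boundary inclusive", {
  gt <- array(0L, c(6, 6, 3)); gt[2:6, 2, 1:2] <- 1L
  pred <- array(0L, c(6, 6, 3)); pred[2:5, 2, 1] <- 1L  # exactly 0.40
  loc <- localize_nodes(label_volume(gt, c(1, 1, 1), "instance"),
                        make_vol(pred), tau = 0.4)
  expect_equal(loc$sensitivity, 0.4)
  expect_true(loc$localized)

  none <- localize_nodes(label_volume(gt, c(1, 1, 1), "instance"),
                         make_vol(array(0L, dim(gt))))
  expect_false(any(none$localized))
})

test_that("prediction-side FP classification thresholds the GT overlap", {
  gt <- array(0L, c(10, 10, 3)); gt[2:5, 2:5, 1:2] <- 1L
  p <- array(0L, c(10, 10, 3))
  p[7:9, 7:9, 1] <- 1L                       # disjoint -> FP
  p[3:4, 3:4, 1] <- 2L                       # fully inside -> not FP
  pv <- label_volume(p, c(1, 1, 1), "instance")
  cls <- classify_predictions(pv, make_vol(gt))
  expect_equal(cls$is_fp, c(TRUE, FALSE))
  expect_equal(cls$gt_overlap_fraction, c(0, 1))

  # 50-voxel prediction with 20 on GT: fraction 0.40, not FP at default
  p2 <- array(0L, c(10, 10, 3))
  p2[1:10, 1:5, 3] <- 1L
  g2 <- array(0L, c(10, 10, 3))
  g2[1:10, 1:2, 3] <- 1L
  cls2 <- classify_predictions(label_volume(p2, c(1, 1, 1), "instance"),
                               make_vol(g2))
  expect_equal(cls2$gt_overlap_fraction, 0.4)
  expect_false(cls2$is_fp)
})

test_that("detection metrics combine counts the standard way", {
  expect_equal(round(f1_score(0.70, 0.73), 2), 0.71)
  expect_equal(f1_score(0, 0), 0)

  # constructed report: 10 GT, 7 localized; 11 predictions, 4 FPs
  match <- structure(list(
    per_gt = tibble::tibble(node_id = 1:10,
                            sensitivity = c(rep(0.9, 7), rep(0.1, 3)),
                            localized = c(rep(TRUE, 7), rep(FALSE, 3))),
    per_pred = tibble::tibble(pred_id = 1:11,
                              gt_overlap_fraction = c(rep(0.9, 7), rep(0, 4)),
                              is_fp = c(rep(FALSE, 7), rep(TRUE, 4))),
    tau_localize = 0.4, theta_fp = 0.4), class = "match_report")
  m <- scan_detection_metrics(match)
  expect_equal(m$recall, 0.7)
  expect_equal(m$precision, 7 / 11)
  expect_equal(m$f1, f1_score(0.7, 7 / 11))
  expect_equal(m$fps, 4)

  # corner conventions
  empty_match <- structure(list(
    per_gt = tibble::tibble(node_id = integer(), sensitivity = double(),
                            localized = logical()),
    per_pred = tibble::tibble(pred_id = integer(), gt_overlap_fraction = double(),
                              is_fp = logical()),
    tau_localize = 0.4, theta_fp = 0.4), class = "match_report")
  m0 <- scan_detection_metrics(empty_match)
  expect_equal(m0$recall, 1)
  expect_equal(m0$precision, 1)

  some_gt <- empty_match
  some_gt$per_gt <- tibble::tibble(node_id = 1L, sensitivity = 0,
                                   localized = FALSE)
  expect_true(is.na(scan_detection_metrics(some_gt)$precision))
})

test_that("perfect prediction yields perfect detection for any phantom", {
  for (seed in c(3, 9)) {
    m <- random_mask(c(15, 15, 8), 0.1, seed)
    gtv <- extract_instances(make_vol(m))$volume
    rep <- match_scan(gtv, gtv)
    expect_true(all(rep$per_gt$localized))
    expect_equal(sum(rep$per_pred$is_fp), 0)
    met <- scan_detection_metrics(rep)
    expect_equal(c(met$recall, met$precision, met$f1), c(1, 1, 1))
  }
})

test_that("growing the prediction never lowers any node's sensitivity", {
  set.seed(21)
  m <- random_mask(c(15, 15, 8), 0.12, 21)
  gtv <- extract_instances(make_vol(m))$volume
  pred <- random_mask(c(15, 15, 8), 0.08, 22)
  s0 <- node_sensitivity(gtv, make_vol(pred))
  grow <- pred
  grow[sample(which(grow == 0L), 150)] <- 1L
  s1 <- node_sensitivity(gtv, make_vol(grow))
  expect_true(all(s1 >= s0))
})

test_that("one bulky prediction can localize several ground-truth nodes", {
  gt <- array(0L, c(12, 12, 3))
  gt[2:4, 2:4, 1:2] <- 1L
  gt[8:10, 2:4, 1:2] <- 2L
  pred <- array(0L, c(12, 12, 3))
  pred[2:10, 2:4, 1:2] <- 1L   # single merged blob over both nodes
  gtv <- label_volume(gt, c(1, 1, 1), "instance")
  rep <- match_scan(gtv, label_volume(pred, c(1, 1, 1), "instance"))
  expect_true(all(rep$per_gt$localized))
  expect_equal(nrow(rep$per_pred), 1)
  expect_false(rep$per_pred$is_fp)
})
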