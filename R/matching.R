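#' Per-node sensitivity against a prediction foreground
#'
#' The sensitivity of a ground-truth node is the fraction of its voxels
#' covered by the predicted foreground, `|GT_i intersect Pred| / |GT_i|`.
#' It serves both as the localization criterion and as a continuous
#' per-node segmentation-quality measure; being GT-centric it stays
#' well-defined for bulky disease, where one merged prediction can cover
#' several ground-truth nodes.
#'
#' @param gt_volume Instance [label_volume] of ground-truth nodes.
#' @param pred_mask Binary [label_volume] of the (filtered) prediction, on
#'   the same grid.
#' @return Numeric vector of sensitivities, one per instance label `1..K`.
#' @export
node_sensitivity <- function(gt_volume, pred_mask) {
  stopifnot(inherits(gt_volume, "label_volume"), inherits(pred_mask, "label_volume"))
  assert_same_grid(gt_volume, pred_mask)
  k <- n_labels(gt_volume)
  if (k == 0L) return(numeric(0))
  tot <- tabulate(gt_volume$voxels, nbins = k)
  hit <- tabulate(gt_volume$voxels[pred_mask$voxels != 0L], nbins = k)
  hit / tot
}

#' Localize ground-truth nodes
#'
#' A node counts as localized when its sensitivity is greater than or equal
#' to `tau` (default 0.4); the boundary value itself counts as localized.
#'
#' @inheritParams node_sensitivity
#' @param tau Localization threshold on sensitivity.
#' @return Tibble with `node_id`, `sensitivity`, `localized`.
#' @export
localize_nodes <- function(gt_volume, pred_mask, tau = 0.4) {
  sens <- node_sensitivity(gt_volume, pred_mask)
  tibble::tibble(
    node_id = seq_along(sens),
    sensitivity = sens,
    localized = sens >= tau
  )
}

#' Classify predicted instances as matched or false positive
#'
#' For each predicted instance the fraction of its voxels lying on
#' ground-truth foreground is computed; an instance is a false positive
#' when that fraction is below `theta_fp`. The threshold defaults to 0.4,
#' symmetric with the localization rule, and is configurable.
#'
#' @param pred_volume Instance [label_volume] of (filtered) predictions.
#' @param gt_mask Binary [label_volume] of ground-truth foreground.
#' @param theta_fp Overlap-fraction threshold below which a prediction is
#'   a false positive.
#' @return Tibble with `pred_id`, `gt_overlap_fraction`, `is_fp`.
#' @export
classify_predictions <- function(pred_volume, gt_mask, theta_fp = 0.4) {
  stopifnot(inherits(pred_volume, "label_volume"), inherits(gt_mask, "label_volume"))
  assert_same_grid(pred_volume, gt_mask)
  k <- n_labels(pred_volume)
  if (k == 0L) {
    return(tibble::tibble(pred_id = integer(), gt_overlap_fraction = double(),
                          is_fp = logical()))
  }
  tot <- tabulate(pred_volume$voxels, nbins = k)
  hit <- tabulate(pred_volume$voxels[gt_mask$voxels != 0L], nbins = k)
  frac <- hit / tot
  tibble::tibble(
    pred_id = seq_len(k),
    gt_overlap_fraction = frac,
    is_fp = frac < theta_fp
  )
}

#' Match one scan's prediction against its ground truth
#'
#' Runs the GT-centric localization rule and the prediction-side false
#' positive classification for one scan and bundles the results. There is
#' no one-to-one assignment: overlap fractions, not bijective matches, are
#' evaluated, so a merged "bulky" prediction can localize several nodes.
#'
#' @param gt_volume Instance [label_volume] of ground-truth nodes.
#' @param pred_volume Instance [label_volume] of size-filtered predictions.
#' @param tau Localization threshold (sensitivity >= tau).
#' @param theta_fp False-positive threshold on prediction overlap fraction.
#' @return A `match_report`: list with `per_gt`, `per_pred` tibbles and the
#'   thresholds used.
#' @export
match_scan <- function(gt_volume, pred_volume, tau = 0.4, theta_fp = 0.4) {
  pred_mask <- binarize(pred_volume)
  gt_mask <- binarize(gt_volume)
  structure(
    list(
      per_gt = localize_nodes(gt_volume, pred_mask, tau = tau),
      per_pred = classify_predictions(pred_volume, gt_mask, theta_fp = theta_fp),
      tau_localize = tau,
      theta_fp = theta_fp
    ),
    class = "match_report"
  )
}

binarize <- function(vol) {
  label_volume(array(as.integer(vol$voxels != 0L), dim = dim(vol$voxels)),
               vol$spacing, "binary")
}

#' F1 score from recall and precision
#'
#' Harmonic mean of recall and precision, 0 when both are 0.
#'
#' @param recall,precision Values in `[0, 1]`.
#' @return F1 in `[0, 1]`.
#' @export
#' @examples
#' f1_score(0.70, 0.73)
f1_score <- function(recall, precision) {
  ifelse(recall + precision == 0, 0, 2 * recall * precision / (recall + precision))
}

#' Detection metrics for one scan
#'
#' Summarises a [match_scan()] report into recall (localized / ground-truth
#' nodes), precision (non-FP predictions / predictions), F1, and the false
#' positive count with its size distribution (including the count of FPs
#' >= 10 mm). With no predictions, precision is 1 on an empty scan
#' (nothing to find, nothing predicted) and missing (`NA`) otherwise;
#' recall mirrors that convention for scans without ground-truth nodes.
#'
#' @param match A `match_report` from [match_scan()].
#' @param pred_instances Optional tibble of prediction instances carrying
#'   `node_id` and `sad_mm`, used to report FP sizes.
#' @return One-row tibble: `n_gt`, `n_pred`, `n_localized`, `recall`,
#'   `precision`, `f1`, `fps`, `fps_ge10`, `fp_sads_mm` (list-column).
#' @export
scan_detection_metrics <- function(match, pred_instances = NULL) {
  n_gt <- nrow(match$per_gt)
  n_pred <- nrow(match$per_pred)
  n_loc <- sum(match$per_gt$localized)
  n_fp <- sum(match$per_pred$is_fp)
  recall <- if (n_gt > 0) n_loc / n_gt else if (n_pred == 0) 1 else NA_real_
  precision <- if (n_pred > 0) (n_pred - n_fp) / n_pred else if (n_gt == 0) 1 else NA_real_
  f1 <- if (is.na(recall) || is.na(precision)) NA_real_ else f1_score(recall, precision)
  fp_sads <- rep(NA_real_, n_fp)
  if (!is.null(pred_instances) && n_fp > 0) {
    fp_ids <- match$per_pred$pred_id[match$per_pred$is_fp]
    fp_sads <- pred_instances$sad_mm[base::match(fp_ids, pred_instances$node_id)]
  }
  tibble::tibble(
    n_gt = n_gt, n_pred = n_pred, n_localized = n_loc,
    recall = recall, precision = precision, f1 = f1,
    fps = n_fp, fps_ge10 = sum(fp_sads >= 10, na.rm = TRUE),
    fp_sads_mm = list(fp_sads)
  )
}
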