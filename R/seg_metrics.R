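#' Filter false positives and false negatives out of a mask pair
#'
#' Global segmentation metrics are computed on masks where detection errors
#' have been removed, so they measure segmentation quality where the model
#' found the node at all: missed (unlocalized) ground-truth instances are
#' dropped from the GT mask and false-positive instances from the
#' prediction mask.
#'
#' @param gt_volume Instance [label_volume] of ground-truth nodes.
#' @param pred_volume Instance [label_volume] of filtered predictions.
#' @param match A `match_report` from [match_scan()] for this pair.
#' @return List of binary [label_volume]s `gt` and `pred`.
#' @export
filtered_masks <- function(gt_volume, pred_volume, match) {
  keep_gt <- match$per_gt$node_id[match$per_gt$localized]
  keep_pred <- match$per_pred$pred_id[!match$per_pred$is_fp]
  list(
    gt = keep_labels(gt_volume, keep_gt),
    pred = keep_labels(pred_volume, keep_pred)
  )
}

keep_labels <- function(vol, ids) {
  keep <- vol$voxels %in% ids & vol$voxels != 0L
  label_volume(array(as.integer(keep), dim = dim(vol$voxels)),
               vol$spacing, "binary")
}

#' Global Dice coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)` over foreground voxels. Defined as 1
#' when both masks are empty and 0 when exactly one is.
#'
#' @param a,b Binary [label_volume]s on the same grid.
#' @return Dice in `[0, 1]`.
#' @export
global_dice <- function(a, b) {
  assert_same_grid(a, b)
  na <- sum(a$voxels != 0L)
  nb <- sum(b$voxels != 0L)
  if (na + nb == 0L) return(1)
  2 * sum(a$voxels != 0L & b$voxels != 0L) / (na + nb)
}

#' Average Hausdorff (symmetric mean surface) distance in mm
#'
#' Implemented as the symmetric average surface distance between the two
#' masks' boundary-voxel centre sets: the mean, over boundary voxels of A,
#' of the Euclidean distance in mm to the nearest boundary voxel of B,
#' averaged with the reverse direction. A boundary voxel is a foreground
#' voxel with at least one background 6-neighbour (the volume face counts
#' as background). Distances use the native anisotropic spacing, never
#' voxel units. Directed variants are available; the maximum (classical
#' Hausdorff) is deliberately not the default, since node evaluation uses
#' the averaged form.
#'
#' @param a,b Binary [label_volume]s on the same grid.
#' @param variant `"symmetric_mean"` (default), `"directed_a_to_b"` or
#'   `"directed_b_to_a"`.
#' @return Distance in mm; `NA` with a warning when either mask is empty.
#' @export
average_hausdorff <- function(a, b,
                              variant = c("symmetric_mean", "directed_a_to_b",
                                          "directed_b_to_a")) {
  variant <- match.arg(variant)
  assert_same_grid(a, b)
  if (all(a$voxels == 0L) || all(b$voxels == 0L)) {
    warning("average Hausdorff undefined for an empty mask; returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  dims <- dim(a$voxels)
  bnd_a <- boundary_voxels_cpp(as.vector(a$voxels), dims)
  bnd_b <- boundary_voxels_cpp(as.vector(b$voxels), dims)
  d_ab <- mean(sqrt(edt_squared_cpp(bnd_b, dims, a$spacing)[bnd_a]))
  if (variant == "directed_a_to_b") return(d_ab)
  d_ba <- mean(sqrt(edt_squared_cpp(bnd_a, dims, a$spacing)[bnd_b]))
  if (variant == "directed_b_to_a") return(d_ba)
  (d_ab + d_ba) / 2
}

#' Segmentation metrics for one scan
#'
#' Convenience wrapper: filters FPs/FNs per the match report, then computes
#' the global Dice and average Hausdorff distance on the filtered pair.
#'
#' @inheritParams filtered_masks
#' @param hausdorff_variant Passed to [average_hausdorff()].
#' @return One-row tibble `global_dice`, `avg_hausdorff_mm`.
#' @export
scan_segmentation_metrics <- function(gt_volume, pred_volume, match,
                                      hausdorff_variant = "symmetric_mean") {
  fm <- filtered_masks(gt_volume, pred_volume, match)
  empty <- all(fm$gt$voxels == 0L) || all(fm$pred$voxels == 0L)
  tibble::tibble(
    global_dice = global_dice(fm$gt, fm$pred),
    avg_hausdorff_mm = if (empty) NA_real_ else
      average_hausdorff(fm$gt, fm$pred, variant = hausdorff_variant)
  )
}
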