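#' Extract node instances from a binary mask
#'
#' Connected-component analysis of the foreground, the post-processing step
#' that turns a binary node mask into individual node instances. Touching
#' nodes (bulky disease) form one instance by construction. Components are
#' labelled consecutively `1..K` in deterministic raster-scan order.
#'
#' @param mask A binary [label_volume].
#' @param connectivity Voxel neighbourhood: 6 (faces), 18 (faces+edges) or
#'   26 (faces+edges+corners, the default — the most permissive merging, so
#'   diagonally touching nodes are a single instance).
#' @param sad_method Short-axis estimator passed to [compute_sad()].
#' @return List with `volume` (an instance [label_volume]) and `instances`,
#'   a tibble with one row per instance: `node_id`, `voxel_count`,
#'   `volume_mm3`, `sad_mm`, `centroid_x_mm`, `centroid_y_mm`,
#'   `centroid_z_mm`.
#' @export
#' @examples
#' vox <- array(0L, c(12, 12, 6))
#' vox[2:4, 2:4, 2:4] <- 1L
#' vox[8:10, 8:10, 2:4] <- 1L
#' ext <- extract_instances(label_volume(vox, c(1, 1, 2)))
#' ext$instances
extract_instances <- function(mask, connectivity = c(26, 6, 18),
                              sad_method = "caliper") {
  stopifnot(inherits(mask, "label_volume"))
  if (mask$kind != "binary") stop("`mask` must be a binary volume", call. = FALSE)
  connectivity <- match.arg(as.character(connectivity[1]), c("26", "6", "18"))
  connectivity <- as.integer(connectivity)

  lab <- label_components_cpp(as.vector(mask$voxels), dim(mask$voxels),
                              connectivity)
  k <- attr(lab, "n_components")
  lab_arr <- array(as.integer(lab), dim = dim(mask$voxels))
  vol <- label_volume(lab_arr, mask$spacing, "instance")
  if (k == 0L) {
    return(list(volume = vol, instances = empty_instance_table()))
  }
  sp <- mask$spacing
  vox_mm3 <- prod(sp)
  coords <- coords_by_label(vol)
  inst <- purrr::map_dfr(seq_len(k), function(id) {
    cc <- coords[[id]]
    ctr <- colMeans(cc) * sp
    tibble::tibble(
      node_id = id,
      voxel_count = nrow(cc),
      volume_mm3 = nrow(cc) * vox_mm3,
      sad_mm = compute_sad(cc, sp, method = sad_method),
      centroid_x_mm = ctr[1], centroid_y_mm = ctr[2], centroid_z_mm = ctr[3]
    )
  })
  list(volume = vol, instances = inst)
}

empty_instance_table <- function() {
  tibble::tibble(
    node_id = integer(), voxel_count = integer(), volume_mm3 = double(),
    sad_mm = double(), centroid_x_mm = double(), centroid_y_mm = double(),
    centroid_z_mm = double()
  )
}

# 0-based voxel index matrices, one per instance label.
coords_by_label <- function(vol) {
  idx <- which(vol$voxels != 0L, arr.ind = TRUE) - 1L
  labs <- vol$voxels[vol$voxels != 0L]
  lapply(seq_len(n_labels(vol)), function(id) {
    m <- idx[labs == id, , drop = FALSE]
    colnames(m) <- c("x", "y", "z")
    m
  })
}

#' Short-axis diameter of one node instance
#'
#' RECIST 1.1 measures nodal lesions by their short-axis diameter (SAD) on
#' the axial plane. The mask-based estimator used here mirrors the manual
#' caliper measurement: for every axial slice the instance occupies, the
#' slice's long axis is the maximal point-pair distance over in-plane voxel
#' centres (max caliper), and the slice's short axis is the maximal extent
#' of the slice perpendicular to that long-axis direction. The SAD is the
#' maximum of the per-slice short axes over slices.
#'
#' Centre-to-centre extents underestimate physical extents by one voxel, so
#' one in-plane voxel dimension is added to the perpendicular extent: a
#' single voxel then measures one in-plane voxel and a digital sphere of
#' diameter d measures d within one in-plane voxel, for any slice spacing.
#' The result is floored at one in-plane voxel dimension.
#'
#' Two alternative estimators are available and documented as non-canonical:
#' `"min_feret"` (minimal caliper width over hull edge directions) and
#' `"ellipse"` (moment-matched ellipse minor diameter), both per-slice and
#' maximised over slices in the same way.
#'
#' @param coords Integer matrix of 0-based voxel indices, columns (x, y, z).
#' @param spacing Voxel spacing `(sx, sy, sz)` in mm.
#' @param method `"caliper"` (default), `"min_feret"` or `"ellipse"`.
#' @return SAD in mm (positive scalar).
#' @export
compute_sad <- function(coords, spacing, method = c("caliper", "min_feret", "ellipse")) {
  method <- match.arg(method)
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  if (nrow(coords) == 0L) stop("empty instance", call. = FALSE)
  sx <- spacing[1]; sy <- spacing[2]
  floor_mm <- min(sx, sy)
  per_slice <- vapply(split.data.frame(coords, coords[, 3]), function(cc) {
    slice_short_axis(cc[, 1] * sx, cc[, 2] * sy, sx, sy, method)
  }, numeric(1))
  max(max(per_slice), floor_mm)
}

slice_short_axis <- function(px, py, sx, sy, method) {
  pts <- unique(cbind(px, py))
  if (nrow(pts) == 1L) return(min(sx, sy))
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  if (method == "ellipse") {
    if (nrow(pts) < 3L) return(min(sx, sy))
    ev <- eigen(stats::cov(cbind(px, py)), symmetric = TRUE, only.values = TRUE)$values
    return(max(4 * sqrt(max(ev[2], 0)), min(sx, sy)))
  }
  if (method == "min_feret") return(min_feret_width(hull, sx, sy))
  # caliper: direction of the maximal point-pair distance, first pair wins ties
  d2 <- as.matrix(stats::dist(hull))^2
  ij <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  dir <- hull[ij[2], ] - hull[ij[1], ]
  dir <- dir / sqrt(sum(dir^2))
  nrm <- c(-dir[2], dir[1])
  proj <- hull %*% nrm
  max(proj) - min(proj) + min(sx, sy)
}

min_feret_width <- function(hull, sx, sy) {
  n <- nrow(hull)
  if (n == 2L) return(min(sx, sy))
  widths <- vapply(seq_len(n), function(i) {
    e <- hull[if (i == n) 1L else i + 1L, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    nrm <- c(-e[2], e[1]) / len
    proj <- hull %*% nrm
    (max(proj) - min(proj)) + min(sx, sy)
  }, numeric(1))
  min(widths)
}

#' Remove too-small predicted instances
#'
#' Predicted instances with a SAD below `min_sad_mm` (default 4.5 mm) are
#' removed from the prediction mask before any matching or metric is
#' computed; the boundary value itself is retained (the rule removes
#' strictly smaller instances).
#'
#' @param instances Instance tibble from [extract_instances()] (needs
#'   `node_id` and `sad_mm`).
#' @param volume The matching instance [label_volume].
#' @param min_sad_mm Size threshold in mm.
#' @return List with `mask` (filtered binary [label_volume]), `volume`
#'   (relabelled instance volume), `instances` (retained rows, relabelled
#'   consecutively) and `removed` (the dropped rows with original ids).
#' @export
filter_small_predictions <- function(instances, volume, min_sad_mm = 4.5) {
  keep <- instances$sad_mm >= min_sad_mm
  removed <- instances[!keep, , drop = FALSE]
  kept <- instances[keep, , drop = FALSE]
  old_ids <- kept$node_id
  vox <- array(match(volume$voxels, old_ids, nomatch = 0L), dim = dim(volume$voxels))
  storage.mode(vox) <- "integer"
  kept$node_id <- seq_len(nrow(kept))
  list(
    mask = label_volume(array(as.integer(vox > 0L), dim = dim(vox)),
                        volume$spacing, "binary"),
    volume = label_volume(vox, volume$spacing, "instance"),
    instances = kept,
    removed = removed
  )
}

#' Assign RECIST-style SAD size bins
#'
#' Bins are left-closed/right-open on the default edges (5, 10, 15) mm:
#' `[0,5)`, `[5,10)`, `[10,15)`, `[15,Inf)`, labelled `"<5"`, `"5-10"`,
#' `"10-15"`, `">15"`.
#'
#' @param sad_mm Positive SAD values in mm.
#' @param bin_edges Increasing positive break points in mm.
#' @return Ordered factor of bin labels.
#' @export
#' @examples
#' assign_sad_bin(c(4.9, 5, 11.3, 57.9))
assign_sad_bin <- function(sad_mm, bin_edges = c(5, 10, 15)) {
  if (any(!is.finite(sad_mm) | sad_mm <= 0)) {
    stop("SAD values must be positive and finite", call. = FALSE)
  }
  labels <- sad_bin_labels(bin_edges)
  cut(sad_mm, breaks = c(0, bin_edges, Inf), labels = labels,
      right = FALSE, ordered_result = TRUE)
}

sad_bin_labels <- function(bin_edges = c(5, 10, 15)) {
  e <- bin_edges
  c(paste0("<", e[1]),
    if (length(e) > 1) paste0(e[-length(e)], "-", e[-1]),
    paste0(">", e[length(e)]))
}
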