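#' Construct a label volume
#'
#' A `label_volume` is the package's container for one co-registered 3D mask:
#' a 3D integer array of voxel labels together with its anisotropic voxel
#' spacing in mm. Axes are ordered (x, y, z) with axis 3 the axial (slice)
#' axis, matching on-disk NIfTI storage order. Voxel indices are 0-based in
#' physical terms: the centre of voxel `(i, j, k)` (1-based R indices) sits at
#' `((i-1)*sx, (j-1)*sy, (k-1)*sz)` mm. No resampling is ever performed; all
#' downstream distances and diameters carry the native spacing.
#'
#' Two kinds are distinguished: `"binary"` volumes contain only \{0, 1\}
#' (foreground masks), `"instance"` volumes use consecutive positive labels
#' `1..K` identifying individual node instances.
#'
#' @param voxels 3D integer array (or something coercible), all values >= 0.
#' @param spacing Numeric length-3 vector `(sx, sy, sz)` in mm, all > 0.
#' @param kind `"binary"` or `"instance"`.
#' @return A `label_volume` object.
#' @export
#' @examples
#' vox <- array(0L, c(8, 8, 4))
#' vox[3:5, 3:5, 2:3] <- 1L
#' label_volume(vox, spacing = c(1, 1, 2), kind = "binary")
label_volume <- function(voxels, spacing, kind = c("binary", "instance")) {
  kind <- match.arg(kind)
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array", call. = FALSE)
  }
  if (any(dim(voxels) < 1L)) stop("grid shape must be >= (1,1,1)", call. = FALSE)
  storage.mode(voxels) <- "integer"
  if (anyNA(voxels)) stop("`voxels` contains NA", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three strictly positive values in mm", call. = FALSE)
  }
  validate_labels(voxels, kind)
  structure(
    list(voxels = voxels, spacing = spacing, kind = kind),
    class = "label_volume"
  )
}

validate_labels <- function(voxels, kind) {
  vals <- voxels[voxels != 0L]
  if (length(vals) == 0L) return(invisible(TRUE))
  if (min(vals) < 0L) stop("labels must be >= 0", call. = FALSE)
  if (kind == "binary" && max(vals) > 1L) {
    stop("binary volume contains labels other than {0, 1}", call. = FALSE)
  }
  if (kind == "instance") {
    u <- sort(unique(as.vector(vals)))
    if (!identical(u, seq_len(max(u)))) {
      stop("instance labels must be consecutive 1..K; found {",
           paste(u, collapse = ", "), "}", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<label_volume [%s]> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$kind, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  n_fg <- sum(x$voxels != 0L)
  if (x$kind == "instance") {
    cat(sprintf("  %d foreground voxels in %d instance(s)\n",
                n_fg, n_labels(x)))
  } else {
    cat(sprintf("  %d foreground voxels\n", n_fg))
  }
  invisible(x)
}

n_labels <- function(vol) {
  if (all(vol$voxels == 0L)) 0L else max(vol$voxels)
}

#' @export
dim.label_volume <- function(x) dim(x$voxels)

assert_same_grid <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels))) {
    stop("grid shape mismatch: (", paste(dim(a$voxels), collapse = "x"),
         ") vs (", paste(dim(b$voxels), collapse = "x"), ")", call. = FALSE)
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-4) {
    stop("voxel spacing mismatch between volumes", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a 3D label mask from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` file as a [label_volume], taking the voxel
#' spacing from the header `pixdim`. Voxel values are taken as stored:
#' no resampling, no thresholding. Values are validated against the
#' expected kind; an instance file with non-consecutive labels is rejected
#' unless `relabel = TRUE`, in which case labels are remapped to `1..K`
#' preserving order.
#'
#' @param path Path to a 3D NIfTI file.
#' @param expected_kind `"binary"` or `"instance"`.
#' @param relabel For instance volumes, remap non-consecutive labels to
#'   consecutive `1..K` instead of rejecting the file.
#' @return A [label_volume].
#' @export
load_label_volume <- function(path, expected_kind = c("binary", "instance"),
                              relabel = FALSE) {
  expected_kind <- match.arg(expected_kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) {
    arr <- arr[, , , 1, drop = TRUE]
  }
  if (length(dim(arr)) != 3L) {
    stop("expected a 3D image, got ", length(dim(arr)), " dimensions: ", path,
         call. = FALSE)
  }
  if (max(abs(arr - round(arr))) > 0) {
    stop("non-integer voxel values in ", path, call. = FALSE)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(spacing <= 0)) stop("non-positive voxel spacing in header: ", path,
                              call. = FALSE)
  arr <- array(as.integer(round(arr)), dim = dim(arr))
  if (expected_kind == "instance" && relabel) {
    u <- sort(unique(arr[arr != 0L]))
    if (length(u) > 0L && !identical(u, seq_along(u))) {
      arr <- array(match(arr, u, nomatch = 0L), dim = dim(arr))
      storage.mode(arr) <- "integer"
    }
  }
  label_volume(arr, spacing, expected_kind)
}

#' Write a label volume to NIfTI
#'
#' The written file round-trips through [load_label_volume()] bit-exactly
#' in voxel values, and the spacing survives to header precision.
#'
#' @param vol A [label_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read per-node metastatic status metadata
#'
#' Metadata travels as a CSV with columns `scan_id`, `node_id`,
#' `metastatic` (0/1 or logical), one row per ground-truth node instance.
#' The flag records the clinical adjudication of each node (necrosis,
#' PET positivity, histology, or chemotherapy response). Optional extra
#' columns (e.g. `necrotic` in synthetic cohorts) are carried through.
#'
#' @param path CSV file path.
#' @return Tibble with `scan_id` (character), `node_id` (integer),
#'   `metastatic` (logical), plus any extra columns.
#' @export
load_node_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("scan_id", "node_id", "metastatic")
  missing_cols <- setdiff(req, names(meta))
  if (length(missing_cols) > 0) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta[c("scan_id", "node_id")]) > 0) {
    stop("duplicate (scan_id, node_id) rows in metadata", call. = FALSE)
  }
  dplyr::mutate(
    meta,
    scan_id = as.character(.data$scan_id),
    node_id = as.integer(.data$node_id),
    metastatic = as.logical(.data$metastatic)
  )
}

#' Align metadata with the instances found in a ground-truth mask
#'
#' Instance ids present in the mask but absent from the metadata default to
#' non-metastatic with a warning; metadata rows with no matching instance
#' are dropped with a warning.
#'
#' @param meta Tibble from [load_node_metadata()] (or equivalent), already
#'   restricted to one scan.
#' @param node_ids Integer instance ids present in the mask.
#' @return Tibble with one row per element of `node_ids`.
#' @export
align_node_metadata <- function(meta, node_ids) {
  node_ids <- as.integer(node_ids)
  extra <- setdiff(meta$node_id, node_ids)
  if (length(extra) > 0) {
    warning("metadata rows for absent instance id(s) ignored: ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(node_ids, meta$node_id)
  if (length(absent) > 0) {
    warning("no metadata for instance id(s) ",
            paste(absent, collapse = ", "),
            "; defaulting to non-metastatic", call. = FALSE)
  }
  out <- dplyr::left_join(tibble::tibble(node_id = node_ids),
                          dplyr::select(meta, -dplyr::any_of("scan_id")),
                          by = "node_id")
  dplyr::mutate(out, metastatic = dplyr::coalesce(.data$metastatic, FALSE))
}
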