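#' Evaluation configuration
#'
#' All thresholds of the evaluation pipeline in one place, with the
#' canonical defaults: predictions under 4.5 mm SAD are discarded, a node
#' is localized at sensitivity >= 0.4, a prediction is a false positive
#' below 0.4 overlap fraction, SAD bins break at 5/10/15 mm, tests run at
#' alpha = 0.01, components connect at 26-neighbourhood.
#'
#' @param min_pred_sad_mm Prediction size filter threshold (mm).
#' @param tau_localize Localization threshold on per-node sensitivity.
#' @param theta_fp False-positive threshold on prediction overlap fraction.
#' @param sad_bin_edges SAD bin edges (mm).
#' @param alpha Significance level for cohort statistics.
#' @param connectivity 6, 18 or 26.
#' @param hausdorff_variant Passed to [average_hausdorff()].
#' @param sad_method Passed to [compute_sad()].
#' @return An `eval_config` list.
#' @export
eval_config <- function(min_pred_sad_mm = 4.5, tau_localize = 0.4,
                        theta_fp = 0.4, sad_bin_edges = c(5, 10, 15),
                        alpha = 0.01, connectivity = 26,
                        hausdorff_variant = "symmetric_mean",
                        sad_method = "caliper") {
  structure(
    list(min_pred_sad_mm = min_pred_sad_mm, tau_localize = tau_localize,
         theta_fp = theta_fp, sad_bin_edges = sad_bin_edges, alpha = alpha,
         connectivity = connectivity, hausdorff_variant = hausdorff_variant,
         sad_method = sad_method),
    class = "eval_config"
  )
}

#' Evaluate one scan's prediction against its ground truth
#'
#' Runs the per-scan pipeline in its fixed order: extract ground-truth and
#' prediction instances (connected components), measure SADs, remove
#' too-small predictions, match (GT-centric localization + FP
#' classification), compute detection metrics, then the FP/FN-filtered
#' global Dice and average Hausdorff distance.
#'
#' @param gt Binary ground-truth [label_volume] (or path to a NIfTI file).
#' @param pred Binary prediction [label_volume] (or path).
#' @param meta Optional per-node metadata tibble for this scan (columns
#'   `node_id`, `metastatic`, ...); missing nodes default to
#'   non-metastatic.
#' @param config An [eval_config()].
#' @param scan_id Identifier carried into the result tables.
#' @return A `scan_eval`: list with `nodes` (per-GT-node tibble:
#'   `sad_mm`, `sad_bin`, `metastatic`, `sensitivity`, `localized`, ...),
#'   `predictions` (per-prediction tibble with `gt_overlap_fraction`,
#'   `is_fp`), and `metrics` (one-row tibble).
#' @export
evaluate_scan <- function(gt, pred, meta = NULL, config = eval_config(),
                          scan_id = "scan") {
  if (is.character(gt)) gt <- load_label_volume(gt, "binary")
  if (is.character(pred)) pred <- load_label_volume(pred, "binary")
  assert_same_grid(gt, pred)

  gt_ext <- extract_instances(gt, connectivity = config$connectivity,
                              sad_method = config$sad_method)
  pred_ext <- extract_instances(pred, connectivity = config$connectivity,
                                sad_method = config$sad_method)
  pred_flt <- filter_small_predictions(pred_ext$instances, pred_ext$volume,
                                       min_sad_mm = config$min_pred_sad_mm)

  match <- match_scan(gt_ext$volume, pred_flt$volume,
                      tau = config$tau_localize, theta_fp = config$theta_fp)
  det <- scan_detection_metrics(match, pred_instances = pred_flt$instances)
  seg <- scan_segmentation_metrics(gt_ext$volume, pred_flt$volume, match,
                                   hausdorff_variant = config$hausdorff_variant)

  nodes <- gt_ext$instances |>
    dplyr::left_join(match$per_gt, by = "node_id") |>
    dplyr::mutate(
      sad_bin = assign_sad_bin(.data$sad_mm, config$sad_bin_edges),
      scan_id = scan_id, .before = 1
    )
  if (!is.null(meta) && nrow(meta) > 0) {
    nodes <- dplyr::left_join(nodes, align_node_metadata(meta, nodes$node_id),
                              by = "node_id")
    nodes$metastatic <- dplyr::coalesce(nodes$metastatic, FALSE)
  } else {
    nodes$metastatic <- FALSE
  }
  preds <- pred_flt$instances |>
    dplyr::rename(pred_id = "node_id") |>
    dplyr::left_join(match$per_pred, by = "pred_id") |>
    dplyr::mutate(scan_id = scan_id, .before = 1)

  structure(
    list(
      scan_id = scan_id,
      nodes = nodes,
      predictions = preds,
      removed_predictions = pred_flt$removed,
      metrics = dplyr::bind_cols(tibble::tibble(scan_id = scan_id), det, seg),
      config = config
    ),
    class = "scan_eval"
  )
}

#' @export
print.scan_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<scan_eval '%s'> %d GT node(s), %d filtered prediction(s)\n",
              x$scan_id, m$n_gt, m$n_pred))
  cat(sprintf("  recall %.2f, precision %.2f, F1 %.2f, %d FP(s)\n",
              m$recall, m$precision, m$f1, m$fps))
  cat(sprintf("  filtered Dice %.3f, avg Hausdorff %.2f mm\n",
              m$global_dice, m$avg_hausdorff_mm))
  invisible(x)
}

#' Evaluate a whole cohort
#'
#' Maps [evaluate_scan()] over paired scans and aggregates the results
#' with [aggregate_cohort()]. Input is either an in-memory
#' `synthetic_cohort` from [simulate_cohort()], or directories of paired
#' NIfTI files plus a metadata CSV (files are paired by basename; an
#' unpaired scan is an error naming it).
#'
#' @param x A `synthetic_cohort`, or a ground-truth directory path.
#' @param pred_dir,metadata_csv With a directory `x`: prediction directory
#'   and metadata CSV path.
#' @param config An [eval_config()].
#' @param recall_test_unit Passed to [aggregate_cohort()].
#' @return A `cohort_eval`: list with `nodes`, `predictions`,
#'   `scan_metrics`, `report` (a `cohort_report`), and `config`.
#' @export
evaluate_cohort <- function(x, pred_dir = NULL, metadata_csv = NULL,
                            config = eval_config(),
                            recall_test_unit = "node") {
  if (inherits(x, "synthetic_cohort")) {
    evals <- lapply(x$scans, function(s) {
      evaluate_scan(s$gt$gt, s$pred, meta = s$gt$instance_meta,
                    config = config, scan_id = s$scan_id)
    })
  } else {
    stopifnot(is.character(x), !is.null(pred_dir))
    gt_files <- sort(list.files(x, pattern = "\\.nii(\\.gz)?$", full.names = TRUE))
    if (length(gt_files) == 0) stop("no NIfTI files in ", x, call. = FALSE)
    meta_all <- if (!is.null(metadata_csv)) load_node_metadata(metadata_csv) else NULL
    evals <- lapply(gt_files, function(f) {
      id <- sub("\\.nii(\\.gz)?$", "", basename(f))
      pf <- file.path(pred_dir, basename(f))
      if (!file.exists(pf)) {
        pf2 <- file.path(pred_dir, paste0(id, ".nii"))
        if (file.exists(pf2)) pf <- pf2
        else stop("missing prediction file for scan '", id, "'", call. = FALSE)
      }
      meta <- if (!is.null(meta_all)) dplyr::filter(meta_all, .data$scan_id == id)
      evaluate_scan(f, pf, meta = meta, config = config, scan_id = id)
    })
  }
  nodes <- purrr::map_dfr(evals, "nodes")
  preds <- purrr::map_dfr(evals, "predictions")
  scan_metrics <- purrr::map_dfr(evals, "metrics")
  report <- aggregate_cohort(nodes, scan_metrics,
                             bin_edges = config$sad_bin_edges,
                             alpha = config$alpha,
                             recall_test_unit = recall_test_unit)
  structure(
    list(nodes = nodes, predictions = preds, scan_metrics = scan_metrics,
         report = report, config = config),
    class = "cohort_eval"
  )
}

#' @export
print.cohort_eval <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Scatter data relating node size to segmentation sensitivity
#'
#' One row per ground-truth node with a defined sensitivity (all nodes,
#' including unlocalized ones, whose sensitivity is below the threshold):
#' the data behind the SAD-vs-sensitivity analysis.
#'
#' @param x A `cohort_eval`.
#' @param localized_only Restrict to localized nodes.
#' @return Tibble `scan_id`, `node_id`, `sad_mm`, `sensitivity`,
#'   `localized`, `metastatic`.
#' @export
sad_sensitivity_data <- function(x, localized_only = FALSE) {
  stopifnot(inherits(x, "cohort_eval"))
  out <- dplyr::select(x$nodes, "scan_id", "node_id", "sad_mm",
                       "sensitivity", "localized", "metastatic")
  if (localized_only) out <- dplyr::filter(out, .data$localized)
  out
}

#' Write evaluation reports to disk
#'
#' Emits the per-scan metrics (`scan_metrics.json` and `.csv`), the
#' per-node table (`nodes.csv`), the stratified cohort table
#' (`cohort_table.csv`, wide layout), the SAD-sensitivity scatter data
#' (`sad_sensitivity.csv`), the statistical test results (`stats.json`)
#' the cohort summary (`cohort_summary.json`) and the evaluation
#' configuration (`config.json`), so every threshold in any report is
#' traceable to the config written beside it. Undefined metrics are
#' emitted as JSON nulls / empty CSV cells, never zeros.
#'
#' @param x A `cohort_eval`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort_report <- function(x, out_dir) {
  stopifnot(inherits(x, "cohort_eval"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sm <- dplyr::mutate(x$scan_metrics,
                      fp_sads_mm = purrr::map_chr(.data$fp_sads_mm, function(v)
                        paste(round(v, 2), collapse = ";")))
  readr::write_csv(sm, file.path(out_dir, "scan_metrics.csv"), na = "")
  jsonlite::write_json(x$scan_metrics, file.path(out_dir, "scan_metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  readr::write_csv(dplyr::select(x$nodes, -dplyr::any_of("fp_sads_mm")),
                   file.path(out_dir, "nodes.csv"), na = "")
  readr::write_csv(render_cohort_table(x$report),
                   file.path(out_dir, "cohort_table.csv"), na = "")
  readr::write_csv(sad_sensitivity_data(x),
                   file.path(out_dir, "sad_sensitivity.csv"), na = "")
  jsonlite::write_json(x$report$stats, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(
    c(as.list(x$report$summary),
      list(recall_test_unit = x$report$recall_test_unit)),
    file.path(out_dir, "cohort_summary.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(unclass(x$config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
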