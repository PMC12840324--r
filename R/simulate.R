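#' Configuration of a synthetic ground-truth cohort
#'
#' The phantom generator emulates the statistical structure of a 125-scan
#' head-and-neck CT cohort: about 29.2 nodes per scan (Poisson), 544/3656
#' metastatic, status-conditional SAD distributions (truncated log-normal,
#' calibrated numerically so the truncated means hit 5.0 mm for
#' non-metastatic nodes with a 23.3 mm maximum and 11.3 mm for metastatic
#' nodes with a 57.9 mm maximum), occasional touching-node clusters, and
#' central necrotic cores in large metastatic nodes. Nodes are
#' random-orientation ellipsoids: not realistic node geometry, but their
#' SAD and volume are analytically controllable, which is what a
#' verification phantom needs.
#'
#' @param n_scans Number of scans in the cohort.
#' @param nodes_per_scan_mean Poisson mean of nodes per scan.
#' @param metastatic_fraction Probability a node is metastatic.
#' @param sad_mean_nonmets,sad_max_nonmets Target truncated mean and upper
#'   truncation (mm) of non-metastatic SADs.
#' @param sad_mean_mets,sad_max_mets Same for metastatic SADs.
#' @param sad_sdlog_nonmets,sad_sdlog_mets Log-scale spreads of the SAD
#'   distributions (chosen to roughly reproduce the reference cohort's
#'   size-bin occupancy).
#' @param sad_min Lower truncation of sampled target SADs in mm. The
#'   default sits just above the evaluation's 4.5 mm prediction filter,
#'   mirroring the annotation protocol that only segmented nodes of
#'   roughly 5 mm and larger; nodes measuring just under 5 mm then
#'   populate the `<5` bin, as in the reference cohort.
#' @param sad_floor_mm Hard lower bound on each node's *measured* SAD: the
#'   voxelizer keeps growing a node until [compute_sad()] clears this
#'   value, so no ground-truth node (and hence no undegraded prediction
#'   of it) can fall under the evaluation's size filter by digitization
#'   alone. Must be below `sad_min`.
#' @param cluster_probability Probability that a node is placed touching
#'   the previously placed node (bulky-disease cluster).
#' @param necrosis_sad_mm Metastatic nodes at or above this SAD carry a
#'   central necrotic core.
#' @param necrosis_core_frac Volume fraction of the necrotic core.
#' @param grid_dim Voxel grid dimensions (x, y, z).
#' @param spacing Voxel spacing (mm); axis 3 is axial.
#' @param axis_ratio_range In-plane long/short axis ratio range of the
#'   ellipsoids.
#' @param seed Cohort seed; all randomness flows from it via per-scan
#'   derived seeds.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_scans = 125,
                          nodes_per_scan_mean = 29.2,
                          metastatic_fraction = 544 / 3656,
                          sad_mean_nonmets = 5.0, sad_max_nonmets = 23.3,
                          sad_mean_mets = 11.3, sad_max_mets = 57.9,
                          sad_sdlog_nonmets = 0.30, sad_sdlog_mets = 0.55,
                          sad_min = 4.7, sad_floor_mm = 4.55,
                          cluster_probability = 0.05,
                          necrosis_sad_mm = 15,
                          necrosis_core_frac = 0.15,
                          grid_dim = c(128, 128, 64),
                          spacing = c(1, 1, 2),
                          axis_ratio_range = c(1.1, 1.5),
                          seed = 1) {
  stopifnot(n_scans >= 1, nodes_per_scan_mean > 0,
            metastatic_fraction >= 0, metastatic_fraction <= 1,
            cluster_probability >= 0, cluster_probability <= 1,
            necrosis_core_frac >= 0, necrosis_core_frac < 1,
            length(grid_dim) == 3, all(grid_dim >= 8),
            length(spacing) == 3, all(spacing > 0), sad_min > 0,
            sad_floor_mm > 0, sad_floor_mm < sad_min)
  cfg <- list(
    n_scans = as.integer(n_scans),
    nodes_per_scan_mean = nodes_per_scan_mean,
    metastatic_fraction = metastatic_fraction,
    sad_mean_nonmets = sad_mean_nonmets, sad_max_nonmets = sad_max_nonmets,
    sad_mean_mets = sad_mean_mets, sad_max_mets = sad_max_mets,
    sad_sdlog_nonmets = sad_sdlog_nonmets, sad_sdlog_mets = sad_sdlog_mets,
    sad_min = sad_min, sad_floor_mm = sad_floor_mm,
    cluster_probability = cluster_probability,
    necrosis_sad_mm = necrosis_sad_mm,
    necrosis_core_frac = necrosis_core_frac,
    grid_dim = as.integer(grid_dim),
    spacing = as.numeric(spacing),
    axis_ratio_range = axis_ratio_range,
    seed = as.integer(seed)
  )
  cfg$sad_meanlog_nonmets <- trunc_lnorm_meanlog(sad_mean_nonmets,
                                                 sad_sdlog_nonmets,
                                                 sad_min, sad_max_nonmets)
  cfg$sad_meanlog_mets <- trunc_lnorm_meanlog(sad_mean_mets, sad_sdlog_mets,
                                              sad_min, sad_max_mets)
  structure(cfg, class = "cohort_config")
}

#' Configuration of the prediction degradation model
#'
#' Turns a ground-truth phantom into a plausible "model prediction" with
#' the failure modes of an imperfect segmentation network: size-dependent
#' whole-node misses (defaults are one minus the reference cohort's per-bin
#' recalls), mild boundary errors (random in-plane erosion or dilation by
#' one voxel), drop-out of necrotic cores in large metastatic nodes, and
#' false-positive blobs at background locations (Poisson-distributed count
#' per scan, truncated log-normal sizes). Miss events are drawn per
#' ground-truth instance, before boundary degradation, so realised per-bin
#' recall is binomial with known success probability -- the structure the
#' verification suite relies on.
#'
#' Two details keep the miss calibration identifiable through the
#' evaluation pipeline: erosion is only applied to nodes at or above
#' `erosion_min_sad_mm` (so a one-voxel erosion can never push a surviving
#' node's sensitivity below the 0.4 localization threshold), and surviving
#' predicted components are dilated in-plane until their SAD clears
#' `min_pred_sad_guard_mm` (so the evaluation's small-prediction filter
#' removes only deliberate noise, never a surviving node). The simulated
#' false-positive population represents the post-filter FP stream --
#' sizes are truncated below just above the filter -- because the
#' reference FP rate and mean size are counted after size filtering.
#'
#' @param miss_probability Per-SAD-bin whole-node miss probabilities
#'   (bins from `bin_edges`).
#' @param bin_edges SAD bin edges in mm.
#' @param erosion_probability,erosion_radius In-plane erosion of surviving
#'   nodes: probability per node and radius in voxels.
#' @param erosion_min_sad_mm Minimum SAD for a node to be eligible for
#'   erosion.
#' @param dilation_probability,dilation_radius In-plane dilation of
#'   surviving nodes.
#' @param necrosis_dropout_probability Probability that a necrotic core is
#'   left out of the prediction.
#' @param fp_rate Poisson mean of false positives per scan.
#' @param fp_sad_mean Mean SAD of false positives in mm.
#' @param fp_sad_sdlog Log-scale spread of FP sizes.
#' @param fp_sad_range Truncation range of FP sizes in mm.
#' @param min_pred_sad_guard_mm Lower SAD guard for surviving predicted
#'   components.
#' @return A `degradation_config` list.
#' @export
degradation_config <- function(miss_probability = c(0.28, 0.21, 0.33, 0.64),
                               bin_edges = c(5, 10, 15),
                               erosion_probability = 0.2, erosion_radius = 1,
                               erosion_min_sad_mm = 9,
                               dilation_probability = 0.3, dilation_radius = 1,
                               necrosis_dropout_probability = 0.8,
                               fp_rate = 6.5,
                               fp_sad_mean = 5.3, fp_sad_sdlog = 0.25,
                               fp_sad_range = c(4.6, 15),
                               min_pred_sad_guard_mm = 4.5) {
  stopifnot(length(miss_probability) == length(bin_edges) + 1,
            all(miss_probability >= 0), all(miss_probability <= 1),
            erosion_probability >= 0, dilation_probability >= 0,
            erosion_probability + dilation_probability <= 1,
            necrosis_dropout_probability >= 0, necrosis_dropout_probability <= 1,
            fp_rate >= 0)
  cfg <- list(
    miss_probability = miss_probability, bin_edges = bin_edges,
    erosion_probability = erosion_probability, erosion_radius = erosion_radius,
    erosion_min_sad_mm = erosion_min_sad_mm,
    dilation_probability = dilation_probability, dilation_radius = dilation_radius,
    necrosis_dropout_probability = necrosis_dropout_probability,
    fp_rate = fp_rate, fp_sad_mean = fp_sad_mean, fp_sad_sdlog = fp_sad_sdlog,
    fp_sad_range = fp_sad_range,
    min_pred_sad_guard_mm = min_pred_sad_guard_mm
  )
  cfg$fp_sad_meanlog <- if (fp_rate > 0) {
    trunc_lnorm_meanlog(fp_sad_mean, fp_sad_sdlog,
                        fp_sad_range[1], fp_sad_range[2])
  } else NA_real_
  structure(cfg, class = "degradation_config")
}

#' Identity (no-op) degradation
#'
#' Convenience config under which the prediction equals the ground truth:
#' no misses, no boundary errors, no necrosis drop-out, no false positives.
#'
#' @param bin_edges SAD bin edges in mm.
#' @return A `degradation_config`.
#' @export
no_degradation <- function(bin_edges = c(5, 10, 15)) {
  degradation_config(
    miss_probability = rep(0, length(bin_edges) + 1), bin_edges = bin_edges,
    erosion_probability = 0, dilation_probability = 0,
    necrosis_dropout_probability = 0, fp_rate = 0
  )
}

# Solve the log-scale location of a [lower, upper]-truncated log-normal so
# its truncated mean equals `target_mean`, at fixed sdlog. The truncated
# mean is monotone in the location and tends to the truncation limits, so
# the root is bracketed; degenerate tails are clamped to those limits.
trunc_lnorm_meanlog <- function(target_mean, sdlog, lower, upper) {
  stopifnot(lower < target_mean, target_mean < upper)
  trunc_mean <- function(mu) {
    plo <- stats::plnorm(lower, mu, sdlog)
    phi <- stats::plnorm(upper, mu, sdlog)
    if (phi - plo < 1e-12) return(if (mu < log(lower)) lower else upper)
    num <- stats::pnorm((log(upper) - mu - sdlog^2) / sdlog) -
      stats::pnorm((log(lower) - mu - sdlog^2) / sdlog)
    exp(mu + sdlog^2 / 2) * num / (phi - plo)
  }
  stats::uniroot(function(mu) trunc_mean(mu) - target_mean,
                 lower = log(lower) - 6 * sdlog - 1,
                 upper = log(upper) + 6 * sdlog + 1,
                 tol = 1e-10)$root
}

rtrunc_lnorm <- function(n, meanlog, sdlog, lower, upper) {
  plo <- stats::plnorm(lower, meanlog, sdlog)
  phi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

# Voxel indices (1-based matrix) of a z-rotated ellipsoid. Semi-axes a, b
# in-plane (mm), c along z (mm); theta is the in-plane rotation.
fill_ellipsoid <- function(grid_dim, spacing, center, a, b, c_ax, theta) {
  r_in <- max(a, b)
  ix <- index_range(center[1], r_in, spacing[1], grid_dim[1])
  iy <- index_range(center[2], r_in, spacing[2], grid_dim[2])
  iz <- index_range(center[3], c_ax, spacing[3], grid_dim[3])
  if (!length(ix) || !length(iy) || !length(iz)) {
    return(matrix(integer(0), ncol = 3))
  }
  dx <- (ix - 1) * spacing[1] - center[1]
  dy <- (iy - 1) * spacing[2] - center[2]
  dz <- (iz - 1) * spacing[3] - center[3]
  ct <- cos(theta); st <- sin(theta)
  # in-plane quadratic form, broadcast over the bounding box
  xr <- outer(dx * ct, dy * st, "+")   # x' = ct*dx + st*dy
  yr <- outer(-dx * st, dy * ct, "+")  # y' = -st*dx + ct*dy
  q2 <- (xr / a)^2 + (yr / b)^2
  inside <- outer(q2, (dz / c_ax)^2, "+") <= 1
  w <- which(inside, arr.ind = TRUE)
  cbind(ix[w[, 1]], iy[w[, 2]], iz[w[, 3]])
}

index_range <- function(center_mm, radius_mm, step_mm, n) {
  lo <- max(1L, as.integer(floor((center_mm - radius_mm) / step_mm)) + 1L)
  hi <- min(n, as.integer(ceiling((center_mm + radius_mm) / step_mm)) + 1L)
  if (lo > hi) integer(0) else lo:hi
}

lin_index <- function(coords, grid_dim) {
  coords[, 1] + grid_dim[1] * (coords[, 2] - 1L) +
    grid_dim[1] * grid_dim[2] * (coords[, 3] - 1L)
}

# Sample one node's geometry from the config (RNG state is the caller's).
sample_node_geometry <- function(cfg) {
  metastatic <- stats::runif(1) < cfg$metastatic_fraction
  sad <- if (metastatic) {
    rtrunc_lnorm(1, cfg$sad_meanlog_mets, cfg$sad_sdlog_mets,
                 cfg$sad_min, cfg$sad_max_mets)
  } else {
    rtrunc_lnorm(1, cfg$sad_meanlog_nonmets, cfg$sad_sdlog_nonmets,
                 cfg$sad_min, cfg$sad_max_nonmets)
  }
  sxy <- min(cfg$spacing[1:2])
  b <- max((sad - sxy) / 2, 0.6 * sxy)
  ratio <- stats::runif(1, cfg$axis_ratio_range[1], cfg$axis_ratio_range[2])
  list(
    metastatic = metastatic,
    necrotic = metastatic && sad >= cfg$necrosis_sad_mm,
    target_sad_mm = sad,
    a = b * ratio, b = b,
    c_ax = max(b * stats::runif(1, 0.8, 1.2), cfg$spacing[3] * 0.6),
    theta = stats::runif(1, 0, pi)
  )
}

# Snap a continuous centre (mm) onto the voxel-centre grid so the
# equatorial axial slice is sampled exactly; keeps realised SADs tight.
snap_center <- function(center, spacing) round(center / spacing) * spacing

# Voxelize one node, calibrating the in-plane semi-axes so the measured
# SAD of the digital ellipsoid lands within ~3/4 of an in-plane voxel of
# the sampled target (digitization shifts small rotated ellipses by more
# than the analytic half-voxel correction).
calibrate_node_voxels <- function(g, center, grid_dim, spacing,
                                  min_realized = 0) {
  sxy <- min(spacing[1:2])
  target <- g$target_sad_mm
  ratio <- g$a / g$b
  b <- g$b
  best <- NULL
  best_dev <- Inf
  for (it in 1:6) {
    idx <- fill_ellipsoid(grid_dim, spacing, center, ratio * b, b, g$c_ax, g$theta)
    if (nrow(idx) == 0) break
    sad <- compute_sad(idx - 1L, spacing)
    dev <- abs(sad - target)
    if (dev < best_dev && sad >= min_realized) {
      best <- list(idx = idx, a = ratio * b, b = b, sad = sad)
      best_dev <- dev
    }
    if (dev <= 0.5 * sxy && sad >= min_realized) break
    step <- if (sad < min_realized) max((min_realized - sad) / 2, 0.3 * sxy)
            else (target - sad) / 2
    step <- sign(step) * min(abs(step), if (it <= 2) Inf else 0.5 * sxy)
    b <- max(b + step, 0.4 * sxy)
  }
  best
}

# In-plane radius of the rotated ellipse along unit direction (ux, uy).
ellipse_radius_along <- function(a, b, theta, ux, uy) {
  ct <- cos(theta); st <- sin(theta)
  u1 <- ux * ct + uy * st
  u2 <- -ux * st + uy * ct
  1 / sqrt((u1 / a)^2 + (u2 / b)^2)
}

#' Generate one synthetic ground-truth scan
#'
#' Places non-overlapping digital ellipsoids (except deliberate touching
#' clusters) in the voxel grid, extracts instances exactly as the
#' evaluation would, and attaches per-instance metadata. A touching
#' cluster becomes one instance, flagged metastatic/necrotic if any member
#' is. Each node's realised SAD, as measured by [compute_sad()], lies
#' within about one in-plane voxel of its sampled target.
#'
#' @param cfg A [cohort_config()].
#' @param scan_seed Integer seed for this scan.
#' @param max_attempts Placement attempts per node before giving up.
#' @return A `gt_scan`: list with `gt` (binary [label_volume]), `volume`
#'   (instance volume), `instances` (measured instance tibble),
#'   `instance_meta` (per-instance `metastatic`/`necrotic`), `gen_nodes`
#'   (generated node parameters) and the placement exclusion map used for
#'   false-positive placement.
#' @export
sample_gt_scan <- function(cfg, scan_seed, max_attempts = 200) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(scan_seed)
  gd <- cfg$grid_dim; sp <- cfg$spacing
  n_nodes <- max(1L, stats::rpois(1, cfg$nodes_per_scan_mean))
  gt <- array(FALSE, gd)
  excl <- array(FALSE, gd)
  gap_xy <- 2 * min(sp[1:2]); gap_z <- 2 * sp[3]
  gen <- vector("list", n_nodes)
  prev <- NULL

  for (i in seq_len(n_nodes)) {
    g <- sample_node_geometry(cfg)
    placed <- FALSE
    clustered <- !is.null(prev) && stats::runif(1) < cfg$cluster_probability
    cal <- NULL
    if (clustered) {
      phi <- stats::runif(1, 0, 2 * pi)
      u <- c(cos(phi), sin(phi))
      d <- 0.9 * (ellipse_radius_along(prev$a, prev$b, prev$theta, u[1], u[2]) +
                    ellipse_radius_along(g$a, g$b, g$theta, -u[1], -u[2]))
      center <- snap_center(c(prev$center[1] + d * u[1],
                              prev$center[2] + d * u[2], prev$center[3]), sp)
      ok_bounds <- all(center[1:2] > max(g$a, g$b) + sp[1:2]) &&
        all(center[1:2] < (gd[1:2] - 1) * sp[1:2] - max(g$a, g$b) - sp[1:2]) &&
        center[3] > g$c_ax && center[3] < (gd[3] - 1) * sp[3] - g$c_ax
      if (ok_bounds) {
        cal <- calibrate_node_voxels(g, center, gd, sp, cfg$sad_floor_mm)
        if (!is.null(cal)) placed <- TRUE
      }
    }
    if (!placed) {
      clustered <- FALSE
      r_in <- max(g$a, g$b)
      lo <- c(r_in + sp[1], r_in + sp[2], g$c_ax + sp[3])
      hi <- c((gd[1] - 1) * sp[1] - r_in - sp[1],
              (gd[2] - 1) * sp[2] - r_in - sp[2],
              (gd[3] - 1) * sp[3] - g$c_ax - sp[3])
      if (any(hi <= lo)) {
        stop("grid too small to place a node of SAD ",
             round(g$target_sad_mm, 1), " mm", call. = FALSE)
      }
      for (att in seq_len(max_attempts)) {
        center <- snap_center(stats::runif(3, lo, hi), sp)
        cal <- calibrate_node_voxels(g, center, gd, sp, cfg$sad_floor_mm)
        if (!is.null(cal) && !any(excl[cal$idx])) { placed <- TRUE; break }
      }
      if (!placed) {
        stop("could not place node ", i, " after ", max_attempts,
             " attempts; grid too crowded", call. = FALSE)
      }
    }
    g$a <- cal$a; g$b <- cal$b
    idx <- cal$idx
    gt[idx] <- TRUE
    excl_idx <- fill_ellipsoid(gd, sp, center, g$a + gap_xy, g$b + gap_xy,
                               g$c_ax + gap_z, g$theta)
    excl[excl_idx] <- TRUE
    g$center <- center
    g$clustered <- clustered
    gen[[i]] <- g
    prev <- g
  }

  gen_nodes <- purrr::map_dfr(seq_along(gen), function(i) {
    g <- gen[[i]]
    tibble::tibble(
      gen_id = i, center_x_mm = g$center[1], center_y_mm = g$center[2],
      center_z_mm = g$center[3], a_mm = g$a, b_mm = g$b, c_mm = g$c_ax,
      theta = g$theta, target_sad_mm = g$target_sad_mm,
      metastatic = g$metastatic, necrotic = g$necrotic,
      clustered = g$clustered
    )
  })

  gt_vol <- label_volume(array(as.integer(gt), gd), sp, "binary")
  ext <- extract_instances(gt_vol)
  centre_idx <- cbind(round(gen_nodes$center_x_mm / sp[1]) + 1,
                      round(gen_nodes$center_y_mm / sp[2]) + 1,
                      round(gen_nodes$center_z_mm / sp[3]) + 1)
  gen_nodes$node_id <- ext$volume$voxels[centre_idx]
  instance_meta <- gen_nodes |>
    dplyr::group_by(.data$node_id) |>
    dplyr::summarise(metastatic = any(.data$metastatic),
                     necrotic = any(.data$necrotic), .groups = "drop")

  structure(
    list(gt = gt_vol, volume = ext$volume, instances = ext$instances,
         instance_meta = instance_meta, gen_nodes = gen_nodes,
         exclusion = excl, config = cfg, seed = scan_seed),
    class = "gt_scan"
  )
}

# In-plane (4-neighbourhood per axial slice) morphology of one component,
# given 1-based voxel coordinates; returns new coordinates.
morph_inplane <- function(coords, grid_dim, radius, op = c("dilate", "erode")) {
  op <- match.arg(op)
  if (radius == 0 || nrow(coords) == 0) return(coords)
  pad <- radius + 1L
  lo <- pmax(apply(coords, 2, min) - c(pad, pad, 0L), 1L)
  hi <- pmin(apply(coords, 2, max) + c(pad, pad, 0L), grid_dim)
  dims <- hi - lo + 1L
  m <- array(FALSE, dims)
  m[cbind(coords[, 1] - lo[1] + 1L, coords[, 2] - lo[2] + 1L,
          coords[, 3] - lo[3] + 1L)] <- TRUE
  nx <- dims[1]; ny <- dims[2]
  for (it in seq_len(radius)) {
    sxp <- array(FALSE, dims); sxm <- array(FALSE, dims)
    syp <- array(FALSE, dims); sym <- array(FALSE, dims)
    sxp[2:nx, , ] <- m[1:(nx - 1), , ]
    sxm[1:(nx - 1), , ] <- m[2:nx, , ]
    syp[, 2:ny, ] <- m[, 1:(ny - 1), ]
    sym[, 1:(ny - 1), ] <- m[, 2:ny, ]
    m <- if (op == "dilate") m | sxp | sxm | syp | sym
         else m & sxp & sxm & syp & sym
  }
  w <- which(m, arr.ind = TRUE)
  cbind(w[, 1] + lo[1] - 1L, w[, 2] + lo[2] - 1L, w[, 3] + lo[3] - 1L)
}

#' Degrade a ground-truth scan into a synthetic prediction
#'
#' Applies the degradation model of [degradation_config()] to one
#' [sample_gt_scan()] phantom: per-instance miss events by measured SAD
#' bin, boundary erosion/dilation, necrotic-core drop-out, the
#' small-prediction SAD guard, and background false positives.
#'
#' @param scan A `gt_scan`.
#' @param dcfg A [degradation_config()].
#' @param seed Integer seed for the degradation randomness.
#' @return Binary prediction [label_volume] on the ground-truth grid.
#' @export
degrade_to_prediction <- function(scan, dcfg, seed) {
  stopifnot(inherits(scan, "gt_scan"), inherits(dcfg, "degradation_config"))
  set.seed(seed)
  gd <- dim(scan$gt$voxels); sp <- scan$gt$spacing
  pred <- array(FALSE, gd)
  coords <- coords_by_label(scan$volume)   # 0-based
  inst <- dplyr::left_join(scan$instances, scan$instance_meta, by = "node_id")

  for (i in seq_len(nrow(inst))) {
    bin <- findInterval(inst$sad_mm[i], dcfg$bin_edges) + 1L
    if (stats::runif(1) < dcfg$miss_probability[bin]) next
    cc <- coords[[inst$node_id[i]]] + 1L   # 1-based
    u <- stats::runif(1)
    if (u < dcfg$dilation_probability) {
      cc <- morph_inplane(cc, gd, dcfg$dilation_radius, "dilate")
    } else if (u < dcfg$dilation_probability + dcfg$erosion_probability &&
               inst$sad_mm[i] >= dcfg$erosion_min_sad_mm) {
      eroded <- morph_inplane(cc, gd, dcfg$erosion_radius, "erode")
      if (nrow(eroded) > 0) cc <- eroded
    }
    if (isTRUE(inst$necrotic[i])) {
      members <- scan$gen_nodes[scan$gen_nodes$node_id == inst$node_id[i] &
                                  scan$gen_nodes$necrotic, , drop = FALSE]
      for (j in seq_len(nrow(members))) {
        if (stats::runif(1) >= dcfg$necrosis_dropout_probability) next
        f <- dcfg_core_scale(scan$config$necrosis_core_frac)
        core <- fill_ellipsoid(gd, sp,
                               c(members$center_x_mm[j], members$center_y_mm[j],
                                 members$center_z_mm[j]),
                               members$a_mm[j] * f, members$b_mm[j] * f,
                               members$c_mm[j] * f, members$theta[j])
        if (nrow(core) > 0) {
          cc <- cc[!(lin_index(cc, gd) %in% lin_index(core, gd)), , drop = FALSE]
        }
      }
    }
    # SAD guard: keep surviving components above the evaluation size filter
    if (inst$sad_mm[i] < dcfg$min_pred_sad_guard_mm + 2.5 && nrow(cc) > 0) {
      for (it in 1:6) {
        if (compute_sad(cc - 1L, sp) >= dcfg$min_pred_sad_guard_mm) break
        cc <- morph_inplane(cc, gd, 1, "dilate")
      }
    }
    if (nrow(cc) > 0) pred[cc] <- TRUE
  }

  # false positives at background locations, outside the exclusion zone
  n_fp <- if (dcfg$fp_rate > 0) stats::rpois(1, dcfg$fp_rate) else 0L
  if (n_fp > 0) {
    excl <- scan$exclusion
    sxy <- min(sp[1:2])
    for (k in seq_len(n_fp)) {
      sad <- rtrunc_lnorm(1, dcfg$fp_sad_meanlog, dcfg$fp_sad_sdlog,
                          dcfg$fp_sad_range[1], dcfg$fp_sad_range[2])
      b <- max((sad - sxy) / 2, 0.6 * sxy)
      gfp <- list(target_sad_mm = sad, a = b * stats::runif(1, 1.1, 1.4),
                  b = b, c_ax = max(b * stats::runif(1, 0.8, 1.2), sp[3] * 0.6),
                  theta = stats::runif(1, 0, pi))
      r_in <- max(gfp$a, gfp$b)
      lo <- c(r_in + sp[1], r_in + sp[2], gfp$c_ax + sp[3])
      hi <- c((gd[1] - 1) * sp[1] - r_in - sp[1],
              (gd[2] - 1) * sp[2] - r_in - sp[2],
              (gd[3] - 1) * sp[3] - gfp$c_ax - sp[3])
      for (att in 1:100) {
        center <- snap_center(stats::runif(3, lo, hi), sp)
        cal <- calibrate_node_voxels(gfp, center, gd, sp,
                                     dcfg$min_pred_sad_guard_mm + 0.05)
        if (!is.null(cal) && !any(excl[cal$idx])) {
          pred[cal$idx] <- TRUE
          pad <- fill_ellipsoid(gd, sp, center, cal$a + 2 * sxy,
                                cal$b + 2 * sxy, gfp$c_ax + 2 * sp[3],
                                gfp$theta)
          excl[pad] <- TRUE
          break
        }
      }
    }
  }
  label_volume(array(as.integer(pred), gd), sp, "binary")
}

# core semi-axis scale from a target volume fraction
dcfg_core_scale <- function(volume_frac) volume_frac^(1 / 3)

#' Analytic expectations implied by a degradation configuration
#'
#' The closed-form counterpart of the simulator: because miss events are
#' sampled per instance before boundary degradation, the expected recall in
#' each SAD bin is one minus that bin's miss probability, and the expected
#' number of false positives per scan is the configured Poisson rate
#' (false positives are placed away from ground truth, so losses to
#' merging are negligible and are measured, not assumed, by the test
#' suite).
#'
#' @param dcfg A [degradation_config()].
#' @return List with `per_bin` (tibble of `sad_bin`, `expected_recall`)
#'   and `fps_per_scan`.
#' @export
expected_metrics <- function(dcfg) {
  stopifnot(inherits(dcfg, "degradation_config"))
  list(
    per_bin = tibble::tibble(
      sad_bin = sad_bin_labels(dcfg$bin_edges),
      expected_recall = 1 - dcfg$miss_probability
    ),
    fps_per_scan = dcfg$fp_rate
  )
}

#' Simulate a full synthetic cohort
#'
#' Generates `cfg$n_scans` ground-truth phantoms and their degraded
#' predictions. All randomness flows from `seed` via per-scan derived
#' seeds, so regeneration is byte-identical.
#'
#' @param cfg A [cohort_config()].
#' @param dcfg A [degradation_config()].
#' @param seed Cohort seed; defaults to `cfg$seed`.
#' @return A `synthetic_cohort`: list of scans, each with `scan_id`, `gt`
#'   (the `gt_scan`) and `pred` (binary [label_volume]), plus the configs.
#' @export
simulate_cohort <- function(cfg, dcfg = degradation_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(seed)
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * cfg$n_scans),
                  ncol = 2)
  scans <- lapply(seq_len(cfg$n_scans), function(i) {
    gt <- sample_gt_scan(cfg, seeds[i, 1])
    pred <- degrade_to_prediction(gt, dcfg, seeds[i, 2])
    list(scan_id = sprintf("scan%03d", i), gt = gt, pred = pred)
  })
  structure(list(scans = scans, config = cfg, degradation = dcfg, seed = seed),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Writes per-scan ground-truth and prediction NIfTI pairs
#' (`<scan_id>_gt.nii.gz`, `<scan_id>_pred.nii.gz` under `gt/` and
#' `pred/`), the per-node metadata CSV (`metadata.csv` with `scan_id`,
#' `node_id`, `metastatic`, `necrotic`) and the generating configuration
#' (`config.json`) into `out_dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_synthetic_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  gt_dir <- file.path(out_dir, "gt")
  pred_dir <- file.path(out_dir, "pred")
  dir.create(gt_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(pred_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- purrr::map_dfr(cohort$scans, function(s) {
    save_label_volume(s$gt$gt, file.path(gt_dir, paste0(s$scan_id, ".nii.gz")))
    save_label_volume(s$pred, file.path(pred_dir, paste0(s$scan_id, ".nii.gz")))
    dplyr::mutate(s$gt$instance_meta, scan_id = s$scan_id, .before = 1)
  })
  readr::write_csv(meta, file.path(out_dir, "metadata.csv"))
  cfg <- cohort$config; cfg$grid_dim <- as.integer(cfg$grid_dim)
  jsonlite::write_json(
    list(cohort = unclass(cfg), degradation = unclass(cohort$degradation),
         seed = cohort$seed),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
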