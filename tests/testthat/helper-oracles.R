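# Independent brute-force oracles the implementation is checked against.
# These stay deliberately naive: queue-based flood fill, exhaustive
# pairwise distances, textbook rank statistics.

# connectivity offsets as an integer matrix
offsets_for <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- ord > 0 & ord <= switch(as.character(connectivity),
                                  "6" = 1, "18" = 2, "26" = 3)
  as.matrix(g[keep, ])
}

# flood-fill connected-component labelling, plain R
flood_fill_oracle <- function(arr, connectivity = 26) {
  dims <- dim(arr)
  lab <- array(0L, dims)
  offs <- offsets_for(connectivity)
  nxt <- 0L
  idx_all <- which(arr != 0)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ai <- arrayInd(cur, dims)
      for (r in seq_len(nrow(offs))) {
        p <- ai + offs[r, ]
        if (any(p < 1) || any(p > dims)) next
        j <- p[1] + dims[1] * (p[2] - 1) + dims[1] * dims[2] * (p[3] - 1)
        if (arr[j] != 0 && lab[j] == 0L) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# boundary voxels (6-neighbourhood, volume face counts as background)
boundary_oracle <- function(arr) {
  dims <- dim(arr)
  out <- array(FALSE, dims)
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (i in which(arr != 0)) {
    ai <- arrayInd(i, dims)
    bnd <- FALSE
    for (r in 1:6) {
      p <- ai + offs[r, ]
      if (any(p < 1) || any(p > dims)) { bnd <- TRUE; break }
      if (arr[p[1], p[2], p[3]] == 0) { bnd <- TRUE; break }
    }
    out[i] <- bnd
  }
  out
}

# symmetric mean surface distance by exhaustive pairwise distances
avg_surface_distance_oracle <- function(a, b, spacing) {
  pa <- (which(boundary_oracle(a), arr.ind = TRUE) - 1) %*% diag(spacing)
  pb <- (which(boundary_oracle(b), arr.ind = TRUE) - 1) %*% diag(spacing)
  if (nrow(pa) == 0 || nrow(pb) == 0) return(NA_real_)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  (mean(apply(d, 1, min)) + mean(apply(d, 2, min))) / 2
}

dice_oracle <- function(a, b) {
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na + nb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (na + nb)
}

sensitivity_oracle <- function(gt_lab, pred, id) {
  sum(gt_lab == id & pred != 0) / sum(gt_lab == id)
}

# Kruskal-Wallis H, textbook formula (no tie correction; use on
# ties-free samples only)
kw_h_oracle <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  rs <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  12 / (n * (n + 1)) * sum(ns * (rs - (n + 1) / 2)^2)
}

# exhaustive per-slice SAD oracle: max caliper direction over all voxel
# pairs, perpendicular extent over all voxels, box widening
sad_oracle <- function(coords0, spacing) {
  sx <- spacing[1]; sy <- spacing[2]
  best <- min(sx, sy)
  for (z in unique(coords0[, 3])) {
    cc <- coords0[coords0[, 3] == z, , drop = FALSE]
    pts <- unique(cbind(cc[, 1] * sx, cc[, 2] * sy))
    if (nrow(pts) < 2) next
    dmax <- -1; pair <- NULL
    for (i in 1:(nrow(pts) - 1)) for (j in (i + 1):nrow(pts)) {
      d <- sum((pts[i, ] - pts[j, ])^2)
      if (d > dmax) { dmax <- d; pair <- c(i, j) }
    }
    dir <- pts[pair[2], ] - pts[pair[1], ]
    dir <- dir / sqrt(sum(dir^2))
    nrm <- c(-dir[2], dir[1])
    pr <- pts %*% nrm
    best <- max(best, max(pr) - min(pr) + min(sx, sy))
  }
  best
}

random_mask <- function(dims, p, seed) {
  set.seed(seed)
  array(as.integer(stats::runif(prod(dims)) < p), dims)
}

make_vol <- function(arr, spacing = c(1, 1, 1), kind = "binary") {
  label_volume(arr, spacing, kind)
}

# digital axial ellipsoid mask centred mid-grid
ellipsoid_mask <- function(dims, spacing, semi_mm, center_mm = NULL) {
  if (is.null(center_mm)) center_mm <- (dims - 1) / 2 * spacing
  x <- ((seq_len(dims[1]) - 1) * spacing[1] - center_mm[1]) / semi_mm[1]
  y <- ((seq_len(dims[2]) - 1) * spacing[2] - center_mm[2]) / semi_mm[2]
  z <- ((seq_len(dims[3]) - 1) * spacing[3] - center_mm[3]) / semi_mm[3]
  q <- outer(outer(x^2, y^2, "+"), z^2, "+")
  array(as.integer(q <= 1), dims)
}

# shared 125-scan default cohort, simulated once per test session
.cohort_cache <- new.env(parent = emptyenv())
default_cohort_eval <- function() {
  if (is.null(.cohort_cache$ev)) {
    co <- simulate_cohort(cohort_config(), degradation_config(), seed = 1)
    .cohort_cache$ev <- evaluate_cohort(co)
  }
  .cohort_cache$ev
}
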