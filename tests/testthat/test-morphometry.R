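cube_at <- function(arr, x, y, z) { arr[x, y, z] <- 1L; arr }

test_that("connected components follow the chosen connectivity", {
  z <- array(0L, c(12, 12, 8))
  expect_equal(nrow(extract_instances(make_vol(z))$instances), 0)

  two <- cube_at(cube_at(z, 2:4, 2:4, 2:4), 8:10, 8:10, 2:4)
  expect_equal(nrow(extract_instances(make_vol(two))$instances), 2)

  # sharing a face: one instance at any connectivity
  face <- cube_at(cube_at(z, 2:4, 2:4, 2:4), 5:7, 2:4, 2:4)
  for (conn in c(6, 18, 26)) {
    expect_equal(nrow(extract_instances(make_vol(face), conn)$instances), 1)
  }

  # touching only at a corner: merged at 26, split at 6
  corner <- cube_at(cube_at(z, 2:4, 2:4, 2:4), 5:7, 5:7, 5:7)
  expect_equal(nrow(extract_instances(make_vol(corner), 26)$instances), 1)
  expect_equal(nrow(extract_instances(make_vol(corner), 6)$instances), 2)

  expect_error(extract_instances(make_vol(z, kind = "binary"), 8), "arg")
  expect_error(extract_instances(
    label_volume(cube_at(z, 2, 2, 2), c(1, 1, 1), "instance")), "binary")
})

test_that("labelling agrees with a flood-fill oracle on random masks", {
  for (seed in 1:8) {
    m <- random_mask(c(20, 20, 20), p = 0.18, seed = seed)
    for (conn in c(6, 26)) {
      ext <- extract_instances(make_vol(m), conn)
      oracle <- flood_fill_oracle(m, conn)
      expect_equal(nrow(ext$instances), max(oracle))
      # identical partitions: labels must be a bijection of oracle labels
      fg <- m != 0
      expect_equal(length(unique(paste(ext$volume$voxels[fg], oracle[fg]))),
                   max(oracle))
      # voxel conservation
      expect_equal(sum(ext$instances$voxel_count), sum(m))
    }
  }
})

test_that("SAD measures degenerate and canonical shapes correctly", {
  # single voxel at anisotropic spacing: floored at one in-plane voxel
  expect_equal(compute_sad(matrix(c(3, 4, 1), ncol = 3), c(1, 1, 2)), 1.0)

  # digital axial disc of radius 10 voxels: SAD = 20 within one voxel
  disc <- ellipsoid_mask(c(25, 25, 3), c(1, 1, 2), c(10, 10, 0.9))
  cc <- which(disc != 0, arr.ind = TRUE) - 1
  expect_lt(abs(compute_sad(cc, c(1, 1, 2)) - 20), 1 + 1e-9)

  # 3D ellipsoid, axial semi-axes 15 x 6 at unit spacing: SAD about 12
  ell <- ellipsoid_mask(c(35, 35, 15), c(1, 1, 1), c(15, 6, 5))
  cc <- which(ell != 0, arr.ind = TRUE) - 1
  expect_lt(abs(compute_sad(cc, c(1, 1, 1)) - 12), 1 + 1e-9)

  expect_error(compute_sad(matrix(numeric(0), ncol = 3), c(1, 1, 1)), "empty")
})

test_that("SAD matches the exhaustive projection oracle and is invariant", {
  set.seed(7)
  for (trial in 1:6) {
    m <- ellipsoid_mask(c(16, 16, 6), c(1, 1, 2),
                        c(runif(1, 2, 6), runif(1, 2, 6), runif(1, 1.5, 4)))
    cc <- which(m != 0, arr.ind = TRUE) - 1
    expect_equal(compute_sad(cc, c(1, 1, 2)), sad_oracle(cc, c(1, 1, 2)),
                 tolerance = 1e-10)
    # translation invariance
    shifted <- sweep(cc, 2, c(5, 3, 2), "+")
    expect_equal(compute_sad(shifted, c(1, 1, 2)), compute_sad(cc, c(1, 1, 2)))
  }
})

test_that("in-plane dilation never decreases SAD", {
  for (r in c(3, 5, 8)) {
    base <- ellipsoid_mask(c(30, 30, 5), c(1, 1, 2), c(r, r * 0.8, 2))
    sads <- vapply(0:2, function(grow) {
      m <- ellipsoid_mask(c(30, 30, 5), c(1, 1, 2), c(r + grow, r * 0.8 + grow, 2))
      compute_sad(which(m != 0, arr.ind = TRUE) - 1, c(1, 1, 2))
    }, numeric(1))
    expect_true(all(diff(sads) >= 0))
  }
})

test_that("small predictions are filtered strictly below the threshold", {
  # three blobs whose table carries SADs 3.0, 4.5 and 9.0 mm
  z <- array(0L, c(30, 12, 4))
  z[2:3, 2:3, 1:2] <- 1L
  z[10:13, 2:5, 1:3] <- 2L
  z[20:28, 2:10, 1:4] <- 3L
  vol <- label_volume(z, c(1, 1, 2), "instance")
  inst <- tibble::tibble(node_id = 1:3, voxel_count = c(8L, 48L, 324L),
                         volume_mm3 = c(16, 96, 648), sad_mm = c(3, 4.5, 9),
                         centroid_x_mm = 0, centroid_y_mm = 0,
                         centroid_z_mm = 0)
  flt <- filter_small_predictions(inst, vol, min_sad_mm = 4.5)
  # the boundary value is retained; strictly smaller ones are removed
  expect_equal(flt$instances$sad_mm, c(4.5, 9))
  expect_equal(flt$removed$sad_mm, 3)
  expect_equal(flt$instances$node_id, 1:2)      # relabelled consecutively
  expect_equal(sort(unique(as.vector(flt$volume$voxels))), 0:2)
  expect_equal(sum(flt$mask$voxels), 48 + 324)

  # all below threshold: mask becomes empty
  flt_all <- filter_small_predictions(inst, vol, min_sad_mm = 99)
  expect_equal(nrow(flt_all$instances), 0)
  expect_true(all(flt_all$mask$voxels == 0L))

  empty <- filter_small_predictions(inst[0, ], vol)
  expect_equal(nrow(empty$instances), 0)
})

test_that("SAD bins are left-closed right-open with canonical labels", {
  expect_equal(as.character(assign_sad_bin(c(4.9, 5.0, 9.99, 10, 11.3, 15, 57.9))),
               c("<5", "5-10", "5-10", "10-15", "10-15", ">15", ">15"))
  expect_error(assign_sad_bin(c(5, -1)), "positive")
  expect_error(assign_sad_bin(0), "positive")
})
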