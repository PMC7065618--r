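test_that("depth window maximizes summed intensity over all placements", {
  set.seed(21)
  g <- voxel_grid(c(60, 8, 8), c(0.01, 0.02, 0.02))
  # signal confined to slices 30..59 (0.3 mm at dz = 0.01)
  a <- array(0, c(60, 8, 8)); a[30:59, , ] <- 1
  win <- select_depth_window(octa_volume(a, g), 0.3)
  expect_equal(win$grid$shape[1], 30L)
  expect_equal(win$depth_offset_mm, 29 * 0.01)
  expect_true(all(win$data == 1))
  # uniform volume: tie broken toward the shallowest window
  u <- select_depth_window(octa_volume(array(1, c(60, 8, 8)), g), 0.3)
  expect_equal(u$depth_offset_mm, 0)
  # random volume: placement equals exhaustive argmax (10-slice window)
  r <- array(runif(60 * 64), c(60, 8, 8))
  rv <- octa_volume(r, g)
  win10 <- select_depth_window(rv, 0.1)
  prof <- vapply(1:60, function(z) sum(r[z, , ]), 0)
  totals <- vapply(1:51, function(z0) sum(prof[z0:(z0 + 9)]), 0)
  expect_equal(win10$depth_offset_mm, (which.max(totals) - 1) * 0.01)
  expect_error(select_depth_window(rv, 10), "thicker")
})

test_that("median filter matches exhaustive sort-and-pick-middle", {
  set.seed(22)
  g <- voxel_grid(c(8, 8, 8), c(1, 1, 1))
  a <- array(runif(512), c(8, 8, 8))
  got <- median3d(octa_volume(a, g), 3L)$data
  reflect <- function(i, n) { i <- ifelse(i < 1, 1 - i, i); ifelse(i > n, 2 * n - i + 1, i) }
  for (pick in list(c(1, 1, 1), c(4, 5, 3), c(8, 8, 8), c(2, 7, 6))) {
    z <- pick[1]; y <- pick[2]; x <- pick[3]
    vals <- a[reflect(z + (-1:1), 8), reflect(y + (-1:1), 8), reflect(x + (-1:1), 8)]
    expect_equal(got[z, y, x], median(vals))
  }
  # constants are fixed points; an isolated impulse is removed
  cv <- octa_volume(array(2, c(6, 6, 6)), voxel_grid(c(6, 6, 6), c(1, 1, 1)))
  expect_true(all(median3d(cv)$data == 2))
  imp <- array(0, c(6, 6, 6)); imp[3, 3, 3] <- 9
  expect_true(all(median3d(octa_volume(imp, voxel_grid(c(6, 6, 6), c(1, 1, 1))))$data == 0))
  expect_error(median3d(cv, 4L), "odd")
})

test_that("median filter is idempotent on thick piecewise-constant volumes", {
  g <- voxel_grid(c(12, 12, 12), c(1, 1, 1))
  a <- array(0, c(12, 12, 12)); a[, , 7:12] <- 3   # two half-spaces
  once <- median3d(octa_volume(a, g))
  twice <- median3d(once)
  expect_equal(once$data, twice$data)
})

test_that("frangi enhances tubes, suppresses background, stays in [0,1]", {
  g <- iso_grid(32)
  tube <- straight_tube(g, radius_vox = 2)
  vol <- octa_volume(array(as.numeric(tube$data), g$shape), g)
  cfg <- frangi_config(scale_units = "voxel")
  fr <- frangi_vesselness(vol, cfg)
  expect_true(all(fr$data >= 0 & fr$data <= 1))
  center <- g$shape %/% 2L
  on_axis <- fr$data[center[1], center[2], 16]
  off_axis <- fr$data[center[1], center[2] + 5L, 16]
  expect_gt(on_axis, off_axis)   # axis response dominates at 5 voxels out
  expect_gt(on_axis, 0.3)
  # uniform volume has zero Hessian everywhere
  u <- octa_volume(array(1, c(8, 8, 8)), voxel_grid(c(8, 8, 8), c(1, 1, 1)))
  expect_true(all(frangi_vesselness(u, cfg)$data == 0))
  expect_error(frangi_vesselness(octa_volume(array(1, c(2, 4, 4)),
                                             spacing = c(1, 1, 1)), cfg),
               ">= 3 voxels")
})

test_that("multiscale response equals the max over single-scale runs", {
  g <- iso_grid(24)
  tube <- straight_tube(g, radius_vox = 2)
  vol <- octa_volume(array(as.numeric(tube$data), g$shape), g)
  # fixed c so single-scale runs share the same normalization
  multi <- frangi_vesselness(vol, frangi_config(scales = c(1, 2, 3), c = 0.5,
                                                scale_units = "voxel"))
  singles <- lapply(c(1, 2, 3), function(s)
    frangi_vesselness(vol, frangi_config(scales = s, c = 0.5,
                                         scale_units = "voxel"))$data)
  expect_equal(multi$data, pmax(singles[[1]], singles[[2]], singles[[3]]),
               tolerance = 1e-6)
})

test_that("a 90-degree rotation about z permutes the response field", {
  g <- iso_grid(24)
  tube_x <- straight_tube(g, radius_vox = 2)
  vol_x <- array(as.numeric(tube_x$data), g$shape)
  # rotate the volume: (z, y, x) -> (z, x, ny + 1 - y)
  vol_y <- aperm(vol_x, c(1, 3, 2))[, , rev(seq_len(24))]
  cfg <- frangi_config(scales = 1:3, c = 0.5, scale_units = "voxel")
  fx <- frangi_vesselness(octa_volume(vol_x, g), cfg)$data
  fy <- frangi_vesselness(octa_volume(vol_y, g), cfg)$data
  expect_equal(fy, aperm(fx, c(1, 3, 2))[, , rev(seq_len(24))],
               tolerance = 1e-5)
})

test_that("frangi_config rejects invalid settings", {
  expect_error(frangi_config(scales = c(2, 1)), "increasing")
  expect_error(frangi_config(alpha = 0), "> 0")
  expect_error(frangi_config(c = -1), "> 0")
})
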