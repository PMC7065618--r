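test_that("a straight tube thins to a single path on its axis", {
  g <- iso_grid(32)
  tube <- straight_tube(g, radius_vox = 3)
  sk <- skeletonize(tube)
  expect_true(all(sk$data <= tube$data))      # skeleton inside mask
  co <- which(sk$data != 0L, arr.ind = TRUE)
  # curve thinning erodes the free tube ends by roughly one radius plus the
  # priority-smoothing reach, so the surviving path is shorter than the tube
  expect_gt(nrow(co), 5)
  # every skeleton voxel within 1 voxel of the true axis (rows/cols 16 or 17)
  expect_true(all(abs(co[, 1] - 16.5) <= 1.5))
  expect_true(all(abs(co[, 2] - 16.5) <= 1.5))
  gr <- build_graph(sk, NULL, 5L)
  expect_equal(gr$n_trees, 1L)
  expect_equal(length(gr$branches), 1L)
  expect_equal(gr$branches[[1]]$kind, "end-end")
})

test_that("skeletonization preserves component count and handles empties", {
  g <- iso_grid(48)
  for (k in 1:3) {
    m <- tube_set_mask(g, k)
    sk <- skeletonize(m)
    expect_equal(build_graph(sk, NULL, 5L)$n_trees, k)
  }
  empty <- vessel_mask(array(0L, g$shape), g)
  expect_equal(sum(skeletonize(empty)$data), 0L)
})

test_that("the skeleton is thin: no fully occupied 2x2x2 block", {
  g <- iso_grid(32)
  sk <- skeletonize(straight_tube(g, radius_vox = 4))
  a <- sk$data
  blocks <- a[-32, -32, -32] & a[-1, -32, -32] & a[-32, -1, -32] &
    a[-32, -32, -1] & a[-1, -1, -32] & a[-1, -32, -1] & a[-32, -1, -1] &
    a[-1, -1, -1]
  expect_false(any(blocks))
  # and build_graph rejects a hand-made thick block
  thick <- array(0L, c(4, 4, 4)); thick[2:3, 2:3, 2:3] <- 1L
  expect_error(build_graph(vessel_mask(thick, voxel_grid(c(4, 4, 4), c(1, 1, 1)),
                                       skeleton = TRUE), NULL, 0L),
               "not thin")
})

test_that("radius estimation recovers tube radii within one voxel", {
  for (r in 2:6) {
    g <- iso_grid(40, d = 0.02)
    tube <- straight_tube(g, radius_vox = r)
    sk <- skeletonize(tube)
    radii <- estimate_radii(tube, sk)
    err <- abs(mean(radii$radius_mm) - r * 0.02)
    expect_lte(err, 0.02)  # <= 1 voxel spacing
  }
})

test_that("radius estimation handles degenerate and anisotropic cases", {
  g <- voxel_grid(c(9, 9, 9), c(1, 1, 1))
  single <- array(0L, c(9, 9, 9)); single[5, 5, 5] <- 1L
  m <- vessel_mask(single, g)
  sk <- vessel_mask(single, g, skeleton = TRUE)
  expect_equal(estimate_radii(m, sk)$radius_mm, 1)   # one voxel spacing
  # plate of half-thickness t in z on an anisotropic grid: radius ~ t
  ga <- voxel_grid(c(41, 21, 21), c(0.005, 0.02, 0.02))
  plate <- array(0L, c(41, 21, 21)); plate[16:26, , ] <- 1L  # 11 slices
  mp <- vessel_mask(plate, ga)
  mid <- array(0L, c(41, 21, 21)); mid[21, 11, 11] <- 1L
  rp <- estimate_radii(mp, vessel_mask(mid, ga, skeleton = TRUE))
  expect_equal(rp$radius_mm, 0.03, tolerance = 0.2)  # ~6 slices * 5 um
  # skeleton voxel outside the mask errors
  off <- array(0L, c(41, 21, 21)); off[1, 1, 1] <- 1L
  expect_error(estimate_radii(mp, vessel_mask(off, ga, skeleton = TRUE)),
               "outside")
})

test_that("graph decomposition handles Y junctions and spur pruning", {
  # arms leave the junction at >= 135 degrees so no two arm voxels are
  # mutually 26-adjacent: -x, +x+y diagonal, +x-y diagonal
  g <- voxel_grid(c(3, 21, 21), c(1, 1, 1))
  a <- array(0L, c(3, 21, 21))
  a[2, 11, 1:11] <- 1L                           # stem along -x, ends at hub
  for (i in 1:7) a[2, 11 + i, 11 + i] <- 1L      # diagonal arm up
  for (i in 1:7) a[2, 11 - i, 11 + i] <- 1L      # diagonal arm down
  sk <- vessel_mask(a, g, skeleton = TRUE)
  gr <- build_graph(sk, NULL, 5L)
  expect_equal(gr$n_trees, 1L)
  expect_equal(length(gr$branches), 3L)
  expect_equal(sum(gr$degree >= 3L), 1L)         # one junction
  # partition: every skeleton voxel owned by exactly one branch
  expect_true(all(!is.na(gr$owner)))
  expect_equal(length(gr$owner), sum(a))
  # short spur: shrinking one diagonal arm below the prune length removes
  # it and the re-derived graph merges the remaining two arms into one
  # branch (the former hub drops to degree 2)
  b <- array(0L, c(3, 21, 21))
  b[2, 11, 1:11] <- 1L
  for (i in 1:7) b[2, 11 + i, 11 + i] <- 1L
  for (i in 1:3) b[2, 11 - i, 11 + i] <- 1L      # 3-voxel spur
  skb <- vessel_mask(b, g, skeleton = TRUE)
  grb <- build_graph(skb, NULL, 5L)
  expect_equal(length(grb$branches), 1L)
  expect_equal(grb$n_trees, 1L)
  grb0 <- build_graph(skb, NULL, 0L)   # pruning off keeps the spur
  expect_equal(length(grb0$branches), 3L)
})

test_that("branch voxel ownership partitions the skeleton after pruning", {
  g <- iso_grid(48)
  sk <- skeletonize(tube_set_mask(g, 2))
  gr <- build_graph(sk, NULL, 5L)
  owned <- unlist(lapply(seq_along(gr$branches), function(i)
    gr$branches[[i]]$vox_rows[gr$owner[gr$branches[[i]]$vox_rows] == i]))
  expect_equal(sort(unique(owned)), seq_len(nrow(gr$voxels)))
  # sum of owned voxel counts equals the skeleton voxel count
  counts <- table(gr$owner)
  expect_equal(sum(counts), nrow(gr$voxels))
})

test_that("graph serializes to JSON", {
  g <- iso_grid(32)
  tube <- straight_tube(g)
  sk <- skeletonize(tube)
  gr <- build_graph(sk, estimate_radii(tube, sk), 5L)
  p <- file.path(withr::local_tempdir(), "graph.json")
  write_graph_json(gr, p)
  back <- jsonlite::read_json(p, simplifyVector = FALSE)
  expect_equal(length(back$trees), gr$n_trees)
  expect_equal(unlist(back$spacing_mm), g$spacing)
})
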