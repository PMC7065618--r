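# hand-built heat maps exercise the rule-based detector without the 3D stages

fake_map <- function(values, spacing = c(1, 0.02, 0.02)) {
  structure(list(values = values, coverage = matrix(1L, nrow(values), ncol(values)),
                 roi_values = as.vector(values), parameter = "VD",
                 grid = voxel_grid(c(1, nrow(values), ncol(values)), spacing)),
            class = "heatmap2d")
}

gauss_bump <- function(n, cy, cx, s, amp) {
  yy <- outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, `+`)
  amp * exp(-yy / (2 * s^2))
}

test_that("presence check follows the painted VD standard deviation", {
  g <- voxel_grid(c(4, 8, 8), c(1, 1, 1))
  a <- array(0L, c(4, 8, 8)); a[2, , ] <- 1L
  sk <- vessel_mask(a, g, skeleton = TRUE)
  hm <- list(heat_skel = array(0.002, c(4, 8, 8)))
  res <- lesion_present(hm, sk, detection_config())
  expect_false(res$present); expect_equal(res$vd_std, 0)
  # half at 0.001, half at 0.003 -> sd ~ 0.001 >> 4e-5
  hv <- array(0.001, c(4, 8, 8)); hv[, , 5:8] <- 0.003
  res2 <- lesion_present(list(heat_skel = hv), sk, detection_config())
  expect_true(res2$present)
  expect_equal(res2$vd_std, sd(c(rep(0.001, 32), rep(0.003, 32))))
  empty <- vessel_mask(array(0L, c(4, 8, 8)), g, skeleton = TRUE)
  expect_error(lesion_present(hm, empty, detection_config()), "fewer than 2")
})

test_that("subtype classification counts distinct high-density areas", {
  base <- matrix(0.001, 100, 100)
  uni <- base + gauss_bump(100, 50, 50, 8, 0.003)
  expect_equal(classify_subtype(fake_map(uni)), "sBCC")
  multi <- base
  multi[10:25, 10:25] <- 0.004
  multi[70:90, 70:90] <- 0.0042
  expect_equal(classify_subtype(fake_map(multi)), "nBCC")
  # components below min_component_px are ignored
  tiny <- base + gauss_bump(100, 50, 50, 8, 0.003)
  tiny[2, 2] <- 0.004
  expect_equal(classify_subtype(fake_map(tiny)), "sBCC")
})

test_that("sBCC area is the largest >= 75%-of-max component, refined", {
  base <- matrix(0.001, 120, 120)
  m <- base + gauss_bump(120, 60, 60, 10, 0.003)
  mask <- detect_sbcc_area(fake_map(m), detection_config())
  expect_true(mask[60, 60])
  expect_false(mask[5, 115])
  expect_equal(attr(mask, "threshold"), 0.75 * max(m))
  # mask contains everything at or above the threshold (refinement extends)
  expect_true(all(mask[m >= 0.75 * max(m)]))
})

test_that("nBCC iterative thresholding equals the exhaustive sweep oracle", {
  base <- matrix(0.002, 120, 120)
  # one low basin + a shallower depression that disappears as thr grows
  m <- base - gauss_bump(120, 40, 40, 9, 0.0015) -
    gauss_bump(120, 90, 90, 6, 0.0008)
  cfg <- detection_config(disk_radius_px = 5L)
  mask <- detect_nbcc_area(fake_map(m), cfg)
  tr <- attr(mask, "trace")
  expect_true(mask[40, 40])
  expect_gte(nrow(tr), 1L)
  expect_equal(tr$n_components[nrow(tr)], 1L)
  # oracle: first threshold in the sequence {1.2 min * 1.3^k} with exactly
  # one qualifying component
  lab_n <- function(thr) {
    sel <- m > 0 & m <= thr
    lab <- octalesion:::.label2d(sel)
    sum(tabulate(lab[lab > 0L]) >= cfg$min_component_px)
  }
  thr <- 1.2 * min(m[m > 0])
  while (lab_n(thr) != 1L) thr <- 1.3 * thr
  expect_equal(attr(mask, "threshold"), thr)
  # non-convergent map: two equal basins everywhere -> error with trace
  m2 <- matrix(0.002, 60, 60)
  m2[10:20, 10:20] <- 0.001
  m2[40:50, 40:50] <- 0.001
  expect_error(detect_nbcc_area(fake_map(m2), cfg), "did not converge")
})

test_that("refine_mask is extensive, monotone and merges nearby blobs", {
  m <- matrix(FALSE, 80, 80)
  m[40, 40] <- TRUE
  cfg20 <- detection_config()
  disk <- refine_mask(m, cfg20)
  expect_true(all(disk[m]))                       # extensive
  expect_gt(sum(disk), 1200)                      # ~ pi * 20^2
  expect_lt(sum(disk), 1400)
  cfg5 <- detection_config(disk_radius_px = 5L)
  expect_true(all(refine_mask(m, cfg5) <= disk))  # monotone in radius
  # two blobs 30 px apart, radius 20 -> merged into one component
  m2 <- matrix(FALSE, 100, 100)
  m2[50, 30] <- TRUE; m2[50, 60] <- TRUE
  merged <- refine_mask(m2, cfg20)
  lab <- octalesion:::.label2d(merged)
  expect_equal(attr(lab, "n_components"), 1L)
  # border masks are clipped, not wrapped
  m3 <- matrix(FALSE, 50, 50); m3[1, 1] <- TRUE
  r3 <- refine_mask(m3, cfg5)
  expect_equal(dim(r3), c(50L, 50L))
  expect_error(refine_mask(matrix(FALSE, 5, 5), cfg5), "nonempty")
})

test_that("lesion ROI centers on the in-mask extremum and clamps", {
  base <- matrix(0.001, 200, 200)
  m <- base + gauss_bump(200, 120, 80, 10, 0.003)
  hm <- fake_map(m)                        # 0.02 mm pixels -> 4 mm field
  lmask <- m >= 0.75 * max(m)
  roi <- place_lesion_roi(hm, lmask, "sBCC",
                          detection_config(roi_size_mm = c(0.3, 1, 1)))
  expect_equal(attr(roi, "center_mm"), c((120 - 0.5) * 0.02, (80 - 0.5) * 0.02))
  # peak close to the border: ROI shifted inward
  m2 <- base + gauss_bump(200, 5, 100, 4, 0.003)
  roi2 <- place_lesion_roi(fake_map(m2), m2 >= 0.75 * max(m2), "sBCC",
                           detection_config(roi_size_mm = c(0.3, 1, 1)))
  expect_equal(roi2$origin_mm[2], 0)
  # nBCC centers on the nonzero minimum inside the mask
  m3 <- matrix(0.002, 200, 200) - gauss_bump(200, 60, 140, 12, 0.0015)
  lm3 <- m3 <= 1.2 * min(m3)
  roi3 <- place_lesion_roi(fake_map(m3), lm3, "nBCC",
                           detection_config(roi_size_mm = c(0.3, 1, 1)))
  expect_equal(attr(roi3, "center_mm"), c(59.5 * 0.02, 139.5 * 0.02))
})

test_that("healthy ROI maximizes distance from the lesion", {
  g <- voxel_grid(c(10, 250, 250), c(0.03, 0.02, 0.02))   # 5 x 5 mm
  rg <- make_roi_grid(g, c(0.3, 1, 1), 0.3)
  lesion <- matrix(FALSE, 250, 250)
  lesion[1:50, 1:50] <- TRUE                               # top-left corner
  roi <- place_healthy_roi(rg, lesion)
  cen <- roi$origin_mm[2:3] + roi$size_mm[2:3] / 2
  expect_true(all(cen > 3.5))                              # opposite corner
  expect_false(attr(roi, "overlaps_lesion"))
  # exhaustive oracle over candidate ROIs
  les_mm <- (which(lesion, arr.ind = TRUE) - 0.5) %*% diag(g$spacing[2:3])
  dists <- vapply(rg$rois, function(r) {
    b <- roi_bounds(r, g)
    if (any(lesion[b$lo[2]:b$hi[2], b$lo[3]:b$hi[3]])) return(-Inf)
    cc <- r$origin_mm[2:3] + r$size_mm[2:3] / 2
    min(sqrt((les_mm[, 1] - cc[1])^2 + (les_mm[, 2] - cc[2])^2))
  }, 0)
  expect_equal(attr(roi, "roi_index"), which.max(dists))
  # all-covering lesion: strict mode errors, fallback flags overlap
  all_les <- matrix(TRUE, 250, 250)
  expect_error(place_healthy_roi(rg, all_les), "intersects")
  rf <- place_healthy_roi(rg, all_les, allow_overlap = TRUE)
  expect_true(attr(rf, "overlaps_lesion"))
})
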