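path3 <- function(y, x, z = 0) {
  p <- cbind(z, y, x)
  colnames(p) <- c("z", "y", "x")
  p
}

test_that("distance metric: straight = 1, right angle = sqrt(2), semicircle -> pi/2", {
  expect_identical(distance_metric(path3(c(0, 0, 0), c(0, 1, 2))), 1)
  expect_equal(distance_metric(path3(c(0, 0, 1), c(0, 1, 1))), sqrt(2))
  th <- seq(0, pi, length.out = 360)
  dm <- distance_metric(path3(sin(th), cos(th)))
  expect_lt(abs(dm - pi / 2) / (pi / 2), 0.005)
  # closed path undefined
  sq <- path3(c(0, 0, 1, 1, 0), c(0, 1, 1, 0, 0))
  expect_true(is.na(distance_metric(sq)))
})

test_that("DM is invariant under en-face rotation and uniform scaling", {
  set.seed(41)
  p <- path3(cumsum(rnorm(20)), cumsum(rnorm(20)))
  for (th in c(0.3, 1.2, 2.8)) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    q <- p; q[, 2:3] <- p[, 2:3] %*% R
    expect_equal(distance_metric(q), distance_metric(p), tolerance = 1e-10)
  }
  expect_equal(distance_metric(p * 3.7), distance_metric(p), tolerance = 1e-10)
})

test_that("inflection counting: straight and single arcs give 0, sine gives 2", {
  expect_identical(inflection_count_metric(path3(rep(0, 10), 1:10)), 0)
  th <- seq(0, 1, length.out = 20)
  expect_identical(inflection_count_metric(path3(sin(th), cos(th))), 0)
  # one full sine period with interior zero crossings -> 2 inflections
  t <- seq(0, 2 * pi, length.out = 100)
  sine <- path3(sin(t + pi / 2), t)
  dm <- distance_metric(sine)
  expect_equal(inflection_count_metric(sine), 2 * dm)
  # brute-force cross-product sign-change oracle on the same path
  tg <- diff(sine[, c(2, 3)])
  cr <- tg[-nrow(tg), 1] * tg[-1, 2] - tg[-nrow(tg), 2] * tg[-1, 1]
  s <- sign(cr)[abs(cr) > 0]
  expect_equal(sum(diff(s) != 0), 2)
  expect_true(is.na(inflection_count_metric(path3(c(0, 1), c(0, 1)))))
})

test_that("SOAM: straight = 0, right angle analytic, helix matches curvature", {
  expect_identical(sum_of_angles_metric(path3(rep(0, 5), seq(0, 2, 0.5))), 0)
  # planar right angle, two 1 mm segments: (pi/2) / 2 rad/mm
  expect_equal(sum_of_angles_metric(path3(c(0, 0, 1), c(0, 1, 1))),
               (pi / 2) / 2)
  hx <- make_path("helix", list(center = c(2, 2, 0), radius = 0.5, pitch = 1,
                                turns = 3, n = 500))
  b <- 1 / (2 * pi)
  kappa <- 0.5 / (0.5^2 + b^2)
  expect_lt(abs(sum_of_angles_metric(hx) - kappa) / kappa, 0.02)
  # all-coincident path undefined
  expect_true(is.na(sum_of_angles_metric(path3(c(1, 1, 1), c(1, 1, 1)))))
})

test_that("SOAM is rigid-motion invariant and scales as 1/length", {
  set.seed(42)
  for (i in 1:20) {
    p <- cbind(cumsum(rnorm(15, 0, 0.1)), cumsum(rnorm(15)), cumsum(rnorm(15)))
    colnames(p) <- c("z", "y", "x")
    s0 <- sum_of_angles_metric(p)
    # random rotation (QR of a random matrix) + translation
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qr_)
    q <- p %*% R + matrix(rnorm(3), nrow(p), 3, byrow = TRUE)
    expect_equal(sum_of_angles_metric(q), s0, tolerance = 1e-8)
    expect_equal(sum_of_angles_metric(p * 2), s0 / 2, tolerance = 1e-8)
  }
})

test_that("vascular density counts skeleton voxels exactly", {
  g <- voxel_grid(c(50, 50, 50), c(0.02, 0.02, 0.02))
  a <- array(0L, c(50, 50, 50))
  a[25, 25, ] <- 1L                      # straight line through the ROI
  sk <- vessel_mask(a, g, skeleton = TRUE)
  roi <- roi_box(c(0, 0, 0), c(1, 1, 1)) # full volume
  expect_equal(vascular_density(sk, roi), 50 / 50^3)
  full <- vessel_mask(array(1L, c(50, 50, 50)), g, skeleton = TRUE)
  expect_equal(vascular_density(full, roi), 1)
  empty <- vessel_mask(array(0L, c(50, 50, 50)), g, skeleton = TRUE)
  expect_equal(vascular_density(empty, roi), 0)
  expect_error(roi_bounds(roi_box(c(10, 10, 10), c(1, 1, 1)), g), "outside")
})

test_that("VD is additive over disjoint ROIs", {
  set.seed(43)
  g <- voxel_grid(c(20, 40, 40), c(0.01, 0.01, 0.01))
  a <- array(rbinom(20 * 1600, 1, 0.01), c(20, 40, 40))
  sk <- vessel_mask(a, g, skeleton = TRUE)
  roi1 <- roi_box(c(0, 0, 0), c(0.2, 0.2, 0.4))
  roi2 <- roi_box(c(0, 0.2, 0), c(0.2, 0.2, 0.4))
  both <- roi_box(c(0, 0, 0), c(0.2, 0.4, 0.4))
  n1 <- vascular_density(sk, roi1) * roi_bounds(roi1, g)$n_vox
  n2 <- vascular_density(sk, roi2) * roi_bounds(roi2, g)$n_vox
  expect_equal(vascular_density(sk, both) * roi_bounds(both, g)$n_vox, n1 + n2)
})

test_that("roi_params composes the per-branch metrics correctly", {
  g <- iso_grid(48)
  # one tube: NT = NB = 1, DM = 1, ICM = SOAM = 0
  sk1 <- skeletonize(straight_tube(g))
  gr1 <- build_graph(sk1, NULL, 5L)
  roi <- roi_box(c(0, 0, 0), grid_extent(g))
  p1 <- roi_params(gr1, sk1, roi)
  expect_equal(p1$NT, 1L); expect_equal(p1$NB, 1L)
  expect_equal(p1$DM, 1, tolerance = 1e-6)
  expect_equal(p1$ICM, 0); expect_equal(p1$SOAM, 0, tolerance = 1e-9)
  # two tubes: NT = NB = 2; VD and NT match brute-force enumeration
  m2 <- tube_set_mask(g, 2)
  sk2 <- skeletonize(m2)
  gr2 <- build_graph(sk2, estimate_radii(m2, sk2), 5L)
  p2 <- roi_params(gr2, sk2, roi)
  expect_equal(p2$NT, 2L); expect_equal(p2$NB, 2L)
  oracle <- brute_roi_counts(sk2$data, g, roi)
  expect_equal(p2$VD, oracle$vd)
  expect_equal(p2$NT, oracle$nt)
  expect_gt(p2$MR, 0)
  # empty ROI: counts zero, tortuosity metrics missing (never 0)
  empty_roi <- roi_box(c(0, 0, 0), c(0.04, 0.04, 0.04))
  pe <- roi_params(gr2, sk2, empty_roi)
  expect_equal(pe$NT, 0L); expect_equal(pe$VD, 0)
  expect_true(is.na(pe$DM) && is.na(pe$ICM) && is.na(pe$SOAM) && is.na(pe$MR))
})

test_that("branch_table summarizes one row per branch", {
  g <- iso_grid(48)
  m <- tube_set_mask(g, 3)
  sk <- skeletonize(m)
  gr <- build_graph(sk, estimate_radii(m, sk), 5L)
  tb <- branch_table(gr)
  expect_equal(nrow(tb), length(gr$branches))
  expect_true(all(tb$length_mm > 0))
  expect_true(all(tb$DM >= 1, na.rm = TRUE))
})
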