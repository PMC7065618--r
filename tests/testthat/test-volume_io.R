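test_that("voxel grid validates shape and spacing", {
  g <- voxel_grid(c(4, 5, 6), c(0.01, 0.02, 0.03))
  expect_equal(grid_extent(g), c(0.04, 0.10, 0.18))
  expect_error(voxel_grid(c(0, 5, 6), c(1, 1, 1)), ">= 1")
  expect_error(voxel_grid(c(4, 5, 6), c(0, 1, 1)), "> 0")
  expect_error(octa_volume(array(-1, c(2, 2, 2)), spacing = c(1, 1, 1)),
               "finite and >= 0")
})

test_that("round trip is identity for every supported format", {
  set.seed(11)
  g <- voxel_grid(c(7, 9, 11), c(0.0033, 0.019, 0.020))
  # values representable in float32 so TIFF round-trips bit-exactly too
  data <- array(round(runif(7 * 9 * 11), 3), dim = c(7, 9, 11))
  vol <- octa_volume(data, g, depth_offset_mm = 0.12)
  for (ext in c("raw", "nii", "tif")) {
    p <- file.path(withr::local_tempdir(), paste0("v.", ext))
    write_volume(vol, p)
    back <- read_volume(p)
    expect_equal(back$data, vol$data, tolerance = 1e-6)
    expect_equal(back$grid$shape, g$shape)
    expect_equal(back$grid$spacing, g$spacing, tolerance = 1e-6)
  }
  # raw float64 must be bit-identical
  p <- file.path(withr::local_tempdir(), "v.raw")
  write_volume(vol, p)
  expect_identical(read_volume(p)$data, vol$data)
})

test_that("degenerate single-voxel raw volume round-trips", {
  g <- voxel_grid(c(1, 1, 1), c(1, 1, 1))
  vol <- octa_volume(array(0, c(1, 1, 1)), g)
  p <- file.path(withr::local_tempdir(), "one.raw")
  write_volume(vol, p)
  expect_identical(read_volume(p)$data, vol$data)
})

test_that("binary masks are {0,255} on disk and {0,1} in memory", {
  set.seed(7)
  g <- voxel_grid(c(4, 6, 5), c(1, 1, 1))
  m <- vessel_mask(array(rbinom(120, 1, 0.4), c(4, 6, 5)), g)
  p <- file.path(withr::local_tempdir(), "m.tif")
  write_volume(m, p)
  back <- read_volume(p)          # sidecar marks it as a mask
  expect_s3_class(back, "vessel_mask")
  expect_identical(sort(unique(as.vector(back$data))), c(0L, 1L))
  expect_identical(back$data, m$data)
  raw_vals <- read_volume(p, kind = "intensity")
  expect_setequal(unique(as.vector(raw_vals$data)), c(0, 255))
})

test_that("write errors on a missing directory and leaves no file", {
  g <- voxel_grid(c(2, 2, 2), c(1, 1, 1))
  vol <- octa_volume(array(1, c(2, 2, 2)), g)
  bad <- file.path(tempdir(), "does", "not", "exist", "v.raw")
  expect_error(write_volume(vol, bad), "directory")
  expect_false(file.exists(bad))
})

test_that("raw volumes demand metadata and a matching byte count", {
  p <- file.path(withr::local_tempdir(), "orphan.raw")
  writeBin(rep(0, 7), p, size = 8)
  expect_error(read_volume(p), "sidecar")
  g <- voxel_grid(c(2, 2, 2), c(1, 1, 1))   # 8 voxels = 64 bytes expected
  expect_error(read_volume(p, metadata = g), "does not match")
  expect_error(read_volume(file.path(tempdir(), "nope.raw")), "exist")
})

test_that("tifffile (Python) reads the TIFF volumes we write", {
  py <- Sys.which("python")
  ok <- nzchar(py) &&
    system2(py, c("-c", shQuote("import tifffile")),
            stdout = FALSE, stderr = FALSE) == 0
  if (!ok) {
    succeed("python/tifffile unavailable; independent oracle not consulted")
    return(invisible(NULL))
  }
  set.seed(3)
  g <- voxel_grid(c(3, 4, 5), c(1, 1, 1))
  vol <- octa_volume(array(round(runif(60), 3), c(3, 4, 5)), g)
  p <- file.path(withr::local_tempdir(), "t.tif")
  write_volume(vol, p)
  script <- sprintf(
    "import tifffile, numpy as np; a = tifffile.imread(%s); print(a.shape); print(float(np.abs(a - 0).sum()))",
    shQuote(p))
  out <- system2(py, c("-c", shQuote(script)), stdout = TRUE)
  expect_equal(out[1], "(3, 4, 5)")
  expect_equal(as.numeric(out[2]), sum(vol$data), tolerance = 1e-4)
})

test_that("MIP matches the brute-force per-column maximum", {
  set.seed(5)
  g <- voxel_grid(c(16, 16, 16), c(0.01, 0.01, 0.01))
  vol <- octa_volume(array(runif(16^3), c(16, 16, 16)), g)
  expect_equal(mip_enface(vol), apply(vol$data, c(2, 3), max))
  # single bright voxel localizes; excluding its depth hides it
  dark <- array(0, c(16, 16, 16)); dark[9, 4, 12] <- 5
  v2 <- octa_volume(dark, g)
  m <- mip_enface(v2, c(0.08, 0.1))   # slice 9 center depth 0.085
  expect_equal(which(m > 0, arr.ind = TRUE)[1, ], c(row = 4, col = 12))
  expect_true(all(mip_enface(v2, c(0, 0.05)) == 0))
  expect_error(mip_enface(v2, c(0.05, 0.05)), "empty depth range")
})

test_that("MIP is monotone: raising one voxel never lowers the map", {
  set.seed(6)
  g <- voxel_grid(c(8, 8, 8), c(1, 1, 1))
  a <- array(runif(512), c(8, 8, 8))
  v1 <- octa_volume(a, g)
  a2 <- a; a2[3, 5, 2] <- a2[3, 5, 2] + 2
  v2 <- octa_volume(a2, g)
  expect_true(all(mip_enface(v2) >= mip_enface(v1)))
})

test_that("depth coloring encodes the depth of the brightest voxel", {
  g <- voxel_grid(c(10, 4, 4), c(0.01, 0.01, 0.01))
  a <- array(0, c(10, 4, 4))
  a[1, 1, 1] <- 1    # shallowest slice -> hue 0 (red)
  a[10, 2, 2] <- 1   # deepest -> hue 0.7 (blue)
  a[4, 3, 3] <- 0.4; a[8, 3, 3] <- 0.9   # deeper voxel brighter
  rgb <- depth_color_enface(octa_volume(a, g))
  expect_gt(rgb[1, 1, 1], 0.9); expect_lt(rgb[1, 1, 3], 0.1)   # red
  expect_gt(rgb[2, 2, 3], 0.5)                                  # blue-ish
  # (3,3): argmax at slice 8 of 10 -> hue near the deep end
  expect_gt(rgb[3, 3, 3], rgb[3, 3, 1])
})

test_that("enface images are written as portable anymaps", {
  d <- withr::local_tempdir()
  m <- matrix(seq(0, 1, length.out = 12), 3, 4)
  p <- write_enface_image(m, file.path(d, "m.pgm"))
  hdr <- readLines(p, n = 1, warn = FALSE)
  expect_equal(hdr, "P5")
  rgbp <- write_enface_image(array(runif(24), c(2, 4, 3)),
                             file.path(d, "m.ppm"))
  expect_equal(readLines(rgbp, n = 1, warn = FALSE), "P6")
})
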