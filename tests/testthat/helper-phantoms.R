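# shared fixtures: small isotropic grids and simple tube volumes

iso_grid <- function(n = 32L, d = 0.02) voxel_grid(c(n, n, n), c(d, d, d))

# straight tube along x through the volume center
straight_tube <- function(grid, radius_vox = 3, margin_vox = 3L) {
  ext <- grid_extent(grid)
  d <- grid$spacing
  path <- cbind(ext[1] / 2, ext[2] / 2,
                seq(margin_vox * d[3], ext[3] - margin_vox * d[3],
                    length.out = 50))
  colnames(path) <- c("z", "y", "x")
  rasterize_tube(path, radius_vox * d[3], grid)
}

# k parallel straight tubes along x at distinct y positions
tube_set_mask <- function(grid, k, radius_vox = 3) {
  ext <- grid_extent(grid)
  d <- grid$spacing
  buf <- vessel_mask(array(0L, grid$shape), grid)
  for (i in seq_len(k)) {
    y0 <- ext[2] * i / (k + 1)
    path <- cbind(ext[1] / 2, y0,
                  seq(3 * d[3], ext[3] - 3 * d[3], length.out = 50))
    colnames(path) <- c("z", "y", "x")
    buf$data <- buf$data | rasterize_tube(path, radius_vox * d[3], grid)$data
  }
  vessel_mask(buf$data, grid)
}

# brute-force windowed-mean threshold (oracle for the integral-image path)
naive_threshold <- function(s, window_frac = 1 / 8, sensitivity = 0.15) {
  ny <- nrow(s); nx <- ncol(s)
  w <- max(1L, floor(window_frac * nx + 0.5))
  r1 <- (w - 1L) %/% 2L; r2 <- w %/% 2L
  out <- matrix(0L, ny, nx)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    ys <- max(1L, y - r1):min(ny, y + r2)
    xs <- max(1L, x - r1):min(nx, x + r2)
    out[y, x] <- as.integer(s[y, x] > (1 - sensitivity) * mean(s[ys, xs]))
  }
  out
}

# brute-force per-ROI quantities from a skeleton array (oracle for roi_params)
brute_roi_counts <- function(skel_arr, grid, roi) {
  b <- roi_bounds(roi, grid)
  sub <- skel_arr[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3],
                  drop = FALSE]
  sub <- array(sub, b$hi - b$lo + 1L)
  nvox <- sum(sub != 0)
  lab <- octalesion:::label_components_cpp(sub != 0, dim(sub), 26L)
  list(vd = nvox / b$n_vox, nt = attr(lab, "n_components"))
}

# small anisotropic-but-realistic phantom grid for pipeline-level tests
small_phantom_grid <- function() voxel_grid(c(96L, 128L, 128L),
                                            c(0.0033, 0.030, 0.030))
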