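#' Synthetic phantom specification
#'
#' Describes a seeded OCTA-like test volume with known vessel geometry and
#' lesion ground truth. The default grid (96 x 256 x 256 voxels at
#' 3.3 x 30 x 30 um, a 7.7 x 7.7 mm field over a 0.32 mm depth crop) keeps
#' the native depth sampling while trading some en-face pitch for field
#' size: the en-face extent must exceed twice the standard 2.5 mm ROI, or
#' no ROI grid position can ever be disjoint from a refined lesion area and
#' no low-density region can separate the high-density zones that identify
#' a nodular lesion. The healthy background is a quasi-regular capillary
#' bed (two depth-separated orthogonal plexus families), emulating the even
#' vascular distribution of lesion-free skin; an sBCC adds a focus of fine
#' extra vessels inside the lesion disk (density raised by
#' `lesion_density_multiplier` > 1); an nBCC is a vessel-poor band crossing
#' the scan (multiplier < 1), the scan-window view of a nodule wider than
#' the field.
#'
#' @param kind `"healthy"`, `"sbcc"`, `"nbcc"`, `"single_tube"` or
#'   `"tube_set"`.
#' @param grid a [voxel_grid()].
#' @param background_vessel_spacing_mm nominal spacing of the background
#'   bed (default 2.5/3 mm). Two orthogonal layered families then carry
#'   about 2.4 mm of centerline per square mm, which keeps the detected
#'   vascular density near the clinically reported healthy-skin value of
#'   about 0.001 (to the printed precision) in voxel-fraction units on this
#'   grid; the spacing divides the standard 2.5 mm ROI evenly, so every ROI
#'   window samples the same number of vessels - the idealized even
#'   distribution of lesion-free skin.
#' @param vessel_radius_range_mm min/max vessel radius (default
#'   0.04-0.05 mm, about 3 en-face pixels, comfortably above the lateral
#'   resolution so vessels segment with smooth walls).
#' @param lesion_center_mm `(y, x)` lesion center; by default an sBCC disk
#'   sits at 30% of the en-face extent (off-center, as clinical scans
#'   typically are) and an nBCC band is centered on the field. For nbcc
#'   only the y component matters (the band crosses the full x range).
#' @param lesion_radius_mm en-face lesion radius: disk radius for sbcc
#'   (default 0.7 mm), band half-width for nbcc (default 0.8 mm).
#' @param lesion_density_multiplier centerline-density factor inside the
#'   lesion; default 3 for sbcc, 0.3 for nbcc, 1 otherwise.

#' @param noise list with `speckle_scale` (multiplicative, exponential
#'   mixture weight) and `gaussian_sigma` (additive).
#' @param seed integer; fixes all randomness.
#' @param n_tubes number of tubes for `tube_set`.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(kind = "healthy",
                         grid = voxel_grid(c(96, 256, 256),
                                           c(0.0033, 0.030, 0.030)),
                         background_vessel_spacing_mm = 0.25 / 0.3,
                         vessel_radius_range_mm = c(0.040, 0.050),
                         lesion_center_mm = NULL,
                         lesion_radius_mm = NULL,
                         lesion_density_multiplier = NULL,
                         noise = list(speckle_scale = 0.3,
                                      gaussian_sigma = 0.05),
                         seed = 1L, n_tubes = 3L) {
  kind <- match.arg(kind, c("healthy", "sbcc", "nbcc", "single_tube",
                            "tube_set"))
  if (is.null(lesion_density_multiplier))
    lesion_density_multiplier <- switch(kind, sbcc = 3, nbcc = 0.3, 1)
  if (lesion_density_multiplier <= 0) stop("multiplier must be > 0")
  if (kind == "sbcc" && lesion_density_multiplier <= 1)
    stop("sbcc needs lesion_density_multiplier > 1")
  if (kind == "nbcc" && lesion_density_multiplier >= 1)
    stop("nbcc needs lesion_density_multiplier < 1")
  ext <- grid_extent(grid)
  if (is.null(lesion_radius_mm))
    lesion_radius_mm <- if (kind == "nbcc") 0.8 else 0.7
  if (is.null(lesion_center_mm))
    lesion_center_mm <- if (kind == "nbcc") 0.5 * ext[2:3] else 0.30 * ext[2:3]
  if (kind == "sbcc") {
    if (lesion_center_mm[1] - lesion_radius_mm < 0 ||
        lesion_center_mm[1] + lesion_radius_mm > ext[2] ||
        lesion_center_mm[2] - lesion_radius_mm < 0 ||
        lesion_center_mm[2] + lesion_radius_mm > ext[3])
      stop("lesion disk must lie inside the volume")
  }
  if (kind == "nbcc") {
    if (lesion_center_mm[1] - lesion_radius_mm < 0 ||
        lesion_center_mm[1] + lesion_radius_mm > ext[2])
      stop("lesion band must lie inside the volume")
  }
  structure(list(kind = kind, grid = grid,
                 background_vessel_spacing_mm = background_vessel_spacing_mm,
                 vessel_radius_range_mm = vessel_radius_range_mm,
                 lesion_center_mm = lesion_center_mm,
                 lesion_radius_mm = lesion_radius_mm,
                 lesion_density_multiplier = lesion_density_multiplier,
                 noise = noise, seed = as.integer(seed),
                 n_tubes = as.integer(n_tubes)),
            class = "phantom_spec")
}

#' Generate an analytic 3D path
#'
#' Paths with known tortuosity: straight (`DM = 1`, `SOAM = 0`), planar
#' sine (2 inflections per period), helix (constant turning rate
#' `r / (r^2 + b^2)` with `b = pitch / 2 pi`), or a smooth seeded random
#' walk.
#'
#' @param kind `"straight"`, `"sine"`, `"helix"` or `"random_walk"`.
#' @param params named list; see Details in the source for each kind
#'   (`from`/`to`/`n`; `start`/`length`/`amplitude`/`periods`/`phase`/`n`;
#'   `center`/`radius`/`pitch`/`turns`/`phase`/`n`;
#'   `start`/`n`/`step_mm`/`wobble`).
#' @param seed optional seed (only `random_walk` draws random numbers).
#' @return n x 3 matrix of `(z, y, x)` positions in mm.
#' @export
make_path <- function(kind, params = list(), seed = NULL) {
  kind <- match.arg(kind, c("straight", "sine", "helix", "random_walk"))
  if (!is.null(seed)) set.seed(seed)
  p <- params
  if (kind == "straight") {
    n <- if (is.null(p$n)) 100L else p$n
    t <- seq(0, 1, length.out = n)
    out <- outer(t, p$to - p$from) + matrix(p$from, n, 3, byrow = TRUE)
  } else if (kind == "sine") {
    n <- if (is.null(p$n)) 200L else p$n
    phase <- if (is.null(p$phase)) 0 else p$phase
    t <- seq(0, p$length, length.out = n)
    wig <- p$amplitude * sin(2 * pi * p$periods * t / p$length + phase) -
      p$amplitude * sin(phase)
    out <- cbind(p$start[1], p$start[2] + wig, p$start[3] + t)
  } else if (kind == "helix") {
    n <- if (is.null(p$n)) 500L else p$n
    phase <- if (is.null(p$phase)) 0 else p$phase
    t <- seq(0, 2 * pi * p$turns, length.out = n)
    out <- cbind(p$center[1] + p$radius * sin(t + phase),
                 p$center[2] + p$radius * cos(t + phase),
                 p$center[3] + p$pitch * t / (2 * pi))
  } else {
    n <- if (is.null(p$n)) 100L else p$n
    step <- if (is.null(p$step_mm)) 0.02 else p$step_mm
    wobble <- if (is.null(p$wobble)) 0.3 else p$wobble
    th <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n - 2, 0, wobble)))
    dz <- cumsum(c(0, rnorm(n - 1, 0, 0.1 * step)))
    out <- cbind(p$start[1] + dz,
                 p$start[2] + c(0, cumsum(step * sin(th))),
                 p$start[3] + c(0, cumsum(step * cos(th))))
  }
  colnames(out) <- c("z", "y", "x")
  out
}

#' Rasterize a tube around a polyline
#'
#' Marks every voxel whose center lies within `radius_mm` (anisotropic
#' physical distance) of the densely resampled path.
#'
#' @param path n x 3 `(z, y, x)` mm matrix, inside the volume.
#' @param radius_mm tube radius, at least half the smallest voxel spacing.
#' @param grid a [voxel_grid()].
#' @return A [vessel_mask()].
#' @export
rasterize_tube <- function(path, radius_mm, grid) {
  if (radius_mm < 0.5 * min(grid$spacing))
    stop("radius below half the minimum voxel spacing (sub-voxel tube)")
  buf <- integer(prod(grid$shape))
  dim(buf) <- grid$shape
  stamp_tube_cpp(buf, grid$shape, grid$spacing, path, radius_mm)
  vessel_mask(buf, grid)
}

.path_len_inside_disk <- function(path, center, radius) {
  if (nrow(path) < 2L) return(0)
  mid <- (path[-1, 2:3, drop = FALSE] + path[-nrow(path), 2:3, drop = FALSE]) / 2
  seg <- .seg_lengths(path)
  inside <- sqrt((mid[, 1] - center[1])^2 + (mid[, 2] - center[2])^2) <= radius
  sum(seg[inside])
}

# Two layered plexus families (echoing the layered organization of cutaneous
# microvasculature): one family running along x in a shallow layer, one along
# y in a deeper layer. Layers are depth-separated so vessels of different
# families never touch, which keeps the lesion-free skeleton free of
# crossing-induced webbing - the even vascular distribution assumed for
# healthy skin.
.background_paths <- function(spec) {
  ext <- grid_extent(spec$grid)
  sp <- spec$background_vessel_spacing_mm
  # mild waviness: strong enough to exercise the tortuosity metrics, weak
  # enough that the bed keeps the even vascular density that operationally
  # defines lesion-free skin for the presence check
  amp <- 0.05 * sp
  pad <- max(spec$vessel_radius_range_mm) + amp + 0.02
  # plexus planes snapped to voxel-center depths: every vessel then meets
  # the sampling grid identically, so the discrete skeleton carries the
  # same voxels-per-length everywhere - the even-density healthy bed
  dz <- spec$grid$spacing[1]
  zlev <- (round(c(0.16, 0.76) * ext[1] / dz - 0.5) + 0.5) * dz
  zamp <- 0
  paths <- list()
  for (fam in 1:2) {
    axis <- c("x", "y")[fam]
    lat_ext <- if (axis == "x") ext[2] else ext[3]
    run_ext <- if (axis == "x") ext[3] else ext[2]
    nl <- floor(lat_ext / sp)
    pos <- (lat_ext - (nl - 1) * sp) / 2 + sp * (seq_len(nl) - 1)  # centered
    pos <- pos + rnorm(length(pos), 0, sp / 100)
    for (p0 in pos) {
      n <- 220L
      # vessels span the full extent; the rasterizer clips tubes at the
      # boundary, so no vessel-free margin biases border ROIs low
      t <- seq(0, run_ext, length.out = n)
      per <- runif(1, 1.5, 3.5)
      ph <- runif(1, 0, 2 * pi)
      lat <- p0 + amp * sin(2 * pi * per * t / run_ext + ph)
      lat <- pmin(pmax(lat, 0), lat_ext)
      zphase <- runif(1, 0, 2 * pi)  # RNG draw kept for stream stability
      z <- rep(zlev[fam], length(t))
      pm <- if (axis == "x") cbind(z, lat, t) else cbind(z, t, lat)
      colnames(pm) <- c("z", "y", "x")
      rr <- runif(1)   # RNG draw kept for stream stability
      paths[[length(paths) + 1L]] <-
        list(points_mm = pm,
             radius_mm = mean(spec$vessel_radius_range_mm))
    }
  }
  paths
}

# fine capillaries confined to the annulus r_in..r_out around the lesion
# center (r_in = 0 gives the full disk); used for the dense sBCC focus and
# for the peripheral arborizing-vessel rim of nodular lesions
.lesion_capillaries <- function(spec, target_len, r_in, r_out) {
  ext <- grid_extent(spec$grid)
  cen <- spec$lesion_center_mm
  zc <- 0.50 * ext[1]   # between the two plexus layers
  out <- list()
  total <- 0
  while (total < target_len) {
    d <- sqrt(runif(1, (0.98 * r_in / r_out)^2, 0.85^2)) * r_out
    a <- runif(1, 0, 2 * pi)
    c0 <- cen + d * c(cos(a), sin(a))
    th <- runif(1, 0, pi)
    len <- runif(1, 0.3, 0.8)
    n <- 80L
    t <- seq(-len / 2, len / 2, length.out = n)
    amp <- runif(1, 0.01, 0.04)
    ph <- runif(1, 0, 2 * pi)
    wig <- amp * sin(2 * pi * t / len * runif(1, 1, 2) + ph)
    y <- c0[1] + t * cos(th) - wig * sin(th)
    x <- c0[2] + t * sin(th) + wig * cos(th)
    z <- zc + 0.04 * ext[1] * sin(2 * pi * t / len + runif(1, 0, 2 * pi))
    rr <- sqrt((y - cen[1])^2 + (x - cen[2])^2)
    keep <- rr <= r_out * 0.98 & rr >= r_in &
      y >= 0 & y <= ext[2] & x >= 0 & x <= ext[3]
    if (sum(keep) < 2L) next
    runs <- .clip_runs(keep)
    for (k in seq_len(nrow(runs))) {
      rn <- runs[k, ]
      if (rn[2] - rn[1] + 1L < 2L) next
      pm <- cbind(z[rn[1]:rn[2]], y[rn[1]:rn[2]], x[rn[1]:rn[2]])
      colnames(pm) <- c("z", "y", "x")
      r <- runif(1, 0.7 * spec$vessel_radius_range_mm[1],
                 spec$vessel_radius_range_mm[1])
      r <- max(r, 0.55 * min(spec$grid$spacing))
      out[[length(out) + 1L]] <- list(points_mm = pm, radius_mm = r)
      total <- total + sum(.seg_lengths(pm))
    }
  }
  out
}

.cull_core <- function(paths, spec, keep_frac = 0) {
  cen <- spec$lesion_center_mm
  rl <- spec$lesion_radius_mm
  out <- list()
  for (p in paths) {
    pm <- p$points_mm
    inside <- abs(pm[, 2] - cen[1]) <= rl   # vessel-poor band, full x range
    if (!any(inside) || runif(1) < keep_frac) {
      out[[length(out) + 1L]] <- p
      next
    }
    runs <- .clip_runs(!inside)
    for (k in seq_len(nrow(runs))) {
      rn <- runs[k, ]
      if (rn[2] - rn[1] + 1L < 2L) next
      out[[length(out) + 1L]] <- list(points_mm = pm[rn[1]:rn[2], , drop = FALSE],
                                      radius_mm = p$radius_mm)
    }
  }
  out
}

# short capillaries scattered uniformly inside the nodular band
.band_capillaries <- function(spec, target_len) {
  ext <- grid_extent(spec$grid)
  cen <- spec$lesion_center_mm
  rl <- spec$lesion_radius_mm
  zc <- 0.50 * ext[1]
  out <- list()
  total <- 0
  while (total < target_len) {
    c0 <- c(runif(1, cen[1] - 0.85 * rl, cen[1] + 0.85 * rl),
            runif(1, 0, ext[3]))
    th <- runif(1, 0, pi)
    len <- runif(1, 0.15, 0.4)
    n <- 60L
    t <- seq(-len / 2, len / 2, length.out = n)
    amp <- runif(1, 0.01, 0.03)
    wig <- amp * sin(2 * pi * t / len * runif(1, 1, 2) + runif(1, 0, 2 * pi))
    y <- c0[1] + t * cos(th) - wig * sin(th)
    x <- c0[2] + t * sin(th) + wig * cos(th)
    z <- zc + 0.04 * ext[1] * sin(2 * pi * t / len + runif(1, 0, 2 * pi))
    keep <- abs(y - cen[1]) <= rl * 0.98 & x >= 0 & x <= ext[3]
    if (sum(keep) < 2L) next
    runs <- .clip_runs(keep)
    for (k in seq_len(nrow(runs))) {
      rn <- runs[k, ]
      if (rn[2] - rn[1] + 1L < 2L) next
      pm <- cbind(z[rn[1]:rn[2]], y[rn[1]:rn[2]], x[rn[1]:rn[2]])
      colnames(pm) <- c("z", "y", "x")
      r <- max(0.7 * spec$vessel_radius_range_mm[1],
               0.55 * min(spec$grid$spacing))
      out[[length(out) + 1L]] <- list(points_mm = pm, radius_mm = r)
      total <- total + sum(.seg_lengths(pm))
    }
  }
  out
}

.disk_mask_2d <- function(grid, center, radius) {
  ny <- grid$shape[2]; nx <- grid$shape[3]
  yy <- ((seq_len(ny) - 0.5) * grid$spacing[2] - center[1])^2
  xx <- ((seq_len(nx) - 0.5) * grid$spacing[3] - center[2])^2
  outer(yy, xx, `+`) <= radius^2
}

#' Generate a synthetic OCTA phantom with ground truth
#'
#' Builds the vessel-path set for the requested kind, rasterizes the tubes,
#' applies a soft intensity profile (Gaussian falloff of width 10 um beyond
#' the tube wall), multiplicative exponential speckle and additive Gaussian
#' noise, and records the ground truth. All randomness derives from
#' `spec$seed`; regeneration is bit-identical and the caller's RNG state is
#' left untouched.
#'
#' @param spec a [phantom_spec()].
#' @return list (class `octa_phantom`) with `volume` (an [octa_volume()])
#'   and `truth`: `vessel_mask`, `centerlines` (list of `points_mm`,
#'   `radius_mm`), `lesion_mask_2d`, `lesion_centroid_mm`, `kind`, `seed`.
#' @export
make_phantom <- function(spec) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(spec$seed)
  grid <- spec$grid
  ext <- grid_extent(grid)
  if (spec$kind == "single_tube") {
    r <- spec$vessel_radius_range_mm[1]
    path <- make_path("straight",
                      list(from = c(ext[1] / 2, ext[2] / 2, r + 2 * grid$spacing[3]),
                           to = c(ext[1] / 2, ext[2] / 2, ext[3] - r - 2 * grid$spacing[3]),
                           n = 200L))
    paths <- list(list(points_mm = path, radius_mm = r))
  } else if (spec$kind == "tube_set") {
    r <- spec$vessel_radius_range_mm[1]
    ys <- ext[2] * seq_len(spec$n_tubes) / (spec$n_tubes + 1)
    paths <- lapply(ys, function(y0) {
      list(points_mm = make_path("straight",
                                 list(from = c(ext[1] / 2, y0, r + 2 * grid$spacing[3]),
                                      to = c(ext[1] / 2, y0, ext[3] - r - 2 * grid$spacing[3]),
                                      n = 200L)),
           radius_mm = r)
    })
  } else {
    paths <- .background_paths(spec)
    if (spec$kind == "sbcc") {
      bg_inside <- sum(vapply(paths, function(p)
        .path_len_inside_disk(p$points_mm, spec$lesion_center_mm,
                              spec$lesion_radius_mm), 0))
      extra <- (spec$lesion_density_multiplier - 1) * bg_inside
      paths <- c(paths, .lesion_capillaries(spec, extra, 0,
                                            spec$lesion_radius_mm))
    } else if (spec$kind == "nbcc") {
      # remove all vasculature inside the band, then restore the residual
      # density as scattered short capillaries: the vessel-poor core is
      # then uniformly poor, not lumpy with surviving whole vessels
      cen <- spec$lesion_center_mm; rl <- spec$lesion_radius_mm
      in_band_len <- sum(vapply(paths, function(p) {
        pm <- p$points_mm
        if (nrow(pm) < 2L) return(0)
        mid <- (pm[-1, 2] + pm[-nrow(pm), 2]) / 2
        sum(.seg_lengths(pm)[abs(mid - cen[1]) <= rl])
      }, 0))
      paths <- .cull_core(paths, spec, keep_frac = 0)
      paths <- c(paths, .band_capillaries(
        spec, spec$lesion_density_multiplier * in_band_len))
    }
  }
  buf <- integer(prod(grid$shape))
  dim(buf) <- grid$shape
  for (p in paths)
    stamp_tube_cpp(buf, grid$shape, grid$spacing, p$points_mm,
                   max(p$radius_mm, 0.51 * min(grid$spacing)))
  mask <- vessel_mask(buf, grid)
  # imaging model: binary flow signal blurred by the system point spread
  # function (axial sigma ~8 um from the ~18.5 um axial resolution in
  # tissue, lateral sigma ~23 um from the ~55 um lateral resolution),
  # multiplied by PSF-correlated speckle, plus additive detection noise
  psf_vox <- c(0.008, 0.023, 0.023) / grid$spacing
  intens <- gauss_smooth_cpp(as.numeric(mask$data), grid$shape, psf_vox)
  n <- length(intens)
  w <- spec$noise$speckle_scale
  if (w > 0) {
    spk <- gauss_smooth_cpp(rexp(n), grid$shape, psf_vox)
    spk <- spk / mean(spk)
    intens <- intens * ((1 - w) + w * spk)
  }
  intens <- intens + rnorm(n, 0, spec$noise$gaussian_sigma)
  vol <- octa_volume(array(pmax(intens, 0), dim = grid$shape), grid)
  lesion2d <- NULL
  centroid <- NULL
  if (spec$kind == "sbcc") {
    lesion2d <- .disk_mask_2d(grid, spec$lesion_center_mm,
                              spec$lesion_radius_mm)
    centroid <- spec$lesion_center_mm
  } else if (spec$kind == "nbcc") {
    yy <- abs((seq_len(grid$shape[2]) - 0.5) * grid$spacing[2] -
                spec$lesion_center_mm[1]) <= spec$lesion_radius_mm
    lesion2d <- matrix(yy, grid$shape[2], grid$shape[3])
    centroid <- c(spec$lesion_center_mm[1], ext[3] / 2)
  }
  structure(list(volume = vol,
                 truth = list(vessel_mask = mask, centerlines = paths,
                              lesion_mask_2d = lesion2d,
                              lesion_centroid_mm = centroid,
                              kind = spec$kind, seed = spec$seed)),
            class = "octa_phantom")
}
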