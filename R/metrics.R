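#' Region of interest box
#'
#' An axis-aligned box in physical coordinates. Voxel bounds are derived
#' half-open with round-half-up at each face and clipped to the volume.
#'
#' @param origin_mm `(z, y, x)` origin in mm.
#' @param size_mm `(dz, dy, dx)` size in mm, all > 0.
#' @return A `roi_box` object.
#' @export
roi_box <- function(origin_mm, size_mm) {
  origin_mm <- as.numeric(origin_mm); size_mm <- as.numeric(size_mm)
  if (length(origin_mm) != 3L || length(size_mm) != 3L)
    stop("origin and size must have 3 components (z, y, x)")
  if (any(size_mm <= 0)) stop("all size components must be > 0")
  structure(list(origin_mm = origin_mm, size_mm = size_mm), class = "roi_box")
}

#' Voxel index bounds of an ROI
#'
#' @param roi a [roi_box()].
#' @param grid a [voxel_grid()].
#' @return list with 1-based inclusive `lo`, `hi` (z, y, x) and `n_vox`, the
#'   unclipped voxel count of the box; errors if the ROI lies fully outside.
#' @export
roi_bounds <- function(roi, grid) {
  lo0 <- round_half_up(roi$origin_mm / grid$spacing)          # 0-based incl.
  hi0 <- round_half_up((roi$origin_mm + roi$size_mm) / grid$spacing) - 1
  lo <- pmax(lo0 + 1, 1L); hi <- pmin(hi0 + 1, grid$shape)
  if (any(hi < lo)) stop("ROI lies fully outside the volume")
  list(lo = as.integer(lo), hi = as.integer(hi),
       n_vox = prod(hi - lo + 1L))
}

.in_bounds <- function(vox, b) {
  vox[, 1] >= b$lo[1] & vox[, 1] <= b$hi[1] &
    vox[, 2] >= b$lo[2] & vox[, 2] <= b$hi[2] &
    vox[, 3] >= b$lo[3] & vox[, 3] <= b$hi[3]
}

#' Vascular density in an ROI
#'
#' Fraction of ROI voxels occupied by the skeleton.
#'
#' @param skel a `skeleton_mask`.
#' @param roi a [roi_box()].
#' @return numeric in `[0, 1]`.
#' @export
vascular_density <- function(skel, roi) {
  b <- roi_bounds(roi, skel$grid)
  sub <- skel$data[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3]]
  sum(sub != 0L) / b$n_vox
}

.dedup_path <- function(p) {
  if (nrow(p) < 2L) return(p)
  keep <- c(TRUE, rowSums(abs(diff(p))) > 0)
  p[keep, , drop = FALSE]
}

.smooth_path <- function(p, window) {
  if (window <= 1L || nrow(p) < 3L) return(p)
  h <- (window - 1L) %/% 2L
  n <- nrow(p)
  out <- p
  for (i in seq_len(n)) {
    r <- max(1L, i - h):min(n, i + h)
    out[i, ] <- colMeans(p[r, , drop = FALSE])
  }
  out
}

.seg_lengths <- function(p) sqrt(rowSums(diff(p)^2))

#' Two-dimensional distance metric (tortuosity)
#'
#' Ratio of the en-face projected path length to the projected endpoint
#' chord; 1 for a straight vessel, larger with increasing curvature.
#' Returns `NA` for closed paths (coincident projected endpoints).
#'
#' @param points n x 3 matrix of `(z, y, x)` positions in mm, n >= 2.
#' @return numeric >= 1, or `NA` when undefined.
#' @export
distance_metric <- function(points) {
  p <- .dedup_path(points[, c(2, 3), drop = FALSE])
  if (nrow(p) < 2L) return(NA_real_)
  chord <- sqrt(sum((p[nrow(p), ] - p[1, ])^2))
  if (chord == 0) return(NA_real_)
  sum(.seg_lengths(p)) / chord
}

#' Inflection count metric
#'
#' The distance metric multiplied by the number of inflection points of the
#' en-face projected path - sign changes of the z-component of the 2D cross
#' product of consecutive tangents, ignoring turns smaller than
#' `angle_floor` radians.
#'
#' @inheritParams distance_metric
#' @param smooth_window odd moving-average window applied to the projected
#'   path before tangent estimation (1 = none; the pipeline uses 3 on voxel
#'   paths to suppress grid staircase turns).
#' @param angle_floor angular noise floor in radians.
#' @return numeric >= 0, or `NA` when the path is too short.
#' @export
inflection_count_metric <- function(points, smooth_window = 1L,
                                    angle_floor = 1e-6) {
  p <- .dedup_path(points[, c(2, 3), drop = FALSE])
  if (nrow(p) < 4L) return(NA_real_)
  dm <- distance_metric(points)
  if (is.na(dm)) return(NA_real_)
  ps <- .dedup_path(.smooth_path(p, smooth_window))
  if (nrow(ps) < 4L) return(NA_real_)
  tg <- diff(ps)
  cross <- tg[-nrow(tg), 1] * tg[-1, 2] - tg[-nrow(tg), 2] * tg[-1, 1]
  dot <- rowSums(tg[-nrow(tg), , drop = FALSE] * tg[-1, , drop = FALSE])
  ang <- atan2(abs(cross), dot)
  s <- sign(cross)[ang > angle_floor]
  s <- s[s != 0]
  flips <- if (length(s) < 2L) 0L else sum(diff(s) != 0)
  dm * flips
}

#' Sum of angles metric
#'
#' Total 3D turning angle between successive tangent vectors, normalized by
#' the 3D path length (rad/mm); zero for straight vessels and large for
#' tightly coiled ones. Zero-length segments are collapsed first.
#'
#' @inheritParams inflection_count_metric
#' @return numeric >= 0 in rad/mm, or `NA` when undefined.
#' @export
sum_of_angles_metric <- function(points, smooth_window = 1L) {
  p <- .dedup_path(points)
  if (nrow(p) < 3L) return(NA_real_)
  p <- .dedup_path(.smooth_path(p, smooth_window))
  if (nrow(p) < 3L) return(NA_real_)
  tg <- diff(p)
  len <- sum(sqrt(rowSums(tg^2)))
  if (len == 0) return(NA_real_)
  a <- tg[-nrow(tg), , drop = FALSE]
  b <- tg[-1, , drop = FALSE]
  cosang <- rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
  sum(acos(pmin(pmax(cosang, -1), 1))) / len
}

.clip_runs <- function(flags) {
  # maximal runs of TRUE as (start, end) pairs
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

#' Quantitative vascular parameters within an ROI
#'
#' Evaluates the seven skeleton-based parameters: `NT` (26-connected
#' components of the skeleton restricted to the ROI), `NB` (branches with at
#' least one voxel inside), `VD` ([vascular_density()]), `MR` (mean radius
#' over skeleton voxels inside, mm), and the tortuosity means `DM`, `ICM`,
#' `SOAM` over branch segments clipped to the ROI that retain >= 4 points.
#' Metrics with no qualifying support are `NA`, never 0.
#'
#' @param graph a [build_graph()] result.
#' @param skel the matching `skeleton_mask`.
#' @param roi a [roi_box()].
#' @param smooth_window moving-average window for tangent estimation on
#'   voxel paths (default 3).
#' @return A `vascular_params` list: `NT`, `NB`, `VD`, `MR`, `DM`, `ICM`,
#'   `SOAM`, `n_branches_evaluated`.
#' @export
roi_params <- function(graph, skel, roi, smooth_window = 3L) {
  b <- roi_bounds(roi, graph$grid)
  sub <- skel$data[b$lo[1]:b$hi[1], b$lo[2]:b$hi[2], b$lo[3]:b$hi[3],
                   drop = FALSE]
  sub <- array(sub, dim = b$hi - b$lo + 1L)
  lab <- label_components_cpp(sub != 0L, dim(sub), 26L)
  nt <- attr(lab, "n_components")
  inside <- if (nrow(graph$voxels) > 0L) .in_bounds(graph$voxels, b) else logical(0)
  vd <- sum(sub != 0L) / b$n_vox
  mr <- if (any(inside)) mean(graph$radii_mm[inside], na.rm = TRUE) else NA_real_
  if (is.nan(mr)) mr <- NA_real_
  nb <- 0L
  dms <- numeric(0); icms <- numeric(0); soams <- numeric(0)
  nev <- 0L
  for (br in graph$branches) {
    fl <- inside[br$vox_rows]
    if (!any(fl)) next
    nb <- nb + 1L
    runs <- .clip_runs(fl)
    for (run in seq_len(nrow(runs))) {
      rn <- runs[run, ]
      if (rn[2] - rn[1] + 1L < 4L) next
      pts <- br$points_mm[rn[1]:rn[2], , drop = FALSE]
      nev <- nev + 1L
      dms <- c(dms, distance_metric(pts))
      icms <- c(icms, inflection_count_metric(pts, smooth_window))
      soams <- c(soams, sum_of_angles_metric(pts, smooth_window))
    }
  }
  mmean <- function(x) if (all(is.na(x)) || length(x) == 0L) NA_real_ else mean(x, na.rm = TRUE)
  structure(list(NT = nt, NB = nb, VD = vd, MR = mr,
                 DM = mmean(dms), ICM = mmean(icms), SOAM = mmean(soams),
                 n_branches_evaluated = nev),
            class = "vascular_params")
}

#' @export
print.vascular_params <- function(x, ...) {
  cat(sprintf("<vascular_params> NT=%d NB=%d VD=%.5g MR=%.4g mm DM=%.4g ICM=%.4g SOAM=%.4g rad/mm (n=%d)\n",
              x$NT, x$NB, x$VD, x$MR, x$DM, x$ICM, x$SOAM,
              x$n_branches_evaluated))
  invisible(x)
}

#' Per-branch summary table
#'
#' @param graph a [build_graph()] result.
#' @param smooth_window tangent-smoothing window for tortuosity metrics.
#' @return data.frame with one row per branch: tree, kind, point count,
#'   length (mm), mean radius (mm), DM, ICM, SOAM.
#' @export
branch_table <- function(graph, smooth_window = 3L) {
  n <- length(graph$branches)
  df <- data.frame(branch = seq_len(n), tree = NA_integer_,
                   kind = NA_character_, n_points = NA_integer_,
                   length_mm = NA_real_, mean_radius_mm = NA_real_,
                   DM = NA_real_, ICM = NA_real_, SOAM = NA_real_)
  for (i in seq_len(n)) {
    br <- graph$branches[[i]]
    df$tree[i] <- br$tree
    df$kind[i] <- br$kind
    df$n_points[i] <- nrow(br$points_mm)
    df$length_mm[i] <- if (nrow(br$points_mm) > 1L)
      sum(.seg_lengths(br$points_mm)) else 0
    df$mean_radius_mm[i] <- if (all(is.na(br$radii_mm))) NA_real_
    else mean(br$radii_mm, na.rm = TRUE)
    if (nrow(br$points_mm) >= 4L) {
      df$DM[i] <- distance_metric(br$points_mm)
      df$ICM[i] <- inflection_count_metric(br$points_mm, smooth_window)
      df$SOAM[i] <- sum_of_angles_metric(br$points_mm, smooth_window)
    }
  }
  df
}
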