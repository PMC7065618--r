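#' Build an overlapping ROI grid
#'
#' Tiles the en-face plane row-major with ROIs of `roi_size_mm`
#' (`(z, y, x)` order) and stride `size * (1 - overlap_frac)` in y and x.
#' The final row/column is shifted inward so the last ROI ends flush with
#' the volume boundary, keeping every ROI the same size (comparable VD
#' denominators). ROIs span the depth range `[z_origin_mm,
#' z_origin_mm + roi_size_mm[1])`, clipped to the volume.
#'
#' @param grid a [voxel_grid()] (typically of the depth-cropped volume).
#' @param roi_size_mm `(dz, dy, dx)` ROI size in mm; default the standard
#'   2.5 x 2.5 mm en-face by 0.3 mm depth box.
#' @param overlap_frac fractional overlap between juxtaposed ROIs
#'   (default 0.3).
#' @param z_origin_mm depth origin of every ROI (default 0).
#' @return A `roi_grid`: list of [roi_box()]es plus layout metadata.
#' @export
make_roi_grid <- function(grid, roi_size_mm = c(0.3, 2.5, 2.5),
                          overlap_frac = 0.3, z_origin_mm = 0) {
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("overlap_frac must be in [0, 1)")
  ext <- grid_extent(grid)
  sy <- roi_size_mm[2]; sx <- roi_size_mm[3]
  if (sy > ext[2] + 1e-9 || sx > ext[3] + 1e-9)
    stop("ROI larger than the volume en-face extent")
  starts <- function(extent, size) {
    stride <- size * (1 - overlap_frac)
    s <- seq(0, extent - size + 1e-12, by = stride)
    last <- extent - size
    if (last - s[length(s)] > 1e-9) s <- c(s, last)
    s
  }
  ys <- starts(ext[2], sy)
  xs <- starts(ext[3], sx)
  sz <- min(roi_size_mm[1], ext[1] - z_origin_mm)
  rois <- list()
  for (y0 in ys) for (x0 in xs)
    rois[[length(rois) + 1L]] <- roi_box(c(z_origin_mm, y0, x0),
                                         c(sz, sy, sx))
  structure(list(rois = rois, y_starts = ys, x_starts = xs,
                 roi_size_mm = c(sz, sy, sx), overlap_frac = overlap_frac,
                 grid = grid),
            class = "roi_grid")
}

#' @export
print.roi_grid <- function(x, ...) {
  cat(sprintf("<roi_grid> %d ROIs (%d x %d), size %.3g x %.3g x %.3g mm, overlap %.0f%%\n",
              length(x$rois), length(x$y_starts), length(x$x_starts),
              x$roi_size_mm[1], x$roi_size_mm[2], x$roi_size_mm[3],
              100 * x$overlap_frac))
  invisible(x)
}

#' Parameter heat map with overlap averaging
#'
#' Evaluates one vascular parameter per ROI and spreads each ROI's scalar
#' value over its en-face footprint; where footprints overlap, the
#' arithmetic mean of the contributing ROI values is reported. ROIs whose
#' parameter is undefined (`NA`) contribute nothing. Optionally paints the
#' averaged field onto skeleton and vessel voxels (the non-binary parameter
#' volumes used for rendering).
#'
#' @param graph a [build_graph()] result.
#' @param skel the matching `skeleton_mask`.
#' @param roigrid a [make_roi_grid()] result.
#' @param parameter one of `"NT"`, `"NB"`, `"VD"`, `"MR"`, `"DM"`, `"ICM"`,
#'   `"SOAM"`.
#' @param vessel optional [vessel_mask()] to paint a vessel heat volume.
#' @param smooth_window passed to [roi_params()].
#' @return A `heatmap2d`: `values` (ny x nx), `coverage` (covering-ROI
#'   count), `roi_values`, `parameter`, `grid`; plus `heat_skel` (and
#'   `heat_vessel` when `vessel` is given) painted 3D arrays.
#' @export
compute_heatmap <- function(graph, skel, roigrid, parameter = "VD",
                            vessel = NULL, smooth_window = 3L) {
  if (!parameter %in% c("NT", "NB", "VD", "MR", "DM", "ICM", "SOAM"))
    stop("unknown parameter: ", parameter)
  grid <- roigrid$grid
  ny <- grid$shape[2]; nx <- grid$shape[3]
  acc <- matrix(0, ny, nx)
  contrib <- matrix(0L, ny, nx)
  coverage <- matrix(0L, ny, nx)
  roi_values <- numeric(length(roigrid$rois))
  for (i in seq_along(roigrid$rois)) {
    roi <- roigrid$rois[[i]]
    p <- roi_params(graph, skel, roi, smooth_window = smooth_window)
    v <- p[[parameter]]
    roi_values[i] <- if (is.null(v)) NA_real_ else as.numeric(v)
    b <- roi_bounds(roi, grid)
    yr <- b$lo[2]:b$hi[2]; xr <- b$lo[3]:b$hi[3]
    coverage[yr, xr] <- coverage[yr, xr] + 1L
    if (!is.na(roi_values[i])) {
      acc[yr, xr] <- acc[yr, xr] + roi_values[i]
      contrib[yr, xr] <- contrib[yr, xr] + 1L
    }
  }
  values <- acc / contrib
  values[contrib == 0L] <- NA_real_
  hm <- structure(list(values = values, coverage = coverage,
                       roi_values = roi_values, parameter = parameter,
                       grid = grid),
                  class = "heatmap2d")
  hm$heat_skel <- .paint_heat(values, skel)
  if (!is.null(vessel)) hm$heat_vessel <- .paint_heat(values, vessel)
  hm
}

.paint_heat <- function(values, mask) {
  dims <- mask$grid$shape
  out <- array(0, dim = dims)
  idx <- which(mask$data != 0L)
  if (length(idx) > 0L) {
    coords <- arrayInd(idx, dims)
    v <- values[coords[, 2:3, drop = FALSE]]
    v[is.na(v)] <- 0
    out[idx] <- v
  }
  out
}

#' @export
print.heatmap2d <- function(x, ...) {
  cat(sprintf("<heatmap2d> %s, %d x %d px, value range [%.4g, %.4g], coverage 1..%d\n",
              x$parameter, nrow(x$values), ncol(x$values),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
              max(x$coverage)))
  invisible(x)
}

#' Normalize a heat map for display
#'
#' Divides values by their maximum. Display convenience only: lesion
#' detection thresholds are relative, so detection is invariant to this
#' scaling.
#'
#' @param map a `heatmap2d`.
#' @return The rescaled `heatmap2d` (max value 1).
#' @export
normalize_for_display <- function(map) {
  mx <- suppressWarnings(max(map$values, na.rm = TRUE))
  if (!is.finite(mx)) stop("heat map has no non-missing values")
  if (mx > 0) {
    map$values <- map$values / mx
    map$roi_values <- map$roi_values / mx
    if (!is.null(map$heat_skel)) map$heat_skel <- map$heat_skel / mx
    if (!is.null(map$heat_vessel)) map$heat_vessel <- map$heat_vessel / mx
  }
  map
}
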