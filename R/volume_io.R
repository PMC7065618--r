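#' Voxel-grid geometry
#'
#' Describes the sampling grid of an OCTA volume: voxel counts and physical
#' voxel spacing. Axis order is always `(z, y, x)` with `z` the depth axis
#' (increasing downward), `y` the slow (B-scan) axis and `x` the fast
#' (A-line) axis.
#'
#' @param shape integer vector `(nz, ny, nx)`, all >= 1.
#' @param spacing numeric vector `(dz, dy, dx)` in mm per voxel, all > 0.
#' @return An object of class `voxel_grid` with fields `shape` and `spacing`.
#' @export
voxel_grid <- function(shape, spacing) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || length(spacing) != 3L)
    stop("shape and spacing must each have 3 components (z, y, x)")
  if (any(shape < 1L)) stop("all shape components must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing components must be finite and > 0")
  structure(list(shape = shape, spacing = spacing), class = "voxel_grid")
}

#' Physical extent of a voxel grid in mm
#' @param grid a [voxel_grid()].
#' @return numeric `(z, y, x)` extent in mm.
#' @export
grid_extent <- function(grid) grid$shape * grid$spacing

#' OCTA intensity volume
#'
#' A 3D non-negative scalar field with attached voxel geometry. The array is
#' indexed `[z, y, x]`.
#'
#' @param data 3D numeric array, finite and >= 0, dim `(nz, ny, nx)`.
#' @param grid a [voxel_grid()]; if `NULL`, built from `spacing`.
#' @param spacing voxel spacing `(dz, dy, dx)` mm, used when `grid` is `NULL`.
#' @param depth_offset_mm depth of slice `z = 1` top below the original
#'   volume top (mm); updated when a depth window is cropped out.
#' @return An object of class `octa_volume`.
#' @export
octa_volume <- function(data, grid = NULL, spacing = NULL, depth_offset_mm = 0) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (is.null(grid)) {
    if (is.null(spacing)) stop("either grid or spacing must be given")
    grid <- voxel_grid(dim(data), spacing)
  }
  if (!identical(as.integer(dim(data)), grid$shape))
    stop("data shape does not match grid shape")
  if (any(!is.finite(data)) || any(data < 0))
    stop("volume values must be finite and >= 0")
  structure(list(data = data, grid = grid,
                 depth_offset_mm = as.numeric(depth_offset_mm)),
            class = "octa_volume")
}

#' Binary vessel / skeleton masks
#'
#' @param data 3D array coercible to 0/1.
#' @param grid a [voxel_grid()].
#' @param skeleton logical; if `TRUE` the object is classed `skeleton_mask`
#'   in addition to `vessel_mask`.
#' @return A `vessel_mask` (and possibly `skeleton_mask`) object with binary
#'   integer `data`.
#' @export
vessel_mask <- function(data, grid, skeleton = FALSE) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (!identical(as.integer(dim(data)), grid$shape))
    stop("data shape does not match grid shape")
  d <- array(as.integer(data != 0), dim = dim(data))
  cls <- if (skeleton) c("skeleton_mask", "vessel_mask") else "vessel_mask"
  structure(list(data = d, grid = grid), class = cls)
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels (z,y,x), spacing %.4g x %.4g x %.4g mm, extent %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$shape[1] * x$spacing[1], x$shape[2] * x$spacing[2],
              x$shape[3] * x$spacing[3]))
  invisible(x)
}

#' @export
print.octa_volume <- function(x, ...) {
  cat("<octa_volume>\n  ")
  print(x$grid)
  cat(sprintf("  depth offset %.4g mm, intensity range [%.4g, %.4g]\n",
              x$depth_offset_mm, min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<%s> %d foreground voxels\n  ", class(x)[1], sum(x$data)))
  print(x$grid)
  invisible(x)
}

.guess_format <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         tif = , tiff = "tiff",
         nii = "nifti",
         raw = , bin = "raw",
         stop("cannot infer volume format from extension '.", ext,
              "'; pass format explicitly"))
}

.sidecar_path <- function(path) paste0(path, ".json")

.write_sidecar <- function(path, grid, dtype, kind, depth_offset_mm,
                           provenance = NULL) {
  meta <- list(shape = grid$shape, spacing_mm = grid$spacing, dtype = dtype,
               kind = kind, depth_offset_mm = depth_offset_mm)
  if (!is.null(provenance)) meta$provenance <- provenance
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
}

.read_sidecar <- function(path) {
  sp <- .sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

.dtype_info <- function(dtype) {
  switch(dtype,
         float64 = list(size = 8L, what = "numeric", signed = TRUE),
         float32 = list(size = 4L, what = "numeric", signed = TRUE),
         uint8 = list(size = 1L, what = "integer", signed = FALSE),
         uint16 = list(size = 2L, what = "integer", signed = FALSE),
         int16 = list(size = 2L, what = "integer", signed = TRUE),
         stop("unsupported dtype: ", dtype))
}

#' Read an OCTA volume or mask
#'
#' Supported containers: multi-page grayscale TIFF (uncompressed, one image
#' per depth slice), NIfTI-1 (`.nii`, uncompressed, little-endian), and raw
#' little-endian binary with a mandatory JSON sidecar
#' (`<path>.json` holding `shape`, `spacing_mm`, `dtype`). TIFF volumes also
#' read the sidecar when present; without any metadata the native scanner
#' spacing (1.35/410, 9.57/512, 10/490 mm) is assumed with a warning.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"tiff"`, `"nifti"`, `"raw"`.
#' @param metadata optional [voxel_grid()] overriding sidecar/header geometry
#'   (mandatory for raw when no sidecar exists).
#' @param kind `"auto"`, `"intensity"` or `"mask"`; masks map on-disk
#'   `{0, 255}` to in-memory `{0, 1}` and return a [vessel_mask()].
#' @return An [octa_volume()] or [vessel_mask()].
#' @export
read_volume <- function(path, format = "auto", metadata = NULL,
                        kind = "auto") {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") format <- .guess_format(path)
  side <- .read_sidecar(path)
  if (kind == "auto") kind <- if (!is.null(side$kind)) side$kind else "intensity"
  res <- switch(format,
                raw = .read_raw(path, metadata, side),
                nifti = .read_nifti(path),
                tiff = .read_tiff(path, metadata, side),
                stop("unknown format: ", format))
  data <- res$data
  grid <- res$grid
  off <- if (!is.null(side$depth_offset_mm)) side$depth_offset_mm else res$depth_offset_mm
  if (!is.null(metadata)) grid <- metadata
  if (!identical(as.integer(dim(data)), grid$shape))
    stop("metadata shape ", paste(grid$shape, collapse = "x"),
         " does not match data shape ", paste(dim(data), collapse = "x"))
  if (identical(kind, "mask"))
    vessel_mask(data != 0, grid)
  else
    octa_volume(data, grid, depth_offset_mm = off)
}

.read_raw <- function(path, metadata, side) {
  if (is.null(side) && is.null(metadata))
    stop("raw volumes need a JSON sidecar (", .sidecar_path(path),
         ") or explicit metadata")
  if (!is.null(side)) {
    grid <- voxel_grid(side$shape, side$spacing_mm)
    dtype <- side$dtype
  } else {
    grid <- metadata
    dtype <- "float64"
  }
  info <- .dtype_info(dtype)
  nvox <- prod(grid$shape)
  expected <- nvox * info$size
  if (file.info(path)$size != expected)
    stop("raw file size ", file.info(path)$size,
         " does not match shape: expected ", expected, " bytes")
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = info$what, n = nvox, size = info$size,
               signed = info$signed, endian = "little")
  list(data = array(as.numeric(v), dim = grid$shape), grid = grid,
       depth_offset_mm = 0)
}

#' Write an OCTA volume or mask
#'
#' Round-trips exactly with [read_volume()] for each supported format.
#' Intensity volumes are stored as float64 (raw/NIfTI) or float32 (TIFF);
#' binary masks as 8-bit with `{0, 255}` coding on disk. A JSON sidecar with
#' shape, spacing, dtype and an optional provenance block accompanies raw and
#' TIFF files.
#'
#' @param vol an [octa_volume()] or [vessel_mask()].
#' @param path destination path; the parent directory must exist.
#' @param format `"auto"`, `"tiff"`, `"nifti"` or `"raw"`.
#' @param provenance optional named list recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = "auto", provenance = NULL) {
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  if (format == "auto") format <- .guess_format(path)
  is_mask <- inherits(vol, "vessel_mask")
  kind <- if (is_mask) "mask" else "intensity"
  off <- if (is.null(vol$depth_offset_mm)) 0 else vol$depth_offset_mm
  data <- if (is_mask) array(255L * (vol$data != 0), dim = dim(vol$data)) else vol$data
  switch(format,
         raw = {
           dtype <- if (is_mask) "uint8" else "float64"
           info <- .dtype_info(dtype)
           con <- file(path, "wb")
           v <- as.vector(data)
           if (info$what == "integer") v <- as.integer(v)
           writeBin(v, con, size = info$size, endian = "little")
           close(con)
           .write_sidecar(path, vol$grid, dtype, kind, off, provenance)
         },
         nifti = .write_nifti(path, data, vol$grid,
                              if (is_mask) "uint8" else "float64"),
         tiff = {
           dtype <- if (is_mask) "uint8" else "float32"
           .write_tiff(path, data, dtype)
           .write_sidecar(path, vol$grid, dtype, kind, off, provenance)
         },
         stop("unknown format: ", format))
  invisible(path)
}

# ---- minimal NIfTI-1 (.nii, single file, little-endian) -------------------

.nifti_codes <- c(uint8 = 2L, int16 = 4L, float32 = 16L, float64 = 64L,
                  uint16 = 512L)

.write_nifti <- function(path, data, grid, dtype) {
  code <- .nifti_codes[[dtype]]
  info <- .dtype_info(dtype)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(n) writeBin(raw(n), con)
  wi(348L, 4)                                   # sizeof_hdr    [0, 4)
  wc(36)                                        # unused + dim_info [4, 40)
  wi(c(3L, grid$shape, 1L, 1L, 1L, 1L), 2)      # dim[8], axes (z,y,x) [40, 56)
  wf(c(0, 0, 0)); wi(0L, 2)                     # intent_p*, intent_code [56, 70)
  wi(code, 2); wi(info$size * 8L, 2); wi(0L, 2) # datatype, bitpix, slice_start [70, 76)
  wf(c(1, grid$spacing, 0, 0, 0, 0))            # pixdim[8], mm [76, 108)
  wf(352); wf(0); wf(0)                         # vox_offset, scl_slope/inter [108, 120)
  wi(0L, 2); wc(1)                              # slice_end, slice_code [120, 123)
  writeBin(as.raw(2L), con)                     # xyzt_units = mm [123, 124)
  wf(c(0, 0, 0, 0))                             # cal_max/min, slice_dur, toffset [124, 140)
  wi(c(0L, 0L), 4)                              # glmax, glmin [140, 148)
  wc(80 + 24)                                   # descrip, aux_file [148, 252)
  wi(c(0L, 0L), 2)                              # qform_code, sform_code [252, 256)
  wf(rep(0, 6))                                 # quatern, qoffset [256, 280)
  wf(rep(0, 12))                                # srow_x/y/z [280, 328)
  wc(16)                                        # intent_name [328, 344)
  writeBin(charToRaw("n+1"), con); wc(1)        # magic [344, 348)
  wc(4)                                         # extender -> data at 352
  v <- as.vector(data)
  if (info$what == "integer") v <- as.integer(v)
  writeBin(v, con, size = info$size, endian = "little")
  invisible(path)
}

.read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 352)
  ri <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = "little")
  if (ri(0, 4) != 348L)
    stop("not a little-endian NIfTI-1 file (sizeof_hdr != 348)")
  dim8 <- ri(40, 2, 8)
  if (dim8[1] != 3L) stop("only 3D NIfTI volumes are supported")
  shape <- dim8[2:4]
  datatype <- ri(70, 2)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  dtype <- names(.nifti_codes)[match(datatype, .nifti_codes)]
  if (is.na(dtype)) stop("unsupported NIfTI datatype code: ", datatype)
  info <- .dtype_info(dtype)
  seek(con, where = vox_offset)
  v <- readBin(con, info$what, n = prod(shape), size = info$size,
               signed = info$signed, endian = "little")
  grid <- voxel_grid(shape, pixdim[2:4])
  list(data = array(as.numeric(v), dim = shape), grid = grid,
       depth_offset_mm = 0)
}

# ---- minimal baseline TIFF (classic, little-endian, uncompressed) ---------

.write_tiff <- function(path, data, dtype) {
  nz <- dim(data)[1]; ny <- dim(data)[2]; nx <- dim(data)[3]
  info <- .dtype_info(dtype)
  bits <- info$size * 8L
  fmt <- if (dtype %in% c("float32", "float64")) 3L else 1L
  slice_bytes <- ny * nx * info$size
  ifd_size <- 2L + 10L * 12L + 4L
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w16(42L)
  first_ifd <- 8L + slice_bytes
  w32(first_ifd)
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count); w32(value)
  }
  for (z in seq_len(nz)) {
    data_off <- 8L + (z - 1L) * (slice_bytes + ifd_size)
    v <- as.vector(t(data[z, , ]))   # row-major
    if (info$what == "integer") {
      writeBin(as.integer(v), con, size = info$size, endian = "little")
    } else {
      writeBin(as.numeric(v), con, size = info$size, endian = "little")
    }
    entry_count <- 10L
    w16(entry_count)
    entry(256L, 4L, 1L, nx)              # ImageWidth
    entry(257L, 4L, 1L, ny)              # ImageLength
    entry(258L, 3L, 1L, bits)            # BitsPerSample
    entry(259L, 3L, 1L, 1L)              # Compression: none
    entry(262L, 3L, 1L, 1L)              # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off)        # StripOffsets
    entry(277L, 3L, 1L, 1L)              # SamplesPerPixel
    entry(278L, 4L, 1L, ny)              # RowsPerStrip
    entry(279L, 4L, 1L, slice_bytes)     # StripByteCounts
    entry(339L, 3L, 1L, fmt)             # SampleFormat
    next_ifd <- if (z < nz) data_off + slice_bytes + ifd_size + slice_bytes else 0L
    w32(next_ifd)
  }
  invisible(path)
}

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `11` = 4L)

.read_tiff <- function(path, metadata, side) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  buf <- readBin(con, "raw", n = sz)
  if (rawToChar(buf[1:2]) != "II")
    stop("only little-endian TIFF is supported")
  r16 <- function(off) readBin(buf[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = "little")
  r32 <- function(off) readBin(buf[(off + 1):(off + 4)], "integer", size = 4,
                               endian = "little")
  ifd_off <- r32(4)
  slices <- list()
  while (ifd_off != 0) {
    nent <- r16(ifd_off)
    tags <- list()
    for (e in seq_len(nent)) {
      base <- ifd_off + 2 + (e - 1) * 12
      tag <- r16(base); type <- r16(base + 2); count <- r32(base + 4)
      tsize <- .tiff_type_size[as.character(type)]
      if (is.na(tsize)) next
      total <- tsize * count
      voff <- if (total <= 4) base + 8 else r32(base + 8)
      vals <- if (type == 3L) {
        vapply(seq_len(count) - 1L, function(i) r16(voff + 2 * i), 0L)
      } else if (type %in% c(4L, 11L)) {
        vapply(seq_len(count) - 1L, function(i) r32(voff + 4 * i), 0L)
      } else {
        as.integer(buf[(voff + 1):(voff + count)])
      }
      tags[[as.character(tag)]] <- vals
    }
    need <- function(t, default = NULL) {
      v <- tags[[as.character(t)]]
      if (is.null(v)) {
        if (is.null(default)) stop("TIFF missing required tag ", t)
        default
      } else v
    }
    if (need(259, 1L)[1] != 1L) stop("compressed TIFF is not supported")
    nx <- need(256); ny <- need(257)
    bits <- need(258, 8L)[1]
    fmt <- need(339, 1L)[1]
    offs <- need(273); counts <- need(279)
    bytespp <- bits %/% 8L
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      nsamp <- counts[s] %/% bytespp
      seg <- buf[(offs[s] + 1):(offs[s] + counts[s])]
      v <- if (fmt == 3L) {
        readBin(seg, "numeric", n = nsamp, size = bytespp, endian = "little")
      } else {
        readBin(seg, "integer", n = nsamp, size = bytespp,
                signed = bytespp >= 4L, endian = "little")
      }
      vals <- c(vals, as.numeric(v))
    }
    slices[[length(slices) + 1L]] <- matrix(vals, nrow = ny, ncol = nx,
                                            byrow = TRUE)
    ifd_off <- r32(ifd_off + 2 + nent * 12)
  }
  nz <- length(slices)
  ny <- nrow(slices[[1]]); nx <- ncol(slices[[1]])
  data <- array(0, dim = c(nz, ny, nx))
  for (z in seq_len(nz)) data[z, , ] <- slices[[z]]
  if (!is.null(side)) {
    grid <- voxel_grid(side$shape, side$spacing_mm)
  } else if (!is.null(metadata)) {
    grid <- metadata
  } else {
    warning("no spacing metadata for TIFF volume; assuming native scanner geometry (dz = 1.35/410, dy = 9.57/512, dx = 10/490 mm)")
    grid <- voxel_grid(c(nz, ny, nx), .default_spacing)
  }
  list(data = data, grid = grid, depth_offset_mm = 0)
}

# ---- en-face renderings ---------------------------------------------------

.slice_depths <- function(vol) {
  vol$depth_offset_mm + (seq_len(vol$grid$shape[1]) - 0.5) * vol$grid$spacing[1]
}

#' En-face maximum intensity projection
#'
#' @param vol an [octa_volume()].
#' @param depth_range_mm `(lo, hi)` depth window in mm (half-open,
#'   slice-center convention) or `NULL` for the full depth.
#' @return `ny x nx` numeric matrix of per-column maxima.
#' @export
mip_enface <- function(vol, depth_range_mm = NULL) {
  d <- .slice_depths(vol)
  sel <- if (is.null(depth_range_mm)) seq_along(d) else {
    if (depth_range_mm[1] >= depth_range_mm[2]) stop("empty depth range")
    which(d >= depth_range_mm[1] & d < depth_range_mm[2])
  }
  if (length(sel) == 0L) stop("empty depth range: no slice centers in window")
  out <- vol$data[sel[1], , ]
  for (z in sel[-1]) out <- pmax(out, vol$data[z, , ])
  out
}

#' Depth-coded en-face projection
#'
#' Renders the depth of the per-column brightest voxel as hue (shallow = hue
#' 0, red; deep = hue 0.7, blue) and its intensity as value, in HSV with full
#' saturation.
#'
#' @inheritParams mip_enface
#' @return `ny x nx x 3` RGB array in `[0, 1]`.
#' @export
depth_color_enface <- function(vol, depth_range_mm = NULL) {
  d <- .slice_depths(vol)
  sel <- if (is.null(depth_range_mm)) seq_along(d) else {
    if (depth_range_mm[1] >= depth_range_mm[2]) stop("empty depth range")
    which(d >= depth_range_mm[1] & d < depth_range_mm[2])
  }
  if (length(sel) == 0L) stop("empty depth range: no slice centers in window")
  best <- vol$data[sel[1], , ]
  argz <- array(sel[1], dim = dim(best))
  for (z in sel[-1]) {
    m <- vol$data[z, , ] > best
    best[m] <- vol$data[z, , ][m]
    argz[m] <- z
  }
  lo <- d[sel[1]]; hi <- d[sel[length(sel)]]
  frac <- if (hi > lo) (d[argz] - lo) / (hi - lo) else argz * 0
  val <- if (max(best) > 0) best / max(best) else best
  cols <- col2rgb(hsv(h = 0.7 * as.vector(frac), s = 1,
                      v = as.vector(val))) / 255
  out <- array(0, dim = c(dim(best), 3L))
  out[, , 1] <- cols[1, ]; out[, , 2] <- cols[2, ]; out[, , 3] <- cols[3, ]
  out
}

#' Write an en-face raster image
#'
#' Grayscale matrices are written as 16-bit binary PGM (P5), RGB arrays
#' (`ny x nx x 3`, values in `[0, 1]`) as 8-bit binary PPM (P6) - portable
#' formats with no compression dependency.
#'
#' @param img matrix or `ny x nx x 3` array.
#' @param path destination (`.pgm` / `.ppm` suggested).
#' @return `path`, invisibly.
#' @export
write_enface_image <- function(img, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (length(dim(img)) == 2L) {
    mx <- max(img)
    v <- if (mx > 0) img / mx else img
    writeBin(charToRaw(sprintf("P5\n%d %d\n65535\n", ncol(img), nrow(img))), con)
    writeBin(as.integer(round(t(v) * 65535)), con, size = 2, endian = "big")
  } else {
    writeBin(charToRaw(sprintf("P6\n%d %d\n255\n", ncol(img), nrow(img))), con)
    rgb <- as.integer(round(pmin(pmax(img, 0), 1) * 255))
    arr <- array(rgb, dim = dim(img))
    inter <- integer(3L * nrow(img) * ncol(img))
    k <- 1L
    for (y in seq_len(nrow(img))) for (x in seq_len(ncol(img))) {
      inter[k:(k + 2L)] <- arr[y, x, ]
      k <- k + 3L
    }
    writeBin(inter, con, size = 1)
  }
  invisible(path)
}
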