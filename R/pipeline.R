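#' Pipeline configuration
#'
#' Nested configuration with every published constant in exactly one place.
#' Unknown keys are rejected on construction and deserialization.
#'
#' @param ... named overrides, nested as in the defaults, e.g.
#'   `preprocess = list(window_mm = 0.25)`.
#' @param seed integer seed recorded with results.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(..., seed = 1L) {
  defaults <- list(
    preprocess = list(window_mm = 0.3, median_kernel = 3L,
                      frangi = list(scales = 1:5, alpha = 0.5, beta = 0.5,
                                    c = NULL, bright_on_dark = TRUE,
                                    scale_units = "inplane_px")),
    segmentation = list(window_frac = 1 / 8, sensitivity = 0.15,
                        min_object_vox = 27L, slice_axis = "enface",
                        close_radius_mm = 0.02, fill_lumen = TRUE,
                        quantize_bits = 8L, max_hole_px = 200L,
                        min_value_frac = 0.15),
    skeleton = list(prune_spur_vox = 5L),
    metrics = list(smooth_window = 3L),
    heatmap = list(roi_size_mm = c(0.3, 2.5, 2.5), overlap_frac = 0.3),
    detection = list(vd_std_lim = 4e-5, sbcc_thr_frac = 0.75,
                     nbcc_init_frac = 0.20, nbcc_step_frac = 0.30,
                     disk_radius_px = 20L, min_component_px = 10L,
                     center_rule = "extremum_in_mask"),
    seed = 1L)
  over <- list(...)
  over$seed <- seed
  cfg <- .merge_config(defaults, over, path = "")
  structure(cfg, class = "pipeline_config")
}

.merge_config <- function(base, over, path) {
  for (nm in names(over)) {
    if (!nm %in% names(base))
      stop("unknown config key: ", sub("^\\.", "", paste0(path, ".", nm)))
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]])) &&
        is.list(over[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], over[[nm]],
                                  paste0(path, ".", nm))
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file.
#' @return [read_config()]: a `pipeline_config`; unknown keys error.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  seed <- if (!is.null(raw$seed)) raw$seed else 1L
  raw$seed <- NULL
  do.call(pipeline_config, c(raw, list(seed = seed)))
}

#' @rdname read_config
#' @param cfg a `pipeline_config`.
#' @return [write_config()]: `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

.stage <- function(name, expr, log = NULL) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  if (!is.null(log))
    log(sprintf("stage %-14s %6.2f s", name,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full lesion-determination pipeline
#'
#' Depth window, 3D median, Frangi enhancement, slice-wise adaptive
#' segmentation, skeletonization, radius estimation, graph decomposition,
#' overlapping-ROI VD heat map, presence check, subtype classification,
#' subtype-specific lesion-area extraction, morphological refinement, and
#' lesion/healthy ROI parameter reports.
#'
#' @param vol an [octa_volume()].
#' @param config a [pipeline_config()].
#' @param verbose print per-stage timing.
#' @param keep_intermediate attach masks, graph and heat map to the result.
#' @return A `lesion_result`: `present`, `subtype` (`"sBCC"`, `"nBCC"` or
#'   `"none"`), `vd_std`, `lesion_mask` (en-face logical, `NULL` when
#'   absent), `lesion_roi`, `healthy_roi`, `lesion_params`,
#'   `healthy_params`, `centroid_mm`, `thresholds`, `config`.
#' @export
run_pipeline <- function(vol, config = pipeline_config(), verbose = FALSE,
                         keep_intermediate = FALSE) {
  log <- if (verbose) function(msg) message(msg) else NULL
  pp <- config$preprocess
  win <- .stage("depth_window",
                select_depth_window(vol, pp$window_mm), log)
  med <- .stage("median3d", median3d(win, pp$median_kernel), log)
  fr <- .stage("frangi", {
    fc <- frangi_config(pp$frangi$scales, pp$frangi$alpha, pp$frangi$beta,
                        pp$frangi$c, pp$frangi$bright_on_dark,
                        pp$frangi$scale_units)
    frangi_vesselness(med, fc)
  }, log)
  sg <- config$segmentation
  mask <- .stage("segmentation",
                 segment_vessels(fr, sg$window_frac, sg$sensitivity,
                                 sg$min_object_vox, sg$slice_axis,
                                 sg$close_radius_mm, sg$fill_lumen,
                                 sg$quantize_bits, sg$max_hole_px,
                                 sg$min_value_frac), log)
  skel <- .stage("skeletonize", skeletonize(mask), log)
  radii <- .stage("radii", estimate_radii(mask, skel), log)
  graph <- .stage("graph",
                  build_graph(skel, radii, config$skeleton$prune_spur_vox),
                  log)
  roigrid <- .stage("roi_grid",
                    make_roi_grid(skel$grid, config$heatmap$roi_size_mm,
                                  config$heatmap$overlap_frac), log)
  vd_map <- .stage("vd_heatmap",
                   compute_heatmap(graph, skel, roigrid, "VD",
                                   smooth_window = config$metrics$smooth_window),
                   log)
  dcfg <- detection_config(
    vd_std_lim = config$detection$vd_std_lim,
    sbcc_thr_frac = config$detection$sbcc_thr_frac,
    nbcc_init_frac = config$detection$nbcc_init_frac,
    nbcc_step_frac = config$detection$nbcc_step_frac,
    disk_radius_px = config$detection$disk_radius_px,
    roi_size_mm = config$heatmap$roi_size_mm,
    min_component_px = config$detection$min_component_px,
    center_rule = config$detection$center_rule)
  pres <- .stage("presence", lesion_present(vd_map, skel, dcfg), log)
  res <- list(present = pres$present, subtype = "none",
              vd_std = pres$vd_std, lesion_mask = NULL, lesion_roi = NULL,
              healthy_roi = NULL, lesion_params = NULL,
              healthy_params = NULL, centroid_mm = NULL,
              thresholds = list(vd_std_lim = dcfg$vd_std_lim),
              config = config)
  if (pres$present) {
    subtype <- .stage("subtype", classify_subtype(vd_map, dcfg), log)
    lmask <- .stage("lesion_area", {
      if (subtype == "sBCC") detect_sbcc_area(vd_map, dcfg)
      else detect_nbcc_area(vd_map, dcfg)
    }, log)
    lroi <- .stage("lesion_roi",
                   place_lesion_roi(vd_map, lmask, subtype, dcfg), log)
    hroi <- .stage("healthy_roi",
                   place_healthy_roi(roigrid, lmask, allow_overlap = TRUE),
                   log)
    sw <- config$metrics$smooth_window
    res$subtype <- subtype
    res$lesion_mask <- lmask
    res$lesion_roi <- lroi
    res$healthy_roi <- hroi
    res$lesion_params <- .stage("lesion_params",
                                roi_params(graph, skel, lroi, sw), log)
    res$healthy_params <- .stage("healthy_params",
                                 roi_params(graph, skel, hroi, sw), log)
    cc <- which(lmask, arr.ind = TRUE)
    res$centroid_mm <- c(mean((cc[, 1] - 0.5) * skel$grid$spacing[2]),
                         mean((cc[, 2] - 0.5) * skel$grid$spacing[3]))
    res$thresholds$lesion_threshold <- attr(lmask, "threshold")
    if (!is.null(attr(lmask, "trace")))
      res$thresholds$nbcc_trace <- attr(lmask, "trace")
  }
  if (keep_intermediate) {
    res$intermediate <- list(window = win, vesselness = fr, mask = mask,
                             skeleton = skel, radii = radii, graph = graph,
                             roigrid = roigrid, vd_map = vd_map)
  }
  structure(res, class = "lesion_result")
}

#' @export
print.lesion_result <- function(x, ...) {
  cat(sprintf("<lesion_result> present=%s subtype=%s vd_std=%.3g\n",
              x$present, x$subtype, x$vd_std))
  if (x$present) {
    cat(sprintf("  lesion centroid (y, x) = (%.2f, %.2f) mm\n",
                x$centroid_mm[1], x$centroid_mm[2]))
    cat("  lesion:  "); print(x$lesion_params)
    cat("  healthy: "); print(x$healthy_params)
  }
  invisible(x)
}

.params_to_list <- function(p) {
  if (is.null(p)) return(NULL)
  lapply(unclass(p), function(v) if (is.null(v)) NULL else v)
}

#' Serialize a lesion result to JSON
#'
#' Writes presence, subtype, VD standard deviation, thresholds (including
#' the nBCC iteration trace), ROI boxes and both parameter sets. The lesion
#' mask itself is written separately as an image.
#'
#' @param result a `lesion_result`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path) {
  roi_to_list <- function(r) if (is.null(r)) NULL else
    list(origin_mm = r$origin_mm, size_mm = r$size_mm)
  out <- list(present = result$present, subtype = result$subtype,
              vd_std = result$vd_std,
              centroid_mm = result$centroid_mm,
              thresholds = result$thresholds,
              lesion_roi = roi_to_list(result$lesion_roi),
              healthy_roi = roi_to_list(result$healthy_roi),
              lesion_params = .params_to_list(result$lesion_params),
              healthy_params = .params_to_list(result$healthy_params),
              config = unclass(result$config))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
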