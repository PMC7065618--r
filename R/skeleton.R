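#' Reduce a vessel mask to its medial-axis skeleton
#'
#' Topology-preserving sequential 3D thinning: border voxels that are simple
#' points (removal changes neither foreground 26-connectivity nor background
#' 6-connectivity in their neighborhood) are deleted in order of increasing
#' distance-to-background, so the surviving 1-voxel-wide curves run along the
#' tube centers. Curve endpoints (at most one foreground neighbor) are
#' preserved. The number of 26-connected components is invariant.
#'
#' @param mask a [vessel_mask()].
#' @return A `skeleton_mask` (subclass of `vessel_mask`).
#' @export
skeletonize <- function(mask) {
  dims <- mask$grid$shape
  fg <- mask$data != 0L
  if (!any(fg)) return(vessel_mask(array(0L, dims), mask$grid, skeleton = TRUE))
  # distance-to-background priority, with the outside of the volume counted
  # as background (one-voxel pad) so clipped vessels at the faces do not
  # attract spurious medial sheets
  padded <- array(TRUE, dims + 2L)
  padded[2:(dims[1] + 1L), 2:(dims[2] + 1L), 2:(dims[3] + 1L)] <- !fg
  prip <- dist_to_set_cpp(padded, dims + 2L, mask$grid$spacing)
  pri <- array(prip, dims + 2L)[2:(dims[1] + 1L), 2:(dims[2] + 1L),
                                2:(dims[3] + 1L)]
  # smooth the priority (ordering only - topology is decided by the simple-
  # point test): wall roughness perturbs the raw distance ridge by a
  # sub-voxel amount per column, which would make the surviving curve
  # dither between adjacent depth levels; a small Gaussian restores a
  # coherent, centered ridge
  pri <- array(gauss_smooth_cpp(as.numeric(pri), dims, c(3, 3, 3)), dims)
  # hierarchical sub-resolution tie-break (z, then y): when the medial set
  # is degenerate (tube axis between voxels, or a flat distance plateau in
  # an elongated cross-section), removal order would otherwise let diagonal
  # shortcuts straighten and then consume the curve; the bias makes the
  # surviving position unique and spatially coherent. Magnitude ~1e-5 mm,
  # far below any genuine distance difference (>= 1e-4 mm).
  zi <- slice.index(pri, 1); yi <- slice.index(pri, 2)
  pri <- pri + 1e-7 * zi + 1e-9 * yi
  out <- thin3d_cpp(fg, dims, as.numeric(pri))
  vessel_mask(array(as.integer(out), dims), mask$grid, skeleton = TRUE)
}

#' Estimate per-point vessel radii
#'
#' Radius at each skeleton voxel is the anisotropic Euclidean distance (mm,
#' voxel spacing aware) to the nearest background voxel of the vessel mask,
#' capped at half the volume diagonal for degenerate all-foreground input.
#'
#' @param mask the [vessel_mask()] the skeleton came from.
#' @param skel the [skeletonize()] output; must satisfy `skel` subset of
#'   `mask`.
#' @return A `radius_map`: list with 1-based linear voxel `index`,
#'   `radius_mm` and the `grid`.
#' @export
estimate_radii <- function(mask, skel) {
  dims <- mask$grid$shape
  if (any(skel$data != 0L & mask$data == 0L))
    stop("skeleton voxel outside vessel mask")
  idx <- which(skel$data != 0L)
  d <- dist_to_set_cpp(mask$data == 0L, dims, mask$grid$spacing)
  cap <- 0.5 * sqrt(sum((dims * mask$grid$spacing)^2))
  structure(list(index = idx, radius_mm = pmin(d[idx], cap),
                 grid = mask$grid), class = "radius_map")
}

.vox_to_mm <- function(vox, spacing) {
  # voxel centers: 1-based index i -> (i - 0.5) * spacing
  sweep(vox - 0.5, 2, spacing, `*`)
}

#' Decompose a skeleton into trees, nodes and branches
#'
#' Nodes are skeleton voxels with 26-degree different from 2; branches are
#' the simple voxel paths between nodes (plus isolated cycles and isolated
#' voxels). Terminal branches shorter than `prune_spur_vox` voxels are
#' removed (thinning spurs) and the graph re-derived once. Trees are the
#' 26-connected components of the (pruned) skeleton. Every skeleton voxel is
#' owned by exactly one branch; shared junction voxels go to the incident
#' branch with the lexicographically smallest (z, y, x) first voxel.
#'
#' @param skel a `skeleton_mask` (thin: no fully occupied 2x2x2 block).
#' @param radii a [estimate_radii()] map (optional, `NULL` for unit radii).
#' @param prune_spur_vox spur-length threshold in voxels (default 5; 0
#'   disables pruning).
#' @return A `skeleton_graph`: list with `voxels` (n x 3, 1-based voxel
#'   indices), `degree`, `branches` (each with `vox_rows`, `points_mm`,
#'   `radii_mm`, `kind`, `tree`), `owner` (branch id per voxel), `tree_id`
#'   (per voxel), `n_trees`, `grid`.
#' @export
build_graph <- function(skel, radii = NULL, prune_spur_vox = 5L) {
  dims <- skel$grid$shape
  fg <- skel$data != 0L
  tr <- trace_graph_cpp(fg, dims)
  if (prune_spur_vox > 0L && length(tr$branches) > 0L) {
    drop_vox <- integer(0)
    for (b in tr$branches) {
      open <- b[1] != b[length(b)]
      d1 <- tr$degree[b[1]]; d2 <- tr$degree[b[length(b)]]
      terminal <- (length(b) == 1L) || (open && (d1 <= 1L || d2 <= 1L))
      if (terminal && length(b) < prune_spur_vox) {
        keep_ends <- b[c(1L, length(b))][c(d1, d2) >= 3L]
        drop_vox <- c(drop_vox, setdiff(b, keep_ends))
      }
    }
    if (length(drop_vox) > 0L) {
      lin <- tr$voxels[drop_vox, 1] +
        dims[1] * (tr$voxels[drop_vox, 2] - 1L) +
        dims[1] * dims[2] * (tr$voxels[drop_vox, 3] - 1L)
      fg[lin] <- FALSE
      tr <- trace_graph_cpp(fg, dims)
    }
  }
  vox <- tr$voxels
  nv <- nrow(vox)
  lin_idx <- if (nv > 0L) vox[, 1] + dims[1] * (vox[, 2] - 1L) +
    dims[1] * dims[2] * (vox[, 3] - 1L) else integer(0)
  rad <- rep(NA_real_, nv)
  if (!is.null(radii) && nv > 0L)
    rad <- radii$radius_mm[match(lin_idx, radii$index)]
  lab <- label_components_cpp(fg, dims, 26L)
  n_trees <- attr(lab, "n_components")
  tree_id <- if (nv > 0L) lab[lin_idx] else integer(0)

  nb <- length(tr$branches)
  branches <- vector("list", nb)
  first_key <- matrix(0L, nrow = max(nb, 1L), ncol = 3L)
  for (i in seq_len(nb)) {
    b <- tr$branches[[i]]
    closed <- length(b) > 1L && b[1] == b[length(b)]
    d1 <- tr$degree[b[1]]; d2 <- tr$degree[b[length(b)]]
    kind <- if (closed) "cycle"
    else if (d1 >= 3L && d2 >= 3L) "junction-junction"
    else if (d1 <= 1L && d2 <= 1L) "end-end"
    else "end-junction"
    branches[[i]] <- list(
      vox_rows = b,
      points_mm = .vox_to_mm(vox[b, , drop = FALSE], skel$grid$spacing),
      radii_mm = rad[b],
      kind = kind,
      tree = if (length(b) > 0L) tree_id[b[1]] else NA_integer_)
    first_key[i, ] <- vox[b[1], ]
  }
  owner <- rep(NA_integer_, nv)
  if (nb > 0L) {
    ord <- order(first_key[seq_len(nb), 1], first_key[seq_len(nb), 2],
                 first_key[seq_len(nb), 3], seq_len(nb))
    for (i in ord) {
      b <- branches[[i]]$vox_rows
      owner[b[is.na(owner[b])]] <- i
    }
  }
  structure(list(voxels = vox, degree = tr$degree, branches = branches,
                 owner = owner, tree_id = tree_id, n_trees = n_trees,
                 lin_idx = lin_idx, radii_mm = rad, grid = skel$grid),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d voxels, %d branches, %d trees\n",
              nrow(x$voxels), length(x$branches), x$n_trees))
  invisible(x)
}

#' Serialize a skeleton graph to JSON
#'
#' Trees -> branches -> point/radius arrays in mm coordinates.
#'
#' @param graph a [build_graph()] result.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  trees <- lapply(seq_len(graph$n_trees), function(t) {
    ids <- which(vapply(graph$branches, function(b) identical(b$tree, t), NA))
    list(tree = t, branches = lapply(graph$branches[ids], function(b) {
      list(kind = b$kind,
           points_mm = unname(b$points_mm),
           radii_mm = b$radii_mm)
    }))
  })
  jsonlite::write_json(list(spacing_mm = graph$grid$spacing,
                            shape = graph$grid$shape, trees = trees),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
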