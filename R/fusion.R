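#' Signed Euclidean distance map of a structure
#'
#' Per-voxel minimum Euclidean distance (mm, anisotropic spacing honored) to
#' the structure's border voxels, negative inside the object and exactly zero
#' on the border voxels themselves. Border voxels are object voxels
#' 6-connected to background (image boundary counts as background).
#'
#' @param mask a [binary_mask()]; must contain at least one object voxel and
#'   at least one border voxel (an all-object mask on a grid with no boundary
#'   exposure would have no border).
#' @return An object of class `signed_distance_map` with fields `grid` and
#'   `values` (3D array, mm).
#' @examples
#' g <- image_grid(c(9, 9, 9))
#' m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
#' d <- signed_distance(binary_mask(g, m))
#' d$values[5, 5, 5]  # 0 on the border voxel
#' @export
signed_distance <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$inside)) stop("mask is empty; no border exists")
  surf <- surface_array(mask$inside)
  if (!any(surf)) stop("mask has no border voxels")
  g <- mask$grid
  d <- sqrt(edt_sq_cpp(as.vector(surf), g$shape, g$spacing))
  d[as.vector(mask$inside)] <- -d[as.vector(mask$inside)]
  # border voxels are object voxels, hence negated to -0; force exact zero
  d[as.vector(surf)] <- 0
  structure(list(grid = g, values = array(d, g$shape)),
            class = "signed_distance_map")
}

#' Threshold a (fused) distance map back to a binary mask
#'
#' Voxels with value `<= 0` are object. The non-strict inequality keeps the
#' border layer, so a single structure's signed distance map round-trips to
#' the original mask exactly; the result may be empty.
#'
#' @param fused a `signed_distance_map` or `fused_distance_map`.
#' @return A [binary_mask()].
#' @export
extract_segmentation <- function(fused) {
  stopifnot(!is.null(fused$grid), !is.null(fused$values))
  binary_mask(fused$grid, fused$values <= 0)
}

#' Weighted fusion of signed distance maps
#'
#' Voxelwise weighted arithmetic mean of the input maps,
#' `D_fus = sum_j w_j D_j / sum_j w_j`. The consensus segmentation is the
#' iso-level-zero region of the result (see [extract_segmentation()]).
#'
#' @param maps list of `signed_distance_map` objects on a common grid.
#' @param weights non-negative weights, one per map, with positive sum;
#'   equal weights when omitted.
#' @return An object of class `fused_distance_map` with fields `grid`,
#'   `values` and `weights`.
#' @export
fuse_distance_maps <- function(maps, weights = NULL) {
  n <- length(maps)
  if (n < 1) stop("at least one distance map is required")
  if (is.null(weights)) weights <- rep(1, n)
  weights <- as.numeric(weights)
  if (length(weights) != n) stop("one weight per map is required")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) stop("weights must have a positive sum")
  g <- maps[[1]]$grid
  acc <- array(0, g$shape)
  for (j in seq_len(n)) {
    stop_if_grid_mismatch(g, maps[[j]]$grid, "distance maps")
    acc <- acc + weights[j] * maps[[j]]$values
  }
  structure(list(grid = g, values = acc / sum(weights), weights = weights),
            class = "fused_distance_map")
}

#' Fuse per-atlas binary masks into a consensus mask
#'
#' Convenience wrapper: signed distance map per mask, weighted mean,
#' iso-level-zero extraction. Atlases whose mask is empty for the structure
#' carry no shape information and are dropped with a warning; if all masks
#' are empty the consensus is empty.
#'
#' @param masks list of [binary_mask()] on a common grid.
#' @param weights non-negative weights, one per mask (before dropping);
#'   equal weights when omitted.
#' @return A [binary_mask()].
#' @export
fuse_masks <- function(masks, weights = NULL) {
  n <- length(masks)
  if (n < 1) stop("at least one mask is required")
  if (is.null(weights)) weights <- rep(1, n)
  nonempty <- vapply(masks, function(m) any(m$inside), logical(1))
  if (!any(nonempty)) {
    warning("all input masks are empty; returning an empty consensus")
    return(binary_mask(masks[[1]]$grid, array(FALSE, masks[[1]]$grid$shape)))
  }
  if (!all(nonempty))
    warning(sprintf("dropping %d empty mask(s) from fusion", sum(!nonempty)))
  maps <- lapply(masks[nonempty], signed_distance)
  extract_segmentation(fuse_distance_maps(maps, weights[nonempty]))
}

#' Majority-vote label fusion baseline
#'
#' A voxel belongs to the consensus iff strictly more than half of the input
#' masks mark it as object.
#'
#' @param masks list of [binary_mask()] on a common grid.
#' @return A [binary_mask()].
#' @export
majority_vote <- function(masks) {
  n <- length(masks)
  if (n < 1) stop("at least one mask is required")
  g <- masks[[1]]$grid
  acc <- array(0L, g$shape)
  for (m in masks) {
    stop_if_grid_mismatch(g, m$grid, "masks")
    acc <- acc + m$inside
  }
  binary_mask(g, acc > n / 2)
}
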