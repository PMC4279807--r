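#' Surface voxels of a binary mask
#'
#' A surface voxel is an object voxel that is 6-connected (shares a face)
#' with at least one background voxel; faces on the image boundary count as
#' background.
#'
#' @param mask a [binary_mask()].
#' @param as_mask return a [binary_mask()] instead of an index matrix.
#' @return By default an n-by-3 integer matrix of 0-based voxel indices of
#'   the surface voxels; an empty matrix for an empty mask.
#' @export
surface_voxels <- function(mask, as_mask = FALSE) {
  stopifnot(inherits(mask, "binary_mask"))
  surf <- surface_array(mask$inside)
  if (as_mask) return(binary_mask(mask$grid, surf))
  w <- which(surf) - 1L
  sh <- mask$grid$shape
  cbind(x = w %% sh[1],
        y = (w %/% sh[1]) %% sh[2],
        z = w %/% (sh[1] * sh[2]))
}

# logical array of 6-connected border voxels; image boundary counts as
# background
surface_array <- function(inside) {
  d <- dim(inside)
  shift_bg <- function(axis, dir) {
    # TRUE where the face-neighbor along (axis, dir) is background/out-of-image
    bg <- array(TRUE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (d[axis] > 1) {
      idx_src[[axis]] <- if (dir > 0) 2:d[axis] else 1:(d[axis] - 1)
      idx_dst[[axis]] <- if (dir > 0) 1:(d[axis] - 1) else 2:d[axis]
      bg[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
        !inside[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    }
    bg
  }
  nb_bg <- shift_bg(1, 1) | shift_bg(1, -1) | shift_bg(2, 1) |
    shift_bg(2, -1) | shift_bg(3, 1) | shift_bg(3, -1)
  inside & nb_bg
}

#' Dice similarity coefficient
#'
#' Overlap score `2|B1 n B2| / (|B1| + |B2|)`: 1 for identical segmentations,
#' 0 for disjoint ones. Two empty masks are treated as identical (DSC 1, with
#' a warning), which keeps evaluation stable when a warped structure leaves
#' the field of view.
#'
#' @param b1,b2 [binary_mask()] objects on the same grid.
#' @return DSC in \[0, 1\].
#' @examples
#' g <- image_grid(c(4, 4, 4))
#' a <- array(FALSE, c(4, 4, 4)); a[1:2, , ] <- TRUE
#' dsc(binary_mask(g, a), binary_mask(g, a))
#' @export
dsc <- function(b1, b2) {
  stopifnot(inherits(b1, "binary_mask"), inherits(b2, "binary_mask"))
  stop_if_grid_mismatch(b1$grid, b2$grid, "masks")
  n1 <- sum(b1$inside)
  n2 <- sum(b2$inside)
  if (n1 == 0 && n2 == 0) {
    warning("both masks are empty; DSC defined as 1")
    return(1)
  }
  2 * sum(b1$inside & b2$inside) / (n1 + n2)
}

# mm distance from each surface voxel of `from` to the nearest surface voxel
# of `to`, via the exact Euclidean distance transform seeded on `to`'s surface
surface_distances <- function(from, to) {
  g <- from$grid
  surf_to <- surface_array(to$inside)
  if (!any(surf_to)) stop("reference mask has no surface voxels")
  d2 <- edt_sq_cpp(as.vector(surf_to), g$shape, g$spacing)
  surf_from <- surface_array(from$inside)
  sqrt(d2[which(surf_from)])
}

#' Fractional mean absolute distance curve
#'
#' For each query distance, the fraction of `b1`'s surface voxels whose 3D
#' Euclidean distance (mm, honoring anisotropic spacing) to the nearest
#' surface voxel of `b2` is at most that distance. An asymmetric, cumulative
#' description of how far one segmentation's surface lies from a reference.
#'
#' @param b1 [binary_mask()] whose surface is queried; must be nonempty.
#' @param b2 [binary_mask()] providing the reference surface; must be
#'   nonempty.
#' @param distances ascending non-negative query distances in mm.
#' @return A data frame of class `fmad_curve` with columns `distance` and
#'   `fraction` (non-decreasing, in \[0, 1\]).
#' @export
fmad <- function(b1, b2, distances) {
  stopifnot(inherits(b1, "binary_mask"), inherits(b2, "binary_mask"))
  stop_if_grid_mismatch(b1$grid, b2$grid, "masks")
  distances <- as.numeric(distances)
  if (any(distances < 0) || is.unsorted(distances))
    stop("distances must be ascending and non-negative")
  if (!any(b1$inside)) stop("b1 is empty; fMAD is undefined")
  if (!any(b2$inside)) stop("b2 is empty; no reference surface")
  d <- surface_distances(b1, b2)
  frac <- vapply(distances, function(r) mean(d <= r), numeric(1))
  structure(data.frame(distance = distances, fraction = frac),
            class = c("fmad_curve", "data.frame"))
}
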