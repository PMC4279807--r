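#' Raster geometry shared by all image-like objects
#'
#' An `image_grid` describes the sampling lattice of a 3D raster: the number
#' of voxels along each axis, the physical voxel spacing in mm, and the world
#' coordinate (mm) of the voxel with index (0,0,0). Voxel indices are 0-based
#' and the world position of index `v` is `origin + v * spacing`; axes are
#' assumed aligned with the world frame (no direction matrix).
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 1).
#' @param spacing numeric vector of length 3, mm per voxel (each > 0).
#' @param origin numeric vector of length 3, world position of voxel (0,0,0)
#'   in mm. Defaults to the world origin.
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(c(64, 64, 48), spacing = c(2, 2, 3))
#' grid_extent(g)
#' @export
image_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3, length(spacing) == 3, length(origin) == 3)
  if (any(shape < 1L)) stop("grid shape entries must be >= 1")
  if (any(spacing <= 0)) stop("grid spacing entries must be > 0")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid: %s voxels, spacing (%s) mm, origin (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Physical extent of a grid
#'
#' World coordinates of the first and last voxel centers, per axis.
#'
#' @param grid an [image_grid()].
#' @return A 2x3 matrix with rows `lo` and `hi` (mm).
#' @export
grid_extent <- function(grid) {
  hi <- grid$origin + (grid$shape - 1) * grid$spacing
  rbind(lo = grid$origin, hi = hi)
}

same_grid <- function(a, b, tol = 1e-9) {
  all(a$shape == b$shape) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b)) stop(sprintf("%s are defined on different grids", what))
}

#' World coordinates of all voxel centers
#'
#' @param grid an [image_grid()].
#' @return An n-by-3 matrix of world coordinates (mm), ordered with the x
#'   index varying fastest so row `i` matches linear array index `i`.
#' @export
grid_points <- function(grid) {
  sh <- grid$shape
  ix <- rep.int(seq_len(sh[1]) - 1L, sh[2] * sh[3])
  iy <- rep.int(rep(seq_len(sh[2]) - 1L, each = sh[1]), sh[3])
  iz <- rep(seq_len(sh[3]) - 1L, each = sh[1] * sh[2])
  cbind(grid$origin[1] + ix * grid$spacing[1],
        grid$origin[2] + iy * grid$spacing[2],
        grid$origin[3] + iz * grid$spacing[3])
}

#' Convert world coordinates to (fractional) 0-based voxel indices
#'
#' @param grid an [image_grid()].
#' @param pts n-by-3 matrix of world coordinates (mm).
#' @return n-by-3 matrix of continuous voxel indices.
#' @export
world_to_index <- function(grid, pts) {
  sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/")
}

#' Scalar intensity image
#'
#' @param grid an [image_grid()].
#' @param values numeric 3D array with `dim(values) == grid$shape`.
#' @return An object of class `scalar_image`.
#' @export
scalar_image <- function(grid, values) {
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("value array shape does not match grid shape")
  values <- array(as.double(values), grid$shape) # plain array, no attributes
  structure(list(grid = grid, values = values), class = "scalar_image")
}

#' Integer label map
#'
#' Voxelwise structure membership: 0 is background, positive integers index
#' structures. Every nonzero label present in the raster must be named.
#'
#' @param grid an [image_grid()].
#' @param labels integer 3D array matching the grid shape.
#' @param structure_names named character vector mapping label (as name, e.g.
#'   `"1"`) to structure name. Missing names are filled as `structure_<label>`.
#' @return An object of class `label_map`.
#' @export
label_map <- function(grid, labels, structure_names = NULL) {
  if (!identical(as.integer(dim(labels)), grid$shape))
    stop("label array shape does not match grid shape")
  if (any(labels < 0)) stop("labels must be non-negative")
  labels <- array(as.integer(labels), grid$shape)
  present <- sort(unique(labels[labels > 0L]))
  nm <- structure_names
  if (is.null(nm)) nm <- character(0)
  missing <- setdiff(as.character(present), names(nm))
  if (length(missing)) {
    fill <- paste0("structure_", missing)
    names(fill) <- missing
    nm <- c(nm, fill)
  }
  structure(list(grid = grid, labels = labels, structure_names = nm),
            class = "label_map")
}

#' Binary structure mask
#'
#' @param grid an [image_grid()].
#' @param inside logical 3D array matching the grid shape.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, inside) {
  if (!identical(as.integer(dim(inside)), grid$shape))
    stop("mask array shape does not match grid shape")
  inside <- array(as.logical(inside), grid$shape)
  inside[is.na(inside)] <- FALSE
  structure(list(grid = grid, inside = inside), class = "binary_mask")
}

#' Split a label map into per-structure binary masks
#'
#' Each distinct nonzero label becomes one mask; together with the background
#' the masks partition the raster.
#'
#' @param labels a [label_map()].
#' @return Named list of [binary_mask()] objects, one per structure, in
#'   increasing label order.
#' @examples
#' g <- image_grid(c(4, 4, 4))
#' lab <- array(0L, c(4, 4, 4)); lab[1:2, , ] <- 1L; lab[4, , ] <- 2L
#' masks <- split_labels(label_map(g, lab))
#' names(masks)
#' @export
split_labels <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  present <- sort(unique(as.vector(labels$labels)))
  present <- present[present > 0L]
  out <- lapply(present, function(l)
    binary_mask(labels$grid, labels$labels == l))
  names(out) <- unname(labels$structure_names[as.character(present)])
  out
}

#' Assemble a label map from disjoint binary masks
#'
#' Inverse of [split_labels()] for disjoint masks; where masks overlap the
#' higher label wins.
#'
#' @param masks named list of [binary_mask()] on a common grid.
#' @param labels integer labels to assign, default `seq_along(masks)`.
#' @return A [label_map()].
#' @export
merge_masks <- function(masks, labels = seq_along(masks)) {
  stopifnot(length(masks) >= 1)
  g <- masks[[1]]$grid
  lab <- array(0L, g$shape)
  for (i in seq_along(masks)) {
    stop_if_grid_mismatch(g, masks[[i]]$grid, "masks")
    lab[masks[[i]]$inside] <- as.integer(labels[i])
  }
  nm <- as.character(names(masks))
  names(nm) <- as.character(labels)
  label_map(g, lab, structure_names = nm)
}

#' Number of object voxels in a mask
#' @param mask a [binary_mask()].
#' @return Integer count.
#' @export
mask_volume <- function(mask) sum(mask$inside)
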