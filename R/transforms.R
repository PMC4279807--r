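#' Cubic B-spline free-form deformation
#'
#' A deformable transform parameterized by 3-vector displacement coefficients
#' (mm) on a regular control-point lattice. The transform follows the
#' resampling (pull-back) convention: it maps fixed-space coordinates to
#' moving-space coordinates, `T(x) = x + d(x)` with `d` the cubic B-spline
#' expansion of the coefficients. Points outside the lattice support receive
#' zero displacement from the missing control points.
#'
#' The lattice is padded by one control point beyond the image domain on each
#' side so the cubic basis support covers the whole domain.
#'
#' @param domain [image_grid()] the transform is defined over.
#' @param control_spacing control-point spacing in mm (scalar or length 3);
#'   8 mm is a common choice for head-and-neck CT deformable registration.
#' @param coefficients optional n_ctrl-by-3 matrix of displacement
#'   coefficients (mm), row order x-fastest over the lattice; zeros (the
#'   identity transform) when omitted.
#' @return An object of class `bspline_transform`.
#' @examples
#' g <- image_grid(c(16, 16, 8), spacing = c(2, 2, 3))
#' t0 <- bspline_transform(g, control_spacing = 8)  # identity
#' @export
bspline_transform <- function(domain, control_spacing = 8, coefficients = NULL) {
  cs <- rep_len(as.numeric(control_spacing), 3)
  if (any(cs <= 0)) stop("control spacing must be positive")
  ext <- grid_extent(domain)
  # lattice index k sits at ctrl_origin + k*cs; need coverage of
  # [floor(u)-1, floor(u)+2] for all domain u
  ctrl_origin <- ext["lo", ] - cs
  nmax <- floor((ext["hi", ] - ctrl_origin) / cs)
  ctrl_shape <- as.integer(nmax + 3) + 1L
  n_ctrl <- prod(ctrl_shape)
  if (is.null(coefficients)) {
    coefficients <- matrix(0, n_ctrl, 3)
  } else {
    coefficients <- as.matrix(coefficients)
    if (nrow(coefficients) != n_ctrl || ncol(coefficients) != 3)
      stop(sprintf("coefficients must be a %d-by-3 matrix for this lattice", n_ctrl))
  }
  structure(list(ctrl_shape = ctrl_shape, ctrl_spacing = cs,
                 ctrl_origin = ctrl_origin, coefficients = coefficients,
                 domain = domain),
            class = "bspline_transform")
}

#' Dense displacement field
#'
#' Voxelwise 3-vector displacements (mm) on a grid; the transform maps
#' `x -> x + v(x)` with `v` trilinearly interpolated and edge-clamped outside
#' the grid.
#'
#' @param grid [image_grid()].
#' @param vectors numeric 4D array `c(grid$shape, 3)` of mm displacements;
#'   zeros (identity) when omitted.
#' @return An object of class `displacement_field`.
#' @export
displacement_field <- function(grid, vectors = NULL) {
  if (is.null(vectors)) vectors <- array(0, c(grid$shape, 3L))
  if (!identical(as.integer(dim(vectors)), c(grid$shape, 3L)))
    stop("vector array must have shape grid$shape x 3")
  vectors <- array(as.double(vectors), c(grid$shape, 3L))
  structure(list(grid = grid, vectors = vectors), class = "displacement_field")
}

#' Ordered chain of transforms
#'
#' The first transform is applied to fixed-space points first; with `m`
#' transforms the chain represents a registration linked through
#' `m - 1` intermediate images.
#'
#' @param ... transforms, or a single list of transforms.
#' @return An object of class `transform_chain` with element `n_links`, the
#'   number of intermediate transformations.
#' @export
transform_chain <- function(...) {
  ts <- list(...)
  if (length(ts) == 1 && is.list(ts[[1]]) && !is_transform(ts[[1]])) ts <- ts[[1]]
  if (length(ts) == 0) stop("a transform chain must contain at least one transform")
  ok <- vapply(ts, is_transform, logical(1))
  if (!all(ok)) stop("all chain elements must be transforms")
  structure(list(transforms = ts, n_links = length(ts) - 1L),
            class = "transform_chain")
}

is_transform <- function(x) {
  inherits(x, "bspline_transform") || inherits(x, "displacement_field") ||
    inherits(x, "transform_chain")
}

#' Displacement of a transform at world points
#'
#' @param t transform.
#' @param pts n-by-3 matrix of world coordinates (mm).
#' @return n-by-3 matrix of displacement vectors (mm).
#' @export
transform_displacement <- function(t, pts) {
  UseMethod("transform_displacement")
}

#' @export
transform_displacement.bspline_transform <- function(t, pts) {
  bspline_sample_cpp(pts, as.numeric(t$coefficients), t$ctrl_shape,
                     t$ctrl_origin, t$ctrl_spacing, 3L, TRUE)
}

#' @export
transform_displacement.displacement_field <- function(t, pts) {
  trilinear_sample_cpp(pts, as.numeric(t$vectors), t$grid$shape,
                       t$grid$origin, t$grid$spacing, 3L)
}

#' @export
transform_displacement.transform_chain <- function(t, pts) {
  transform_points(t, pts) - pts
}

#' Map world points through a transform
#'
#' Returns the moving-space coordinates corresponding to fixed-space points:
#' `x + d(x)` for a single transform, and the successive application of each
#' member for a chain.
#'
#' @param t a `bspline_transform`, `displacement_field` or `transform_chain`.
#' @param pts n-by-3 matrix of world coordinates (mm).
#' @return n-by-3 matrix of mapped world coordinates (mm).
#' @export
transform_points <- function(t, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  if (inherits(t, "transform_chain")) {
    for (ti in t$transforms) pts <- pts + transform_displacement(ti, pts)
    pts
  } else {
    pts + transform_displacement(t, pts)
  }
}

#' Compose two transforms into a dense displacement field
#'
#' Materializes `outer(inner(x))` on the voxel centers of `output_grid`:
#' the returned field `d` satisfies `x + d(x) = outer(inner(x))` with `outer`
#' evaluated exactly for B-splines and by trilinear interpolation for fields.
#' Points that `inner` maps outside `outer`'s grid are edge-clamped (fields)
#' or get zero displacement outside the lattice support (B-splines).
#'
#' @param outer,inner transforms; `inner` is applied first.
#' @param output_grid [image_grid()] on which to sample the composition.
#' @return A [displacement_field()] on `output_grid`.
#' @export
compose_transforms <- function(outer, inner, output_grid) {
  pts <- grid_points(output_grid)
  mapped <- transform_points(outer, transform_points(inner, pts))
  displacement_field(output_grid, array(mapped - pts, c(output_grid$shape, 3L)))
}

#' Collapse a transform chain to a single displacement field
#'
#' Left fold of [compose_transforms()] realized by successive evaluation:
#' each member is evaluated at the points produced by the previous one
#' (one interpolation per link), and the net mapping is sampled on
#' `output_grid`. A chain of length one returns that transform resampled.
#'
#' @param chain a [transform_chain()] (or plain list of transforms).
#' @param output_grid [image_grid()].
#' @return A [displacement_field()] on `output_grid`.
#' @export
compose_chain <- function(chain, output_grid) {
  if (!inherits(chain, "transform_chain")) chain <- transform_chain(chain)
  pts <- grid_points(output_grid)
  mapped <- transform_points(chain, pts)
  displacement_field(output_grid, array(mapped - pts, c(output_grid$shape, 3L)))
}

#' Resample an image through a transform
#'
#' Produces the registered image `R(x) = M(T(x))` on `fixed_grid`. Linear
#' interpolation samples the moving image trilinearly; `cubic_bspline` first
#' converts the image to interpolating cubic B-spline coefficients
#' (recursive prefilter) and then evaluates the spline at the mapped points.
#' Sampling outside the moving image is edge-clamped.
#'
#' @param img a [scalar_image()] (the moving image).
#' @param t transform mapping fixed-space to moving-space coordinates.
#' @param fixed_grid [image_grid()] of the output; defaults to `img$grid`.
#' @param interpolation `"linear"` or `"cubic_bspline"`.
#' @return A [scalar_image()] on `fixed_grid`.
#' @export
warp_image <- function(img, t, fixed_grid = img$grid,
                       interpolation = c("linear", "cubic_bspline")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(img, "scalar_image"))
  pts <- grid_points(fixed_grid)
  mapped <- transform_points(t, pts)
  g <- img$grid
  if (interpolation == "linear") {
    vals <- trilinear_sample_cpp(mapped, as.numeric(img$values), g$shape,
                                 g$origin, g$spacing, 1L)
  } else {
    coef <- bspline_prefilter_cpp(as.numeric(img$values), g$shape)
    vals <- bspline_sample_cpp(mapped, coef, g$shape, g$origin, g$spacing,
                               1L, FALSE)
  }
  scalar_image(fixed_grid, array(vals[, 1], fixed_grid$shape))
}

# nearest-neighbor gather of an integer/logical array at mapped points;
# out-of-domain points return `fill`
nn_gather <- function(arr, grid, mapped, fill = 0L) {
  idx <- round(world_to_index(grid, mapped))
  sh <- grid$shape
  ok <- idx[, 1] >= 0 & idx[, 1] < sh[1] &
        idx[, 2] >= 0 & idx[, 2] < sh[2] &
        idx[, 3] >= 0 & idx[, 3] < sh[3]
  out <- rep(fill, nrow(mapped))
  lin <- 1 + idx[ok, 1] + sh[1] * (idx[ok, 2] + sh[2] * idx[ok, 3])
  out[ok] <- arr[lin]
  out
}

#' Warp a binary mask through a transform
#'
#' Nearest-neighbor sampling of the mask at the mapped points, which
#' preserves binary membership exactly; points mapping outside the mask's
#' grid become background (a structure may leave the field of view).
#'
#' @param mask a [binary_mask()] in moving space.
#' @param t transform mapping fixed-space to moving-space coordinates.
#' @param fixed_grid [image_grid()] of the output; defaults to `mask$grid`.
#' @return A [binary_mask()] on `fixed_grid`.
#' @export
warp_mask <- function(mask, t, fixed_grid = mask$grid) {
  stopifnot(inherits(mask, "binary_mask"))
  pts <- grid_points(fixed_grid)
  mapped <- transform_points(t, pts)
  vals <- nn_gather(mask$inside, mask$grid, mapped, fill = FALSE)
  binary_mask(fixed_grid, array(vals, fixed_grid$shape))
}

#' Warp a label map through a transform
#'
#' Nearest-neighbor label transfer; all voxels of one structure keep a common
#' label. Out-of-domain points become background (0).
#'
#' @param labels a [label_map()] in moving space.
#' @param t transform mapping fixed-space to moving-space coordinates.
#' @param fixed_grid [image_grid()] of the output; defaults to `labels$grid`.
#' @return A [label_map()] on `fixed_grid`.
#' @export
warp_labels <- function(labels, t, fixed_grid = labels$grid) {
  stopifnot(inherits(labels, "label_map"))
  pts <- grid_points(fixed_grid)
  mapped <- transform_points(t, pts)
  vals <- nn_gather(labels$labels, labels$grid, mapped, fill = 0L)
  label_map(fixed_grid, array(as.integer(vals), fixed_grid$shape),
            structure_names = labels$structure_names)
}
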