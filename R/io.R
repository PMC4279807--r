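# Image, label, displacement-field and transform file IO.
# NIfTI-1 goes through RNifti; MetaImage (.mha/.mhd) is read and written
# directly (plain key = value header plus raw little-endian voxel data),
# since no installed reader covers it.

nifti_ext <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
meta_ext <- function(path) grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)

grid_from_nifti <- function(img, d) {
  pix <- attr(img, "pixdim")
  if (is.null(pix)) pix <- RNifti::pixdim(img)
  xf <- RNifti::xform(img)
  image_grid(d, pix[1:3], xf[1:3, 4])
}

write_nifti_raster <- function(arr, grid, path, datatype) {
  img <- RNifti::asNifti(arr)
  m <- structure(diag(c(grid$spacing, 1)), code = 2L)
  m[1:3, 4] <- grid$origin
  RNifti::qform(img) <- m
  RNifti::pixdim(img) <- if (length(dim(arr)) == 4) c(grid$spacing, 1) else grid$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

meta_type <- function(storage) {
  switch(storage, double = "MET_DOUBLE", integer = "MET_INT",
         logical = "MET_UCHAR", "MET_FLOAT")
}

write_meta_raster <- function(arr, grid, path, ncomp = 1L, element_type = "MET_DOUBLE") {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    sprintf("DimSize = %s", paste(grid$shape, collapse = " ")),
    sprintf("ElementSpacing = %s", paste(format(grid$spacing, digits = 17), collapse = " ")),
    sprintf("Offset = %s", paste(format(grid$origin, digits = 17), collapse = " ")),
    sprintf("ElementNumberOfChannels = %d", ncomp),
    sprintf("ElementType = %s", element_type),
    "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  # channel-interleaved voxel order, x fastest (MetaImage convention)
  v <- as.vector(arr)
  if (ncomp > 1L) {
    n <- length(v) / ncomp
    v <- as.vector(t(matrix(v, n, ncomp)))
  }
  if (element_type == "MET_DOUBLE") writeBin(as.double(v), con, size = 8, endian = "little")
  else if (element_type == "MET_FLOAT") writeBin(as.double(v), con, size = 4, endian = "little")
  else if (element_type == "MET_INT") writeBin(as.integer(v), con, size = 4, endian = "little")
  else if (element_type == "MET_SHORT") writeBin(as.integer(v), con, size = 2, endian = "little")
  else if (element_type == "MET_UCHAR") writeBin(as.integer(v), con, size = 1, endian = "little")
  else stop(sprintf("unsupported MetaImage element type %s", element_type))
  invisible(path)
}

read_meta_raster <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("unexpected end of MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop(sprintf("malformed MetaImage header line: '%s'", line))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  ndims <- as.integer(hdr[["NDims"]] %||% "3")
  if (ndims != 3) stop(sprintf("expected a 3D volume, got NDims = %d", ndims))
  shape <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||% "1 1 1", "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr[["Offset"]] %||% "0 0 0", "\\s+")[[1]])
  ncomp <- as.integer(hdr[["ElementNumberOfChannels"]] %||% "1")
  et <- hdr[["ElementType"]]
  msb <- identical(tolower(hdr[["BinaryDataByteOrderMSB"]] %||% "false"), "true")
  endian <- if (msb) "big" else "little"
  n <- prod(shape) * ncomp
  src <- hdr[["ElementDataFile"]]
  if (identical(src, "LOCAL")) {
    raw_con <- con
  } else {
    raw_con <- file(file.path(dirname(path), src), "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  v <- switch(et,
    MET_DOUBLE = readBin(raw_con, "double", n, size = 8, endian = endian),
    MET_FLOAT = readBin(raw_con, "double", n, size = 4, endian = endian),
    MET_INT = readBin(raw_con, "integer", n, size = 4, endian = endian),
    MET_SHORT = readBin(raw_con, "integer", n, size = 2, endian = endian),
    MET_UCHAR = readBin(raw_con, "integer", n, size = 1, signed = FALSE, endian = endian),
    stop(sprintf("unsupported MetaImage element type %s", et)))
  if (length(v) != n) stop("truncated MetaImage voxel data")
  list(values = v, shape = shape, grid = image_grid(shape, spacing, origin),
       ncomp = ncomp, integer_type = et %in% c("MET_INT", "MET_SHORT", "MET_UCHAR"))
}

#' Read a 3D scalar image or label map
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) and MetaImage (`.mha`, `.mhd`).
#' Integer-typed volumes become label maps, floating-point volumes scalar
#' images; `type` overrides the choice. Grid spacing and origin are
#' populated from the header.
#'
#' @param path file path.
#' @param type `"auto"`, `"scalar"` or `"labels"`.
#' @return A [scalar_image()] or [label_map()].
#' @export
read_image <- function(path, type = c("auto", "scalar", "labels")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (nifti_ext(path)) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 3)
      stop(sprintf("expected a 3D volume, got %d dimensions", length(d)))
    grid <- grid_from_nifti(img, d)
    vals <- as.array(img)
    is_int <- is.integer(vals)
  } else if (meta_ext(path)) {
    r <- read_meta_raster(path)
    if (r$ncomp != 1) stop("expected a scalar volume, got a vector image")
    grid <- r$grid
    vals <- array(r$values, r$shape)
    is_int <- r$integer_type
  } else {
    stop(sprintf("unrecognized image format: %s (use .nii[.gz], .mha or .mhd)", path))
  }
  if (type == "labels" || (type == "auto" && is_int))
    label_map(grid, array(as.integer(round(vals)), grid$shape))
  else
    scalar_image(grid, vals)
}

#' Write a scalar image or label map
#'
#' Scalar images are stored as float32, label maps as int32 (exact label
#' round-trip). Format follows the extension.
#'
#' @param x [scalar_image()] or [label_map()].
#' @param path output path (`.nii`, `.nii.gz`, `.mha`).
#' @return The path, invisibly.
#' @export
write_image <- function(x, path) {
  if (inherits(x, "scalar_image")) {
    if (nifti_ext(path)) write_nifti_raster(x$values, x$grid, path, "float")
    else if (meta_ext(path)) write_meta_raster(x$values, x$grid, path, 1L, "MET_FLOAT")
    else stop("unrecognized output format")
  } else if (inherits(x, "label_map")) {
    if (nifti_ext(path)) write_nifti_raster(x$labels, x$grid, path, "int32")
    else if (meta_ext(path)) write_meta_raster(x$labels, x$grid, path, 1L, "MET_INT")
    else stop("unrecognized output format")
  } else stop("x must be a scalar_image or label_map")
  invisible(path)
}

#' Read a dense displacement field
#'
#' Vector-valued volume with 3 components in mm: NIfTI stores components as
#' a trailing 4th dimension, MetaImage as interleaved channels.
#'
#' @param path file path.
#' @return A [displacement_field()].
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (nifti_ext(path)) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) == 5 && d[4] == 1) { # NIfTI vector convention (u dim)
      img <- array(as.array(img), d[c(1:3, 5)])
      d <- dim(img)
    }
    if (length(d) != 4 || d[4] != 3)
      stop("expected a 3-component vector volume")
    grid <- grid_from_nifti(img, d[1:3])
    displacement_field(grid, as.array(img))
  } else if (meta_ext(path)) {
    r <- read_meta_raster(path)
    if (r$ncomp != 3) stop("expected a 3-component vector volume")
    # de-interleave channels
    v <- matrix(r$values, 3, prod(r$shape))
    displacement_field(r$grid, array(t(v), c(r$shape, 3L)))
  } else stop("unrecognized field format")
}

#' Write a dense displacement field
#'
#' @param field a [displacement_field()].
#' @param path output path (`.nii`, `.nii.gz`, `.mha`).
#' @return The path, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "displacement_field"))
  if (nifti_ext(path)) {
    write_nifti_raster(field$vectors, field$grid, path, "double")
  } else if (meta_ext(path)) {
    write_meta_raster(field$vectors, field$grid, path, 3L, "MET_DOUBLE")
  } else stop("unrecognized field format")
  invisible(path)
}

#' Write a B-spline transform as JSON
#'
#' Schema: `grid_spacing_mm`, `grid_origin_mm`, `coefficient_shape`,
#' `coefficients` (flattened xyz displacement triples, mm, x index fastest)
#' and `domain` (shape/spacing/origin of the image grid the transform is
#' defined over).
#'
#' @param t a [bspline_transform()].
#' @param path output path (`.json`).
#' @return The path, invisibly.
#' @export
write_bspline <- function(t, path) {
  stopifnot(inherits(t, "bspline_transform"))
  obj <- list(
    grid_spacing_mm = t$ctrl_spacing,
    grid_origin_mm = t$ctrl_origin,
    coefficient_shape = t$ctrl_shape,
    coefficients = as.vector(t(t$coefficients)),
    domain = list(shape = t$domain$shape, spacing = t$domain$spacing,
                  origin = t$domain$origin))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a B-spline transform from JSON
#'
#' @param path path to a transform file written by [write_bspline()].
#' @return A [bspline_transform()].
#' @export
read_bspline <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  domain <- image_grid(obj$domain$shape, obj$domain$spacing, obj$domain$origin)
  coefs <- matrix(obj$coefficients, ncol = 3, byrow = TRUE)
  t <- bspline_transform(domain, obj$grid_spacing_mm)
  if (!identical(t$ctrl_shape, as.integer(obj$coefficient_shape)))
    stop("coefficient lattice in file does not match the domain-derived lattice")
  if (nrow(coefs) != nrow(t$coefficients))
    stop("coefficient count does not match the lattice")
  t$coefficients <- coefs
  t
}

#' Read a transform of either representation
#'
#' JSON files are read as B-spline transforms, image formats as
#' displacement fields.
#'
#' @param path file path.
#' @return A transform.
#' @export
read_transform <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) read_bspline(path)
  else read_field(path)
}
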