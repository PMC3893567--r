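## Internal helpers ----------------------------------------------------------

vx_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "vx_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

vx_check_geometry_fields <- function(origin, spacing, direction, d) {
  if (length(origin) != d || length(spacing) != d)
    vx_stop("vx_contract_error", "origin/spacing length must equal dimension")
  if (any(!is.finite(origin)) || any(!is.finite(spacing)))
    vx_stop("vx_contract_error", "origin/spacing must be finite")
  if (any(spacing <= 0))
    vx_stop("vx_contract_error", "spacing must be strictly positive in every axis")
  if (!is.matrix(direction) || any(dim(direction) != c(d, d)))
    vx_stop("vx_contract_error", "direction must be a d x d matrix")
  if (max(abs(crossprod(direction) - diag(d))) > 1e-6)
    vx_stop("vx_contract_error", "direction matrix must be orthonormal (within 1e-6)")
  invisible(TRUE)
}

## Image / Geometry constructors ---------------------------------------------

#' Create an image with physical geometry
#'
#' An image couples a d-dimensional scalar array (d = 2 or 3) with the physical
#' geometry that places each voxel in world (mm) coordinates: the position of
#' voxel `(0, ..., 0)` (`origin`), the voxel sizes along each axis (`spacing`)
#' and an orthonormal `direction` matrix of axis cosines. Indices are 0-based
#' and a voxel's physical position is the position of its center.
#'
#' @param data Numeric array (2-d or 3-d). `NaN` values are rejected.
#' @param origin Physical coordinate (mm) of the center of voxel 0.
#' @param spacing Strictly positive voxel sizes (mm) per axis.
#' @param direction Orthonormal d x d matrix of direction cosines.
#' @param domain_id Optional tag naming the space the image lives in
#'   (e.g. `"fixed"` or `"moving"`); purely informational.
#' @return An object of class `vximage`.
#' @export
#' @examples
#' img <- vx_image(array(runif(64), c(4, 4, 4)), spacing = c(1, 1, 2))
#' vx_geometry_of(img)
vx_image <- function(data, origin = rep(0, length(dim(data))),
                     spacing = rep(1, length(dim(data))),
                     direction = diag(length(dim(data))),
                     domain_id = NULL) {
  if (is.null(dim(data))) dim(data) <- length(data)
  d <- length(dim(data))
  if (!d %in% c(2L, 3L))
    vx_stop("vx_contract_error", "only 2-d and 3-d images are supported")
  if (anyNA(data))
    vx_stop("vx_contract_error", "image data must not contain NA/NaN")
  data <- array(as.double(data), dim(data))   # plain array, no stray attributes
  origin <- as.double(origin); spacing <- as.double(spacing)
  direction <- matrix(as.double(direction), d, d)
  vx_check_geometry_fields(origin, spacing, direction, d)
  structure(list(data = data, origin = origin, spacing = spacing,
                 direction = direction, domain_id = domain_id),
            class = "vximage")
}

#' Create a label image
#'
#' A label image shares the geometry model of [vx_image()] but stores
#' non-negative integer region labels; label 0 is the background.
#'
#' @inheritParams vx_image
#' @param data Array of non-negative integers.
#' @return An object of class `c("vxlabelimage", "vximage")`.
#' @export
vx_label_image <- function(data, origin = rep(0, length(dim(data))),
                           spacing = rep(1, length(dim(data))),
                           direction = diag(length(dim(data))),
                           domain_id = NULL) {
  if (anyNA(data) || any(data < 0) || any(data != round(data)))
    vx_stop("vx_contract_error", "labels must be integers >= 0")
  img <- vx_image(data, origin, spacing, direction, domain_id)
  img$data <- array(as.integer(round(img$data)), dim(img$data))
  class(img) <- c("vxlabelimage", "vximage")
  img
}

#' Describe an image domain without pixel data
#'
#' A geometry is the shape + origin + spacing + direction of an image domain.
#' It is the currency of resampling: any image or transform output can be
#' evaluated onto an arbitrary geometry.
#'
#' @param shape Integer extents per axis.
#' @inheritParams vx_image
#' @return An object of class `vxgeometry`.
#' @export
vx_geometry <- function(shape, origin = rep(0, length(shape)),
                        spacing = rep(1, length(shape)),
                        direction = diag(length(shape))) {
  d <- length(shape)
  if (!d %in% c(2L, 3L))
    vx_stop("vx_contract_error", "only 2-d and 3-d geometries are supported")
  shape <- as.integer(shape)
  if (any(shape < 1)) vx_stop("vx_contract_error", "shape must be >= 1 per axis")
  origin <- as.double(origin); spacing <- as.double(spacing)
  direction <- matrix(as.double(direction), d, d)
  vx_check_geometry_fields(origin, spacing, direction, d)
  structure(list(shape = shape, origin = origin, spacing = spacing,
                 direction = direction),
            class = "vxgeometry")
}

#' @rdname vx_geometry
#' @param image A `vximage`.
#' @export
vx_geometry_of <- function(image) {
  vx_geometry(dim(image$data), image$origin, image$spacing, image$direction)
}

#' @export
print.vximage <- function(x, ...) {
  cat(sprintf("<vximage> %s  spacing (%s) mm  origin (%s)\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
print.vxgeometry <- function(x, ...) {
  cat(sprintf("<vxgeometry> %s  spacing (%s) mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$spacing), collapse = ", ")))
  invisible(x)
}

vx_dim <- function(x) {
  if (inherits(x, "vxgeometry")) length(x$shape) else length(dim(x$data))
}

vx_shape <- function(x) {
  if (inherits(x, "vxgeometry")) x$shape else dim(x$data)
}

## Index <-> world mapping ----------------------------------------------------

#' Map continuous voxel indices to physical points and back
#'
#' `vx_voxel_to_world()` returns `origin + direction %*% (spacing * index)` for
#' each row of `index`; `vx_world_to_voxel()` is its exact inverse. Indices are
#' 0-based and continuous (index `(0,...,0)` is the center of the first voxel).
#'
#' @param geometry A `vxgeometry` (or `vximage`).
#' @param index,point Numeric matrix with one row per point (a single point may
#'   be given as a plain vector).
#' @return A matrix of the same shape as the input.
#' @export
vx_voxel_to_world <- function(geometry, index) {
  if (inherits(geometry, "vximage")) geometry <- vx_geometry_of(geometry)
  d <- length(geometry$shape)
  index <- vx_as_points(index, d)
  # explicit per-axis accumulation: element-wise deterministic regardless of
  # how the point set is chunked (bit-exact chunking contract)
  vx_affine_points(index, geometry$direction %*% diag(geometry$spacing, d),
                   geometry$origin)
}

# out[i, ] = M %*% x[i, ] + b, accumulated axis-by-axis in fixed order
vx_affine_points <- function(x, M, b) {
  d <- ncol(x)
  out <- matrix(0, nrow(x), d)
  for (q in seq_len(d)) {
    acc <- rep(b[q], nrow(x))
    for (ax in seq_len(d)) acc <- acc + M[q, ax] * x[, ax]
    out[, q] <- acc
  }
  out
}

#' @rdname vx_voxel_to_world
#' @export
vx_world_to_voxel <- function(geometry, point) {
  if (inherits(geometry, "vximage")) geometry <- vx_geometry_of(geometry)
  d <- length(geometry$shape)
  point <- vx_as_points(point, d)
  M <- geometry$direction %*% diag(geometry$spacing, d)
  vx_affine_points(point, solve(M), as.double(-solve(M) %*% geometry$origin))
}

vx_as_points <- function(x, d) {
  if (is.null(dim(x))) {
    if (length(x) != d)
      vx_stop("vx_contract_error", sprintf("expected %d-d point(s)", d))
    x <- matrix(as.double(x), 1, d)
  } else {
    if (ncol(x) != d)
      vx_stop("vx_contract_error", sprintf("expected %d-column point matrix", d))
    x <- matrix(as.double(x), nrow(x), d)
  }
  x
}

## World-coordinate grids -----------------------------------------------------

# All voxel-center world coordinates of a geometry, as an n x d matrix in
# array (column-major, x-fastest) order. Used by resampling, field export and
# transform averaging.
vx_grid_points <- function(geometry, flat_range = NULL) {
  if (inherits(geometry, "vximage")) geometry <- vx_geometry_of(geometry)
  shape <- geometry$shape
  d <- length(shape)
  if (is.null(flat_range)) flat <- seq_len(prod(shape)) - 1L
  else flat <- seq.int(flat_range[1], flat_range[2] - 1L)
  idx <- matrix(0, length(flat), d)
  rem <- flat
  for (ax in seq_len(d)) {
    idx[, ax] <- rem %% shape[ax]
    rem <- rem %/% shape[ax]
  }
  vx_voxel_to_world(geometry, idx)
}

# The closed physical-domain box test: TRUE where 0 <= continuous index <=
# shape-1 on every axis.
vx_inside_domain <- function(geometry, points) {
  if (inherits(geometry, "vximage")) geometry <- vx_geometry_of(geometry)
  cidx <- vx_world_to_voxel(geometry, points)
  ok <- rep(TRUE, nrow(cidx))
  for (ax in seq_along(geometry$shape))
    ok <- ok & cidx[, ax] >= 0 & cidx[, ax] <= geometry$shape[ax] - 1L
  ok
}

# Physical volume of one voxel (mm^d); |det(direction)| = 1 for orthonormal
# direction matrices so the product of spacings suffices.
vx_voxel_volume <- function(geometry) {
  if (inherits(geometry, "vximage")) geometry <- vx_geometry_of(geometry)
  prod(geometry$spacing)
}

## Single-precision emulation -------------------------------------------------

# Round a double vector/array to the nearest IEEE-754 binary32 value, staying
# in double storage. Emulates a single-precision compute path; applied after
# each arithmetic stage of "accelerated" code paths.
vx_to_float32 <- function(x) {
  dm <- dim(x)
  out <- readBin(writeBin(as.double(x), raw(), size = 4L),
                 what = "double", size = 4L, n = length(x))
  if (!is.null(dm)) dim(out) <- dm
  out
}
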