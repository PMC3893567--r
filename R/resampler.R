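## Final resampling: a three-stage initialize -> transform-sequence ->
## interpolate pipeline over output chunks. Chunking is pure memory
## management: the per-voxel arithmetic is identical for any chunk size, so
## results are bit-identical.

#' Plan chunked traversal of an output geometry
#'
#' Splits the output voxels (flat, array-order indices) into contiguous
#' half-open ranges of at most `chunk_voxels` voxels that cover the output
#' exactly once.
#'
#' @param output_geometry A `vxgeometry` (the resampling domain).
#' @param chunk_voxels Maximum voxels per chunk (default `2^20`).
#' @return A `vxchunkplan` with the geometry and a list of `c(start, end)`
#'   0-based half-open ranges.
#' @export
vx_chunk_plan <- function(output_geometry, chunk_voxels = 2^20) {
  stopifnot(chunk_voxels >= 1)
  total <- prod(output_geometry$shape)
  starts <- seq(0, total - 1, by = chunk_voxels)
  chunks <- lapply(starts, function(s) c(s, min(s + chunk_voxels, total)))
  structure(list(output_geometry = output_geometry,
                 chunk_voxels = chunk_voxels, chunks = chunks),
            class = "vxchunkplan")
}

#' The three resampling stages
#'
#' @description
#' * `vx_initialize_chunk()` fills a deformation-field buffer with the
#'   physical coordinates of the chunk's output voxel centers.
#' * `vx_apply_transform_stage()` replaces every buffered point by its image
#'   under one transform; for a composite the member stages are applied
#'   innermost (first) to outermost (last), so the buffer ends up holding
#'   `T_n(...T_1(x))`.
#' * `vx_interpolate_chunk()` evaluates the moving image at the buffered
#'   points (with the interpolator's outside rule).
#'
#' @param plan A `vxchunkplan`.
#' @param chunk A `c(start, end)` range from the plan.
#' @param buffer n x d matrix of physical points.
#' @param transform A `vxtransform`.
#' @param moving_interp A `vxinterp`.
#' @return The buffer (matrix) or the interpolated chunk values (vector).
#' @name vx_resample_stages
NULL

#' @rdname vx_resample_stages
#' @export
vx_initialize_chunk <- function(plan, chunk) {
  vx_grid_points(plan$output_geometry, flat_range = chunk)
}

#' @rdname vx_resample_stages
#' @export
vx_apply_transform_stage <- function(buffer, transform) {
  if (transform$kind == "composite") {
    for (m in transform$members) buffer <- vx_map_point(m, buffer)
    buffer
  } else {
    vx_map_point(transform, buffer)
  }
}

#' @rdname vx_resample_stages
#' @export
vx_interpolate_chunk <- function(buffer, moving_interp) {
  vx_evaluate(moving_interp, buffer)
}

#' Resample an image through a transform
#'
#' Evaluates `I_M(T(x))` on every voxel of the output geometry, chunk by
#' chunk: initialize the chunk's point buffer, run each transform stage
#' (composite members innermost first), interpolate. The result is
#' bit-identical for any `chunk_voxels`.
#'
#' @param moving A `vximage` (the image being deformed).
#' @param transform A `vxtransform` mapping output-domain points into the
#'   moving domain.
#' @param output_geometry A `vxgeometry`; defaults to the moving image's own
#'   geometry.
#' @param interpolator `"nearest"`, `"linear"`, `"bspline1"` or `"bspline3"`.
#' @param chunk_voxels Maximum voxels held in the intermediate deformation
#'   buffer (default `2^20`).
#' @param outside_value Intensity assigned where `T(x)` falls outside the
#'   moving domain.
#' @param precision `"double"` (reference) or `"single"`: the single path
#'   rounds the buffered coordinates and interpolated values to IEEE
#'   binary32, emulating an accelerated single-precision device path.
#' @return The resampled `vximage` on `output_geometry`.
#' @export
vx_resample <- function(moving, transform, output_geometry = NULL,
                        interpolator = "linear", chunk_voxels = 2^20,
                        outside_value = 0, precision = c("double", "single")) {
  precision <- match.arg(precision)
  single <- precision == "single"
  if (is.null(output_geometry)) output_geometry <- vx_geometry_of(moving)
  if (inherits(output_geometry, "vximage"))
    output_geometry <- vx_geometry_of(output_geometry)
  interp <- if (inherits(interpolator, "vxinterp")) interpolator
            else vx_interpolator(moving, interpolator, outside_value)
  if (single) {
    im32 <- interp$image; im32$data <- vx_to_float32(im32$data)
    interp <- vx_interpolator(im32, interp$kind, outside_value)
    if (!is.null(interp$coefficients))
      interp$coefficients <- vx_to_float32(interp$coefficients)
  }
  plan <- vx_chunk_plan(output_geometry, chunk_voxels)
  out <- numeric(prod(output_geometry$shape))
  stages <- if (transform$kind == "composite") transform$members else list(transform)
  for (chunk in plan$chunks) {
    buf <- vx_initialize_chunk(plan, chunk)
    if (single) buf <- vx_to_float32(buf)
    for (stage in stages) {
      buf <- vx_apply_transform_stage(buf, stage)
      if (single) buf <- vx_to_float32(buf)
    }
    vals <- vx_interpolate_chunk(buf, interp)
    if (single) vals <- vx_to_float32(vals)
    out[(chunk[1] + 1L):chunk[2]] <- vals
  }
  vx_image(array(out, output_geometry$shape), output_geometry$origin,
           output_geometry$spacing, output_geometry$direction,
           domain_id = moving$domain_id)
}
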