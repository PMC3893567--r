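## Multi-resolution Gaussian pyramid: per-axis recursive (IIR) Gaussian
## smoothing with optional downsampling by shrinking (subsampling) or
## resampling (linear interpolation).
##
## The smoother follows Deriche's recursive scheme: the Gaussian is
## approximated by a sum of two exponentially damped cosine/sine pairs, whose
## z-transform yields a 4th-order causal + anti-causal recursive filter pair.
## The numerator/denominator coefficients are assembled numerically from the
## pole/residue form, and the DC gain is normalized to exactly 1 so constants
## (and total mass, away from boundaries) are preserved. Boundaries use
## edge-value extension with steady-state initialization.

# Deriche's 4-term approximation of exp(-x^2/2) (unit-sigma, unnormalized):
# g(x) ~ sum of e^{-b_i |x|} (p_i cos(w_i x) + q_i sin(w_i |x|)), i = 1,2
vx_deriche_constants <- function() {
  list(p = c(1.68, -0.6803), q = c(3.735, -0.2598),
       b = c(1.783, 1.723),  w = c(0.6318, 1.997))
}

# Recursive filter coefficients for a given sigma (in samples).
# Returns numerators n (causal, z^0..z^-3), m (anti-causal, z^+1..z^+4),
# denominator d (z^-1..z^-4, shared), normalized to unit DC gain.
vx_deriche_coefficients <- function(sigma) {
  k <- vx_deriche_constants()
  terms <- vector("list", 2)
  for (i in 1:2) {
    lam <- k$b[i] / sigma; om <- k$w[i] / sigma
    e <- exp(-lam); cw <- cos(om); sw <- sin(om)
    # z-transform of e^{-lam n}(p cos(om n) + q sin(om n)) u[n]
    num <- c(k$p[i], e * (k$q[i] * sw - k$p[i] * cw))
    den <- c(1, -2 * e * cw, e * e)
    terms[[i]] <- list(num = num, den = den)
  }
  conv <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1L)
    for (i in seq_along(a)) {
      j <- i + seq_along(b) - 1L
      out[j] <- out[j] + a[i] * b
    }
    out
  }
  num <- conv(terms[[1]]$num, terms[[2]]$den) + conv(terms[[2]]$num, terms[[1]]$den)
  den <- conv(terms[[1]]$den, terms[[2]]$den)      # length 5, den[1] = 1
  n_causal <- c(num, 0)[1:4]                        # z^0 .. z^-3
  d <- den[2:5]                                     # z^-1 .. z^-4
  # anti-causal numerator so that h[-n] = h[n] with h[0] counted once:
  # m_k = n_k - d_k * n_0 (k = 1..3), m_4 = -d_4 * n_0
  m <- c(n_causal[2] - d[1] * n_causal[1],
         n_causal[3] - d[2] * n_causal[1],
         n_causal[4] - d[3] * n_causal[1],
         -d[4] * n_causal[1])
  # normalize DC gain (causal + anti-causal) to 1
  dc <- (sum(n_causal) + sum(m)) / (1 + sum(d))
  list(n = n_causal / dc, m = m / dc, d = d)
}

# Apply the recursive Gaussian to every column of a matrix (lines along rows).
# Edge-value boundary: the signal is extended with its first/last sample and
# the recursions start in the corresponding steady state.
vx_recursive_gaussian_lines <- function(x, sigma, single = FALSE) {
  n <- nrow(x)
  if (sigma <= 0) return(x)
  co <- vx_deriche_coefficients(sigma)
  # the scalar filter constants are precomputed once on the host and stay in
  # double even on the accelerated path; only the data arrays are rounded
  if (single) x <- vx_to_float32(x)
  nc <- co$n; mc <- co$m; dc <- co$d
  first <- x[1, , drop = FALSE]; last <- x[n, , drop = FALSE]
  # steady-state outputs for constant input
  dc_causal <- sum(nc) / (1 + sum(dc))
  dc_anti <- sum(mc) / (1 + sum(dc))
  yc <- matrix(0, n, ncol(x))
  # causal pass: x[k<1] := x[1], y[k<1] := dc_causal * x[1]
  xm1 <- first; xm2 <- first; xm3 <- first
  ym1 <- dc_causal * first; ym2 <- ym1; ym3 <- ym1; ym4 <- ym1
  for (i in seq_len(n)) {
    xi <- x[i, , drop = FALSE]
    yi <- nc[1] * xi + nc[2] * xm1 + nc[3] * xm2 + nc[4] * xm3 -
      dc[1] * ym1 - dc[2] * ym2 - dc[3] * ym3 - dc[4] * ym4
    yc[i, ] <- yi
    xm3 <- xm2; xm2 <- xm1; xm1 <- xi
    ym4 <- ym3; ym3 <- ym2; ym2 <- ym1; ym1 <- yi
  }
  if (single) yc <- vx_to_float32(yc)
  ya <- matrix(0, n, ncol(x))
  # anti-causal pass: x[k>n] := x[n], y[k>n] := dc_anti * x[n]
  xp1 <- last; xp2 <- last; xp3 <- last; xp4 <- last
  yp1 <- dc_anti * last; yp2 <- yp1; yp3 <- yp1; yp4 <- yp1
  for (i in rev(seq_len(n))) {
    yi <- mc[1] * xp1 + mc[2] * xp2 + mc[3] * xp3 + mc[4] * xp4 -
      dc[1] * yp1 - dc[2] * yp2 - dc[3] * yp3 - dc[4] * yp4
    ya[i, ] <- yi
    xp4 <- xp3; xp3 <- xp2; xp2 <- xp1; xp1 <- x[i, , drop = FALSE]
    yp4 <- yp3; yp3 <- yp2; yp2 <- yp1; yp1 <- yi
  }
  if (single) ya <- vx_to_float32(ya)
  out <- yc + ya
  if (single) out <- vx_to_float32(out)
  out
}

#' Recursive Gaussian smoothing of a 1-d signal
#'
#' Approximates convolution with a normalized Gaussian `G(x; sigma)` by a
#' causal + anti-causal 4th-order recursive filter (infinite impulse
#' response), so the cost is independent of `sigma`. `sigma = 0` returns the
#' input unchanged.
#'
#' @param line Numeric vector.
#' @param sigma Smoothing scale in samples (voxels).
#' @return Smoothed vector of the same length.
#' @export
vx_recursive_gaussian_1d <- function(line, sigma) {
  if (sigma <= 0) return(as.double(line))
  as.vector(vx_recursive_gaussian_lines(matrix(as.double(line), ncol = 1), sigma))
}

#' Smooth an image with a per-axis recursive Gaussian
#'
#' The 1-d recursive filter is applied axis by axis (x, then y, then z); scan
#' lines within one axis are independent, so any processing order of lines
#' yields the identical result.
#'
#' @param image A `vximage`.
#' @param sigma Per-axis smoothing scales in voxel units (recycled if scalar).
#' @param precision `"double"` (reference) or `"single"`: the single path
#'   rounds the filter coefficients and each pass's output to IEEE binary32,
#'   emulating an accelerated single-precision compute path.
#' @return The smoothed `vximage`.
#' @export
vx_smooth_image <- function(image, sigma, precision = c("double", "single")) {
  precision <- match.arg(precision)
  single <- precision == "single"
  d <- vx_dim(image)
  sigma <- rep(as.double(sigma), length.out = d)
  dm <- vx_shape(image)
  for (ax in seq_len(d))
    if (sigma[ax] > 0 && dm[ax] < 4)
      vx_stop("vx_degenerate_error",
              sprintf("axis %d has extent %d < 4; cannot smooth with sigma > 0", ax, dm[ax]))
  arr <- image$data
  if (single) arr <- vx_to_float32(arr)
  for (ax in seq_len(d)) {
    if (sigma[ax] <= 0) next
    perm <- c(ax, setdiff(seq_len(d), ax))
    a <- aperm(arr, perm)
    m <- matrix(a, dm[ax], prod(dm[-ax]))
    m <- vx_recursive_gaussian_lines(m, sigma[ax], single = single)
    arr <- aperm(array(m, dm[perm]), order(perm))
  }
  out <- image
  out$data <- arr
  out
}

#' Define a multi-resolution pyramid schedule
#'
#' Level 1 is the coarsest and level `levels` the finest. The classic
#' 4-level schedule pairs downsampling factors 8, 4, 2, 1 with smoothing
#' sigmas 4, 2, 1, 0 (voxel units).
#'
#' @param sigma Length-L vector (or L x d matrix) of smoothing scales in
#'   voxel units.
#' @param factor Length-L integer downsampling factors (>= 1).
#' @param mode `"off"` (no size change), `"resampler"` (linear-interpolated
#'   resampling onto a coarser grid) or `"shrinker"` (subsampling without
#'   interpolation).
#' @return A `vxpyramid_schedule`.
#' @export
vx_pyramid_schedule <- function(sigma, factor, mode = c("resampler", "shrinker", "off")) {
  mode <- match.arg(mode)
  sig <- if (is.matrix(sigma)) sigma else matrix(sigma, ncol = 1)
  if (length(factor) != nrow(sig))
    vx_stop("vx_contract_error", "sigma and factor must list the same number of levels")
  if (any(factor < 1) || any(factor != round(factor)))
    vx_stop("vx_contract_error", "factors must be integers >= 1")
  if (any(sig < 0)) vx_stop("vx_contract_error", "sigma must be >= 0")
  structure(list(levels = nrow(sig), sigma = sig, factor = as.integer(factor),
                 mode = mode),
            class = "vxpyramid_schedule")
}

#' Build a Gaussian image pyramid
#'
#' Each level smooths the input image with that level's sigma and then, per
#' the schedule mode, keeps the grid (`off`), subsamples every `factor`-th
#' voxel starting at index 0 (`shrinker`), or resamples with linear
#' interpolation onto a grid with `factor`-times coarser spacing
#' (`resampler`). Output geometries carry the scaled spacing (and, for the
#' shrinker, the unchanged origin of the index-0 voxel center).
#'
#' @param image A `vximage`.
#' @param schedule A `vxpyramid_schedule`.
#' @param precision `"double"` or `"single"` (see [vx_smooth_image()]).
#' @return List of `vximage` levels, coarsest first.
#' @export
vx_build_pyramid <- function(image, schedule, precision = c("double", "single")) {
  precision <- match.arg(precision)
  d <- vx_dim(image)
  dm <- vx_shape(image)
  out <- vector("list", schedule$levels)
  for (lev in seq_len(schedule$levels)) {
    f <- schedule$factor[lev]
    if (any(f > dm))
      vx_stop("vx_degenerate_error",
              sprintf("level %d factor %d exceeds an image extent", lev, f))
    sig <- if (ncol(schedule$sigma) == 1) rep(schedule$sigma[lev, 1], d)
           else schedule$sigma[lev, ]
    sm <- if (all(sig <= 0)) {
      im <- image
      if (precision == "single") im$data <- vx_to_float32(im$data)
      im
    } else vx_smooth_image(image, sig, precision)
    out[[lev]] <- if (schedule$mode == "off" || f == 1L) sm
      else if (schedule$mode == "shrinker") vx_shrink_image(sm, f)
      else vx_resample_to_factor(sm, f, precision)
  }
  out
}

vx_shrink_image <- function(image, factor) {
  d <- vx_dim(image)
  dm <- vx_shape(image)
  idx <- lapply(seq_len(d), function(ax) seq(1, dm[ax], by = factor))
  data <- do.call(`[`, c(list(image$data), idx, list(drop = FALSE)))
  vx_image(data, origin = image$origin, spacing = image$spacing * factor,
           direction = image$direction, domain_id = image$domain_id)
}

vx_resample_to_factor <- function(image, factor, precision = "double") {
  d <- vx_dim(image)
  dm <- vx_shape(image)
  new_shape <- pmax(as.integer(ceiling(dm / factor)), 1L)
  geom <- vx_geometry(new_shape, image$origin, image$spacing * factor,
                      image$direction)
  vx_resample(image, vx_identity_transform(d), geom, interpolator = "linear",
              precision = precision)
}

#' Longest scan line processable in a bounded local memory
#'
#' The recursive smoother needs `buffers` per-line floating-point buffers
#' resident in local (on-chip) memory at once; this planning utility returns
#' `floor(local_memory_bytes / (buffers * bytes_per_element))`, the longest
#' line that fits. A 16 kB local memory with 3 single-precision buffers
#' allows lines of 1365 samples. The portable implementation itself has no
#' such limit.
#'
#' @param local_memory_bytes Available local memory in bytes.
#' @param buffers Number of line-sized buffers (input, output, temporary).
#' @param bytes_per_element Bytes per stored element (4 for single precision).
#' @return Integer line length.
#' @export
vx_max_local_line_length <- function(local_memory_bytes, buffers = 3L,
                                     bytes_per_element = 4L) {
  stopifnot(local_memory_bytes > 0, buffers > 0, bytes_per_element > 0)
  as.integer(floor(local_memory_bytes / (buffers * bytes_per_element)))
}
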