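## Iterative stochastic gradient descent inside a multi-resolution loop, with
## transform staging (similarity -> affine -> B-spline by composition) and
## dyadic B-spline grid refinement between resolutions.

#' Decaying gain schedule for gradient descent
#'
#' The step size at iteration k (0-based) is `a_k = a / (A + k)^alpha`. With
#' `a = NULL` the base gain is calibrated automatically at the start of each
#' resolution so that the first update moves the (scaled) parameters by
#' `step_target` mm at most (see [vx_registration_config()]).
#'
#' @param a Base gain (> 0), or `NULL` for automatic calibration.
#' @param A Offset (>= 1), delays the decay.
#' @param alpha Decay exponent in (0, 1].
#' @return A `vxgain_schedule`.
#' @export
vx_gain_schedule <- function(a = NULL, A = 20, alpha = 0.602) {
  if (!is.null(a) && a <= 0) vx_stop("vx_contract_error", "a must be > 0")
  if (A < 1 || alpha <= 0 || alpha > 1)
    vx_stop("vx_contract_error", "need A >= 1 and alpha in (0, 1]")
  structure(list(a = a, A = A, alpha = alpha), class = "vxgain_schedule")
}

vx_gain_at <- function(schedule, a, k) a / (schedule$A + k)^schedule$alpha

#' One gradient-descent parameter update
#'
#' Returns `mu - gain * gradient`. The update is elementwise, hence
#' partition-parallelizable over disjoint index ranges with bit-identical
#' results.
#'
#' @param mu Current parameters.
#' @param gradient Cost derivative (same length).
#' @param gain Positive step size `a_k`.
#' @return Updated parameter vector.
#' @export
vx_gradient_descent_step <- function(mu, gradient, gain) {
  if (length(mu) != length(gradient))
    vx_stop("vx_contract_error", "mu and gradient lengths differ")
  if (any(!is.finite(gradient)))
    vx_stop("vx_numeric_error", "non-finite gradient components")
  stopifnot(gain > 0)
  mu - gain * gradient
}

#' Registration configuration
#'
#' @param resolutions Number of multi-resolution levels R per stage.
#' @param iterations Gradient-descent iterations per resolution (scalar or
#'   length R).
#' @param metric `"msd"`, `"nc"` or `"mi"`.
#' @param samples Stochastic samples per iteration (new set each iteration).
#' @param stages Transform staging, a character vector drawn from
#'   `c("translation", "rigid", "similarity", "affine", "bspline")`; each
#'   stage composes (as outermost member) with the frozen previous stages.
#' @param grid_spacing Control-point spacing (mm) of the B-spline stage at
#'   the finest resolution; coarser levels use dyadic multiples (e.g. 24, 12,
#'   6 mm for R = 3 and `grid_spacing = 6`).
#' @param pyramid_mode `"resampler"`, `"shrinker"` or `"off"`.
#' @param pyramid_sigma,pyramid_factor Optional explicit schedule (length R,
#'   coarsest first); by default factors are `2^(R-1), ..., 2, 1` with sigma
#'   `factor/2` and 0 at the finest level.
#' @param gain A [vx_gain_schedule()].
#' @param step_target First-step parameter motion (mm) used to auto-calibrate
#'   the gain when `gain$a` is `NULL`.
#' @param seed Integer seed; all stochastic sampling derives from it.
#' @param threads Partition count T for fork-join metric evaluation.
#' @param regularizer_weight Weight w of the bending-energy penalty added to
#'   the similarity cost during B-spline stages (default 0).
#' @param bins MI histogram bins.
#' @param interpolator Moving-image interpolator used during optimization.
#' @param mask Optional fixed-domain `vxlabelimage` restricting sampling.
#' @return A `vxregconfig`.
#' @export
vx_registration_config <- function(resolutions = 3L, iterations = 150L,
                                   metric = c("msd", "nc", "mi"),
                                   samples = 2000L,
                                   stages = c("similarity", "affine", "bspline"),
                                   grid_spacing = NULL,
                                   pyramid_mode = "resampler",
                                   pyramid_sigma = NULL, pyramid_factor = NULL,
                                   gain = vx_gain_schedule(),
                                   step_target = 0.4,
                                   seed = 1L, threads = 1L,
                                   regularizer_weight = 0, bins = 32L,
                                   interpolator = "linear", mask = NULL) {
  metric <- match.arg(metric)
  stopifnot(resolutions >= 1, all(iterations >= 0), samples >= 1)
  ok <- c("translation", "rigid", "similarity", "affine", "bspline")
  if (!all(stages %in% ok))
    vx_stop("vx_contract_error",
            sprintf("unknown stage(s): %s", paste(setdiff(stages, ok), collapse = ", ")))
  if (is.null(pyramid_factor)) pyramid_factor <- 2^((resolutions - 1):0)
  if (is.null(pyramid_sigma)) {
    pyramid_sigma <- pyramid_factor / 2
    pyramid_sigma[length(pyramid_sigma)] <- 0
  }
  structure(list(resolutions = as.integer(resolutions),
                 iterations = rep(as.integer(iterations), length.out = resolutions),
                 metric = metric, samples = as.integer(samples),
                 stages = stages, grid_spacing = grid_spacing,
                 pyramid_mode = pyramid_mode,
                 pyramid_sigma = pyramid_sigma,
                 pyramid_factor = as.integer(pyramid_factor),
                 gain = gain, step_target = step_target,
                 seed = as.integer(seed), threads = as.integer(threads),
                 regularizer_weight = regularizer_weight, bins = as.integer(bins),
                 interpolator = interpolator, mask = mask),
            class = "vxregconfig")
}

# Classical parameter scales: angle and matrix entries move points by ~the
# domain radius per unit, translations and B-spline coefficients are already
# in mm. Scaled gradient descent divides the gradient by scale^2.
vx_parameter_scales <- function(active, fixed_geometry) {
  d <- active$dim
  radius <- mean((fixed_geometry$shape - 1) * fixed_geometry$spacing) / 2
  radius <- max(radius, 1)
  switch(active$kind,
    translation = rep(1, d),
    rigid = c(rep(radius, if (d == 2) 1 else 3), rep(1, d)),
    similarity = c(rep(radius, if (d == 2) 1 else 3), rep(1, d), radius),
    affine = c(rep(radius, d * d), rep(1, d)),
    bspline = rep(1, length(vx_parameters(active))),
    rep(1, length(vx_parameters(active))))
}

#' Run the gradient-descent iterations of one resolution level
#'
#' Each iteration draws a fresh sample set (deterministically keyed by the
#' config seed and the global iteration index), evaluates the metric
#' derivative over `threads` partitions, optionally adds the weighted
#' bending-energy penalty, and applies one scaled gradient-descent step. On a
#' non-finite derivative the iteration is retried once with a fresh sample
#' set, then aborted.
#'
#' @param fixed_level,moving_level Pyramid images at this resolution.
#' @param transform Current transform (composite allowed; the last member is
#'   optimized).
#' @param config A `vxregconfig`.
#' @param resolution 1-based resolution index (coarsest = 1).
#' @param iter_offset Global iteration counter offset (for sample streams).
#' @return List `transform` (updated), `log` (one data.frame row per
#'   iteration), `iters` (iterations executed).
#' @export
vx_run_resolution <- function(fixed_level, moving_level, transform, config,
                              resolution = 1L, iter_offset = 0L) {
  iters <- config$iterations[min(resolution, length(config$iterations))]
  active <- vx_active_transform(transform)
  scales <- vx_parameter_scales(active, vx_geometry_of(fixed_level))
  moving_interp <- vx_interpolator(moving_level, config$interpolator)
  sched <- config$gain
  a_base <- sched$a
  log_rows <- vector("list", iters)
  if (iters == 0)
    return(list(transform = transform, log = vx_empty_log(), iters = 0L))
  mu <- vx_active_parameters(transform)
  use_bending <- config$regularizer_weight > 0 &&
    vx_active_transform(transform)$kind == "bspline"
  for (k in seq_len(iters) - 1L) {
    t0 <- proc.time()[["elapsed"]]
    rep_k <- NULL
    for (attempt in 1:2) {
      samples <- vx_draw_samples(fixed_level, config$mask, config$samples,
                                 seed = config$seed,
                                 iteration = iter_offset + k + (attempt - 1L) * 1e6)
      rep_try <- vx_evaluate_partitioned(config$metric, fixed_level,
                                         moving_interp, transform, samples,
                                         partitions = config$threads,
                                         bins = config$bins)
      if (use_bending) {
        be <- vx_bending_energy_value_and_derivative(transform, samples)
        rep_try$value <- rep_try$value + config$regularizer_weight * be$value
        rep_try$derivative <- rep_try$derivative +
          config$regularizer_weight * be$derivative
      }
      if (all(is.finite(rep_try$derivative)) && is.finite(rep_try$value)) {
        rep_k <- rep_try; break
      }
    }
    if (is.null(rep_k))
      vx_stop("vx_numeric_error",
              sprintf("non-finite derivative at resolution %d iteration %d (after retry)",
                      resolution, k))
    g_scaled <- rep_k$derivative / (scales * scales)
    if (is.null(a_base)) {
      # physical first-step motion ~ a * |g|/s (update a*g/s^2 times s mm/unit)
      gmax <- max(abs(rep_k$derivative / scales))
      gmax <- max(gmax, .Machine$double.eps)
      a_base <- config$step_target / gmax * sched$A^sched$alpha
    }
    a_k <- vx_gain_at(sched, a_base, k)
    # trust region: no single update may move parameters by more than
    # 2 * step_target mm in scaled space, whatever the stochastic gradient
    motion <- a_k * max(abs(rep_k$derivative / scales))
    if (motion > 2 * config$step_target)
      a_k <- a_k * (2 * config$step_target) / motion
    mu <- vx_gradient_descent_step(mu, g_scaled, a_k)
    transform <- vx_set_active_parameters(transform, mu)
    log_rows[[k + 1L]] <- data.frame(
      iteration = iter_offset + k, resolution = resolution,
      value = rep_k$value, grad_maxnorm = max(abs(rep_k$derivative)),
      gain = a_k, samples_used = rep_k$samples_used,
      seconds = proc.time()[["elapsed"]] - t0)
  }
  list(transform = transform, log = do.call(rbind, log_rows), iters = iters)
}

vx_empty_log <- function() {
  data.frame(iteration = integer(0), resolution = integer(0),
             value = numeric(0), grad_maxnorm = numeric(0), gain = numeric(0),
             samples_used = integer(0), seconds = numeric(0))
}

## B-spline grid refinement ----------------------------------------------------

# one dyadic subdivision along axis ax of a (already padded) coefficient
# array; standard two-scale relation c'_{2i} = (c_{i-1} + 6 c_i + c_{i+1})/8,
# c'_{2i+1} = (c_i + c_{i+1})/2 with zero extension.
vx_subdivide_axis <- function(arr, ax) {
  dm <- dim(arr); d <- length(dm)
  perm <- c(ax, setdiff(seq_len(d), ax))
  a <- aperm(arr, perm)
  m <- matrix(a, dm[ax], prod(dm[-ax]))
  n <- nrow(m)
  zero <- matrix(0, 1, ncol(m))
  ext <- rbind(zero, m, zero)
  even <- (ext[1:n, , drop = FALSE] + 6 * ext[2:(n + 1), , drop = FALSE] +
             ext[3:(n + 2), , drop = FALSE]) / 8
  odd <- (m[1:(n - 1), , drop = FALSE] + m[2:n, , drop = FALSE]) / 2
  out <- matrix(0, 2 * n - 1, ncol(m))
  out[seq(1, 2 * n - 1, by = 2), ] <- even
  out[seq(2, 2 * n - 2, by = 2), ] <- odd
  newdm <- dm[perm]; newdm[1] <- 2 * n - 1
  aperm(array(out, newdm), order(perm))
}

vx_pad_axis <- function(arr, ax, pad) {
  dm <- dim(arr); d <- length(dm)
  perm <- c(ax, setdiff(seq_len(d), ax))
  a <- aperm(arr, perm)
  m <- matrix(a, dm[ax], prod(dm[-ax]))
  z <- matrix(0, pad, ncol(m))
  out <- rbind(z, m, z)
  newdm <- dm[perm]; newdm[1] <- newdm[1] + 2L * pad
  aperm(array(out, newdm), order(perm))
}

#' Refine a B-spline control grid to a finer spacing
#'
#' For exact dyadic halving (`new_spacing = spacing / 2`) the standard
#' knot-insertion (two-scale) weights produce a finer transform whose
#' displacement field equals the input's to machine precision on the old
#' grid's support. For non-dyadic refinement the new coefficients are fitted
#' by separable least squares to the old displacement sampled on a dense
#' lattice; the fit residual (max abs mm) is attached as attribute
#' `residual`.
#'
#' @param transform A B-spline `vxtransform`.
#' @param new_spacing Target control-point spacing (mm), strictly smaller
#'   than the current one.
#' @return The refined B-spline `vxtransform`.
#' @export
vx_refine_bspline_grid <- function(transform, new_spacing) {
  stopifnot(transform$kind == "bspline")
  d <- transform$dim
  g <- transform$grid
  new_spacing <- rep(as.double(new_spacing), length.out = d)
  if (any(new_spacing >= g$spacing))
    vx_stop("vx_contract_error", "new_spacing must be smaller than the current spacing")
  dyadic <- all(abs(g$spacing / new_spacing - 2) < 1e-9)
  G <- prod(g$shape)
  if (dyadic) {
    comp <- vector("list", d)
    for (q in seq_len(d)) {
      cq <- array(matrix(transform$coefficients, G, d)[, q], g$shape)
      for (ax in seq_len(d)) cq <- vx_pad_axis(cq, ax, 2L)
      for (ax in seq_len(d)) cq <- vx_subdivide_axis(cq, ax)
      comp[[q]] <- cq
    }
    newshape <- dim(comp[[1]])
    newgrid <- vx_geometry(newshape, g$origin - 2 * g$spacing, new_spacing,
                           g$direction)
    coef <- array(0, c(newshape, d))
    for (q in seq_len(d)) coef[slice.index(coef, d + 1L) == q] <- comp[[q]]
    out <- vx_bspline(newgrid, coef, transform$order)
    attr(out, "residual") <- 0
    return(out)
  }
  # least-squares fallback on a tensor lattice over the covered domain (the
  # grid minus its margin ring, i.e. the physical box the grid was built for)
  lo <- g$origin + 2 * g$spacing
  hi <- g$origin + (g$shape - 3) * g$spacing
  newgrid <- vx_bspline_grid_for_box(lo - new_spacing, hi + new_spacing,
                                     new_spacing, transform$order)
  axes <- lapply(seq_len(d), function(ax)
    seq(lo[ax], hi[ax], length.out = max(4L * newgrid$shape[ax], 16L)))
  lattice <- as.matrix(do.call(expand.grid, axes))
  disp <- vx_map_point(transform, lattice) - lattice
  # separable pseudo-inverse: per-axis cubic design matrices on the new grid
  Bs <- lapply(seq_len(d), function(ax) {
    u <- (axes[[ax]] - newgrid$origin[ax]) / newgrid$spacing[ax]
    i0 <- floor(u) - 1; t <- u - floor(u)
    W <- vx_bsp_axis_weights(t, transform$order, 0L)
    B <- matrix(0, length(u), newgrid$shape[ax])
    for (a in 0:transform$order) {
      j <- i0 + a + 1
      ok <- j >= 1 & j <= newgrid$shape[ax]
      B[cbind(which(ok), j[ok])] <- W[ok, a + 1L]
    }
    B
  })
  pinv <- lapply(Bs, function(B) solve(crossprod(B) + 1e-10 * diag(ncol(B)),
                                       t(B)))
  dims_in <- vapply(axes, length, integer(1))
  coef <- array(0, c(newgrid$shape, d))
  for (q in seq_len(d)) {
    A <- array(disp[, q], dims_in)
    for (ax in seq_len(d)) {
      dmA <- dim(A)
      perm <- c(ax, setdiff(seq_len(d), ax))
      Am <- matrix(aperm(A, perm), dmA[ax], prod(dmA[-ax]))
      Am <- pinv[[ax]] %*% Am
      nd <- dmA[perm]; nd[1] <- nrow(Am)
      A <- aperm(array(Am, nd), order(perm))
    }
    coef[slice.index(coef, d + 1L) == q] <- A
  }
  out <- vx_bspline(newgrid, coef, transform$order)
  res <- max(abs(vx_map_point(out, lattice) - lattice - disp))
  attr(out, "residual") <- res
  out
}

## Full registration -----------------------------------------------------------

vx_domain_center <- function(geometry) {
  as.double(vx_voxel_to_world(geometry, (geometry$shape - 1) / 2))
}

vx_new_stage_transform <- function(kind, fixed_geometry, config, inner = NULL) {
  d <- length(fixed_geometry$shape)
  cen <- vx_domain_center(fixed_geometry)
  switch(kind,
    translation = vx_translation(rep(0, d)),
    rigid = vx_rigid(rep(0, if (d == 2) 1 else 3), rep(0, d), center = cen),
    similarity = vx_similarity(rep(0, if (d == 2) 1 else 3), rep(0, d),
                               scale = 1, center = cen),
    affine = vx_affine(diag(d), rep(0, d), center = cen),
    bspline = {
      sp <- config$grid_spacing
      if (is.null(sp)) sp <- 4 * min(fixed_geometry$spacing) *
          2^(config$resolutions - 1)
      else sp <- sp * 2^(config$resolutions - 1)
      vx_bspline_for_domain(fixed_geometry, sp, inner = inner)
    })
}

#' Register a moving image to a fixed image
#'
#' Builds Gaussian pyramids for both images, then runs each transform stage
#' in turn over the multi-resolution levels, optimizing with stochastic
#' gradient descent. Later stages compose (as the outermost, optimized
#' member) with the frozen earlier stages; the B-spline stage refines its
#' control grid dyadically from resolution to resolution. Finally the moving
#' image is resampled through the full composite onto the fixed geometry.
#' The whole run is deterministic given `config$seed` (with `threads = 1`).
#'
#' @param fixed,moving `vximage`s of the same dimension.
#' @param config A [vx_registration_config()].
#' @return List with `transform` (the final `vxtransform`), `log`
#'   (per-iteration data.frame), `resampled` (moving resampled onto the
#'   fixed geometry).
#' @export
vx_register <- function(fixed, moving, config = vx_registration_config()) {
  if (vx_dim(fixed) != vx_dim(moving))
    vx_stop("vx_contract_error", "fixed and moving dimensions differ")
  sched <- vx_pyramid_schedule(config$pyramid_sigma, config$pyramid_factor,
                               config$pyramid_mode)
  fpyr <- vx_build_pyramid(fixed, sched)
  mpyr <- vx_build_pyramid(moving, sched)
  total <- NULL
  logs <- list()
  iter_offset <- 0L
  for (stage in config$stages) {
    stage_tr <- vx_new_stage_transform(stage, vx_geometry_of(fixed), config,
                                       inner = total)
    current <- if (is.null(total)) stage_tr
               else if (total$kind == "composite")
                 vx_composite(c(total$members, list(stage_tr)))
               else vx_composite(list(total, stage_tr))
    for (res in seq_len(config$resolutions)) {
      if (stage == "bspline" && res > 1) {
        act <- vx_active_transform(current)
        refined <- vx_refine_bspline_grid(act, act$grid$spacing / 2)
        current <- vx_set_active_transform(current, refined)
      }
      run <- vx_run_resolution(fpyr[[res]], mpyr[[res]], current, config,
                               resolution = res, iter_offset = iter_offset)
      current <- run$transform
      logs[[length(logs) + 1L]] <- cbind(stage = stage, run$log)
      iter_offset <- iter_offset + run$iters
    }
    total <- current
  }
  resampled <- vx_resample(moving, total, vx_geometry_of(fixed),
                           interpolator = "linear")
  list(transform = total, log = do.call(rbind, logs), resampled = resampled)
}

# replace the optimized (last) member
vx_set_active_transform <- function(transform, new_active) {
  if (transform$kind == "composite") {
    transform$members[[length(transform$members)]] <- new_active
    transform
  } else new_active
}
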