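## Similarity metrics (MSD, NC, MI) and the bending-energy penalty, with
## analytic derivatives assembled as eta-weighted sums over a stochastic
## sample set: each sample contributes xi(.) combined with the sparse
## product t(J) %*% grad I_M, so the per-sample cost is O(d*P), not O(d*N).

## Sample sets ----------------------------------------------------------------

# run code under a private RNG stream derived from (seed, iteration),
# restoring the caller's RNG state afterwards
vx_with_stream <- function(seed, iteration, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed((as.double(seed) %% 65536) * 32749 + (as.double(iteration) %% 32749))
  force(code)
}

#' Draw a stochastic sample set from the fixed domain
#'
#' Samples `count` physical points uniformly over the fixed image's
#' voxel-center box (rejection-sampled against a mask if given: a point is
#' kept when the nearest mask voxel is nonzero). The draw is a pure function
#' of `(seed, iteration)`, so iteration-k sample sets are reproducible
#' without sequential RNG state.
#'
#' @param fixed Fixed `vximage` (or `vxgeometry`).
#' @param mask Optional `vxlabelimage`; samples restricted to nonzero labels.
#' @param count Number of samples.
#' @param seed Integer seed.
#' @param iteration Iteration index k at which the set is drawn.
#' @return A `vxsampleset`: `points` (count x d, mm), `eta = 1/count`,
#'   `seed`, `iteration`.
#' @export
vx_draw_samples <- function(fixed, mask = NULL, count, seed = 1L, iteration = 0L) {
  if (count < 1) vx_stop("vx_contract_error", "count must be >= 1")
  geom <- if (inherits(fixed, "vxgeometry")) fixed else vx_geometry_of(fixed)
  d <- length(geom$shape)
  if (!is.null(mask) && all(mask$data == 0))
    vx_stop("vx_degenerate_error", "mask has no nonzero voxels")
  mask_ip <- if (!is.null(mask))
    vx_interpolator(vx_image(mask$data + 0, mask$origin, mask$spacing,
                             mask$direction), "nearest")
  else NULL
  pts <- vx_with_stream(seed, iteration, {
    draw <- function(n) {
      idx <- matrix(0, n, d)
      for (ax in seq_len(d)) idx[, ax] <- runif(n, 0, geom$shape[ax] - 1L)
      vx_voxel_to_world(geom, idx)
    }
    if (is.null(mask_ip)) draw(count)
    else {
      acc <- matrix(0, 0, d)
      tries <- 0L
      while (nrow(acc) < count && tries < 1000L) {
        cand <- draw(max(count, 2L * (count - nrow(acc))))
        keep <- vx_evaluate(mask_ip, cand) > 0
        acc <- rbind(acc, cand[keep, , drop = FALSE])
        tries <- tries + 1L
      }
      if (nrow(acc) < count)
        vx_stop("vx_degenerate_error", "mask rejection sampling failed to reach count")
      acc[seq_len(count), , drop = FALSE]
    }
  })
  structure(list(points = pts, eta = 1 / count, count = as.integer(count),
                 seed = seed, iteration = iteration),
            class = "vxsampleset")
}

## Derivative assembly: sum_i J_i^T (c_i * grad_i) ----------------------------

# active: the optimized (non-composite) transform; pts: its input points
# (inner-chain mapped); wg: n x d matrix of c_i * grad_i rows.
# bsp: for bspline kinds, precomputed list(W, IDX, inside) at pts.
vx_assemble_jtg <- function(active, pts, wg, bsp = NULL) {
  d <- active$dim
  if (active$kind == "bspline") {
    G <- prod(active$grid$shape)
    out <- numeric(d * G)
    ins <- which(bsp$inside)
    if (length(ins)) {
      W <- bsp$W; IDX <- bsp$IDX     # already subset to inside rows
      for (q in seq_len(d))
        out[(q - 1L) * G + seq_len(G)] <-
          vx_bsp_scatter(W, IDX, wg[ins, q], G)
    }
    return(out)
  }
  cen <- if (!is.null(active$center)) active$center else rep(0, d)
  xc <- sweep(pts, 2, cen)
  switch(active$kind,
    translation = colSums(wg),
    rigid = {
      dR <- vx_rotation_matrix(active$angles, d, deriv = 1L)
      ang <- vapply(dR, function(D) sum(vx_affine_points(xc, D, rep(0, d)) * wg),
                    numeric(1))
      c(ang, colSums(wg))
    },
    similarity = {
      R <- vx_rotation_matrix(active$angles, d)
      dR <- vx_rotation_matrix(active$angles, d, deriv = 1L)
      ang <- vapply(dR, function(D)
        active$scale * sum(vx_affine_points(xc, D, rep(0, d)) * wg), numeric(1))
      sc <- sum(vx_affine_points(xc, R, rep(0, d)) * wg)
      c(ang, colSums(wg), sc)
    },
    affine = {
      M <- crossprod(wg, xc)          # M[q, j] = sum_i wg[i,q] xc[i,j]
      c(as.vector(t(M)), colSums(wg))
    },
    vx_stop("vx_unsupported_error",
            sprintf("no parameter Jacobian for kind '%s'", active$kind)))
}

## Metric evaluation -----------------------------------------------------------

vx_metric_prepare <- function(fixed, moving_interp, transform, samples) {
  pts <- samples$points
  mapped <- vx_map_point(transform, pts)
  inc <- which(vx_interp_inside(moving_interp, mapped))
  if (length(inc) < 2)
    vx_stop("vx_overlap_error",
            sprintf("only %d sample(s) map inside the moving domain", length(inc)))
  fixed_ip <- vx_interpolator(fixed, "linear")
  mpt <- mapped[inc, , drop = FALSE]
  f <- vx_evaluate(fixed_ip, pts[inc, , drop = FALSE])
  m <- vx_evaluate(moving_interp, mpt)
  grad <- vx_evaluate_gradient(moving_interp, mpt)
  active <- vx_active_transform(transform)
  inner <- vx_inner_chain_map(transform, pts[inc, , drop = FALSE])
  bsp <- NULL
  if (active$kind == "bspline") {
    loc <- vx_bsp_locate(active$grid, inner, active$order)
    ins <- which(loc$inside)
    tp <- if (length(ins))
      vx_bsp_tensor(loc$i0[ins, , drop = FALSE], loc$tfrac[ins, , drop = FALSE],
                    active$grid$shape, active$order)
    else list(W = matrix(0, 0, 0), IDX = matrix(0L, 0, 0))
    bsp <- list(W = tp$W, IDX = tp$IDX, inside = loc$inside)
  }
  list(f = f, m = m, grad = grad, inc = inc, n_inc = length(inc),
       active = active, inner = inner, bsp = bsp)
}

# Per-sample coefficients c_i with derivative = eta * sum_i c_i J_i^T grad_i,
# plus the metric value.
vx_metric_weights <- function(metric, f, m, eta_inc, bins = 32L,
                              intensity_range = NULL) {
  n <- length(f)
  if (metric == "msd") {
    resid <- m - f
    list(value = sum(resid * resid) * eta_inc, c = 2 * resid)
  } else if (metric == "nc") {
    ft <- f - sum(f) / n
    mt <- m - sum(m) / n
    sff <- sum(ft * ft); smm <- sum(mt * mt); sfm <- sum(ft * mt)
    if (sff <= 0 || smm <= 0)
      return(list(value = 1, c = numeric(n)))
    ncc <- sfm / sqrt(sff * smm)
    w <- -2 * ncc * (ft - (sfm / smm) * mt) / sqrt(sff * smm)
    list(value = 1 - ncc * ncc, c = w * n)      # eta * (w * n) = w
  } else if (metric == "mi") {
    B <- as.integer(bins); pad <- 2L
    fr <- intensity_range$fixed; mr <- intensity_range$moving
    bwf <- max(fr[2] - fr[1], .Machine$double.eps) / (B - 2L * pad)
    bwm <- max(mr[2] - mr[1], .Machine$double.eps) / (B - 2L * pad)
    tf <- pmin(pmax((f - fr[1]) / bwf + pad, pad), B - pad - 1e-7)
    tm <- pmin(pmax((m - mr[1]) / bwm + pad, pad), B - pad - 1e-7)
    fbin <- floor(tf)                           # zero-order window, 0-based
    k0 <- floor(tm) - 1                         # cubic window start bin
    t <- tm - floor(tm)
    W4 <- vx_bsp_axis_weights(t, 3L, 0L)
    W4d <- vx_bsp_axis_weights(t, 3L, 1L)
    # joint histogram p[fixed bin + 1, moving bin + 1]
    joint <- numeric(B * B)
    for (a in 0:3) {
      cell <- fbin + (k0 + a) * B + 1           # fixed varies fastest
      s <- rowsum(W4[, a + 1L], cell, reorder = FALSE)
      ii <- as.integer(rownames(s))
      joint[ii] <- joint[ii] + s[, 1]
    }
    p <- matrix(joint * eta_inc, B, B)
    pF <- rowSums(p); pM <- colSums(p)
    pos <- p > 0
    mi <- sum(p[pos] * log(p[pos] / (pF[row(p)[pos]] * pM[col(p)[pos]])))
    # c_i = -(1/bwm) sum_a W4d * log(p(fbin, k0+a) / pM(k0+a))
    cc <- numeric(n)
    lp <- matrix(-Inf, B, B)
    lp[pos] <- log(p[pos])
    lm <- ifelse(pM > 0, log(pM), 0)
    for (a in 0:3) {
      kb <- k0 + a
      lj <- lp[cbind(fbin + 1, kb + 1)]
      term <- ifelse(is.finite(lj), lj - lm[kb + 1], 0)
      cc <- cc + W4d[, a + 1L] * term
    }
    list(value = -mi, c = -cc / bwm)
  } else {
    vx_stop("vx_contract_error", sprintf("unknown metric '%s'", metric))
  }
}

#' Evaluate a similarity metric and its derivative over a sample set
#'
#' Computes the cost value and the analytic derivative with respect to the
#' optimized transform parameters as the eta-weighted sample sum: each
#' included sample contributes a scalar intensity term times the sparse
#' product of the transposed parameter Jacobian with the moving-image
#' spatial gradient. Samples whose mapped point falls outside the moving
#' domain are excluded and eta is recomputed over the included count.
#'
#' All metrics are returned as costs to minimize: MSD is the mean squared
#' intensity difference, NC is returned as `1 - NC^2`, MI as the negated
#' Mattes mutual information (32-bin Parzen joint histogram; zero-order
#' window on the fixed intensity, cubic window on the moving intensity, bin
#' edges fixed from the global intensity ranges).
#'
#' @param metric `"msd"`, `"nc"` or `"mi"`.
#' @param fixed Fixed `vximage` (sampled with linear interpolation).
#' @param moving_interp `vxinterp` over the moving image (value + gradient).
#' @param transform The current `vxtransform`; for a composite, the
#'   derivative is taken w.r.t. the last (optimized) member.
#' @param samples A `vxsampleset` from [vx_draw_samples()].
#' @param bins Histogram bins for MI (default 32).
#' @return A `vxmetricreport`: `value`, `derivative` (length N of the
#'   optimized transform), `samples_used`.
#' @export
vx_metric_value_and_derivative <- function(metric, fixed, moving_interp,
                                           transform, samples, bins = 32L) {
  vx_evaluate_partitioned(metric, fixed, moving_interp, transform, samples,
                          partitions = 1L, bins = bins)
}

#' Partitioned (fork-join) metric evaluation
#'
#' Splits the included samples into `partitions` contiguous, disjoint
#' partitions whose sizes differ by at most one, computes one partial
#' derivative per partition, and joins them with [vx_join_partials()]. Global
#' sufficient statistics (means, the MI joint histogram) are shared, so for
#' any `partitions` the result equals the single-partition result up to
#' floating-point reassociation of the per-partition sums.
#'
#' @inheritParams vx_metric_value_and_derivative
#' @param partitions Number of partitions T (1 <= T <= samples).
#' @return A `vxmetricreport` with attribute `partials` (list of
#'   `vxpartialderivative`).
#' @export
vx_evaluate_partitioned <- function(metric, fixed, moving_interp, transform,
                                    samples, partitions = 1L, bins = 32L) {
  if (partitions < 1 || partitions > samples$count)
    vx_stop("vx_contract_error", "partitions must be in [1, number of samples]")
  prep <- vx_metric_prepare(fixed, moving_interp, transform, samples)
  eta_inc <- 1 / prep$n_inc
  ir <- list(fixed = range(fixed$data),
             moving = range(moving_interp$image$data))
  mw <- vx_metric_weights(metric, prep$f, prep$m, eta_inc, bins, ir)
  wg <- mw$c * prep$grad                       # c_i recycled over columns
  # contiguous partitions of the included samples, sizes differing by <= 1
  sizes <- rep(prep$n_inc %/% partitions, partitions)
  extra <- prep$n_inc %% partitions
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes); starts <- ends - sizes + 1L
  partials <- vector("list", partitions)
  for (t in seq_len(partitions)) {
    rows <- starts[t]:ends[t]
    bsp_t <- NULL
    if (!is.null(prep$bsp)) {
      ins_all <- which(prep$bsp$inside)
      keep <- ins_all %in% rows
      bsp_t <- list(W = prep$bsp$W[keep, , drop = FALSE],
                    IDX = prep$bsp$IDX[keep, , drop = FALSE],
                    inside = prep$bsp$inside & (seq_len(prep$n_inc) %in% rows))
      # vx_assemble_jtg re-derives inside rows; keep W/IDX consistent
      bsp_t$inside_rows <- rows
    }
    gsum <- if (is.null(bsp_t)) {
      vx_assemble_jtg(prep$active, prep$inner[rows, , drop = FALSE],
                      wg[rows, , drop = FALSE])
    } else {
      d <- prep$active$dim
      G <- prod(prep$active$grid$shape)
      out <- numeric(d * G)
      if (nrow(bsp_t$W)) {
        rows_ins <- intersect(rows, which(prep$bsp$inside))
        for (q in seq_len(d))
          out[(q - 1L) * G + seq_len(G)] <-
            vx_bsp_scatter(bsp_t$W, bsp_t$IDX, wg[rows_ins, q], G)
      }
      out
    }
    partials[[t]] <- structure(
      list(values = gsum / sizes[t], thread_id = t,
           samples_in_partition = sizes[t]),
      class = "vxpartialderivative")
  }
  deriv <- vx_join_partials(partials, eta_inc)
  structure(list(value = mw$value, derivative = deriv,
                 samples_used = prep$n_inc),
            class = "vxmetricreport", partials = partials)
}

#' Join per-partition partial derivatives
#'
#' Each partial holds the mean contribution of its partition; the join is the
#' sample-count-weighted sum times the normalizer eta. Joining over disjoint
#' index ranges of the parameter vector is associativity-free, hence
#' parallelizable with bit-identical results.
#'
#' @param partials List of `vxpartialderivative`.
#' @param eta Normalizer (1 / included samples).
#' @return Length-N numeric derivative vector.
#' @export
vx_join_partials <- function(partials, eta) {
  stopifnot(length(partials) >= 1)
  N <- length(partials[[1]]$values)
  out <- numeric(N)
  for (p in partials) {
    if (length(p$values) != N)
      vx_stop("vx_contract_error", "partial derivative lengths differ")
    out <- out + p$samples_in_partition * p$values
  }
  out * eta
}

## Bending energy --------------------------------------------------------------

#' Bending energy of a B-spline transform and its derivative
#'
#' The eta-weighted sample mean of the squared Frobenius norm of the second
#' spatial derivative of the transformation (the classic thin-metal-plate
#' smoothness penalty). It is exactly zero, with zero derivative, for any
#' transform whose displacement is globally affine in x.
#'
#' @param transform A B-spline `vxtransform` (or a composite whose optimized
#'   last member is one; samples are then mapped through the frozen inner
#'   members first).
#' @param samples A `vxsampleset`.
#' @return A `vxmetricreport` (`derivative` has the B-spline's N parameters).
#' @export
vx_bending_energy_value_and_derivative <- function(transform, samples) {
  active <- vx_active_transform(transform)
  if (active$kind != "bspline")
    vx_stop("vx_unsupported_error", "bending energy requires a B-spline transform")
  d <- active$dim
  pts <- vx_inner_chain_map(transform, samples$points)
  eta <- 1 / nrow(pts)
  g <- active$grid
  G <- prod(g$shape)
  coef <- matrix(active$coefficients, G, d)
  loc <- vx_bsp_locate(g, pts, active$order)
  ins <- which(loc$inside)
  deriv <- numeric(d * G)
  if (length(ins) == 0 || active$order < 2)
    return(structure(list(value = 0, derivative = deriv,
                          samples_used = nrow(pts)),
                     class = "vxmetricreport"))
  i0 <- loc$i0[ins, , drop = FALSE]; tf <- loc$tfrac[ins, , drop = FALSE]
  Mch <- solve(g$direction %*% diag(g$spacing, d))    # du/dx
  # basis second-derivative tensors per unordered axis pair
  pairs <- which(upper.tri(diag(d), diag = TRUE), arr.ind = TRUE)
  W2 <- vector("list", nrow(pairs)); IDX <- NULL
  for (pi in seq_len(nrow(pairs))) {
    dflags <- integer(d)
    ax <- pairs[pi, 1]; bx <- pairs[pi, 2]
    dflags[ax] <- dflags[ax] + 1L; dflags[bx] <- dflags[bx] + 1L
    tp <- vx_bsp_tensor(i0, tf, g$shape, active$order, dflags)
    W2[[pi]] <- tp$W
    IDX <- tp$IDX
  }
  pair_index <- matrix(0L, d, d)
  for (pi in seq_len(nrow(pairs))) {
    pair_index[pairs[pi, 1], pairs[pi, 2]] <- pi
    pair_index[pairs[pi, 2], pairs[pi, 1]] <- pi
  }
  value <- 0
  for (r in seq_len(d)) for (l in r:d) {
    wt <- if (l == r) 1 else 2                 # symmetric off-diagonal terms
    # H[i, p] = sum_{ax, bx} W2_{ax bx}[i, p] * Mch[ax, r] * Mch[bx, l]
    H <- 0
    for (ax in seq_len(d)) for (bx in seq_len(d)) {
      co <- Mch[ax, r] * Mch[bx, l]
      if (co != 0) H <- H + co * W2[[pair_index[ax, bx]]]
    }
    for (q in seq_len(d)) {
      Sq <- rowSums(H * matrix(coef[IDX, q], nrow(H)))
      value <- value + wt * sum(Sq * Sq)
      deriv[(q - 1L) * G + seq_len(G)] <- deriv[(q - 1L) * G + seq_len(G)] +
        vx_bsp_scatter(H, IDX, 2 * wt * Sq, G)
    }
  }
  structure(list(value = value * eta, derivative = deriv * eta,
                 samples_used = nrow(pts)),
            class = "vxmetricreport")
}
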