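## Cohort-level operations: unbiased template-space construction from
## pairwise transforms, template-image averaging, multi-atlas label fusion,
## Jacobian-determinant modulation, region-wise volume features, and the
## comparison measures (nRMSE, deformation-field RMSE, Dice).

#' A graph of pairwise inter-subject transforms
#'
#' Stores the transforms `W[i,j]` mapping subject i's domain into subject
#' j's domain, as produced by registering image i (fixed) to image j
#' (moving). The self-transform `W[i,i]` is the identity and need not be
#' supplied.
#'
#' @param subjects Character vector of subject identifiers.
#' @param pairwise Named list of `vxtransform`s with names `"i|j"` (subject
#'   identifiers separated by `|`).
#' @return A `vxtransformgraph`.
#' @export
vx_transform_graph <- function(subjects, pairwise = list()) {
  structure(list(subjects = subjects, pairwise = pairwise),
            class = "vxtransformgraph")
}

vx_graph_get <- function(graph, i, j) {
  if (identical(i, j)) return(NULL)          # identity, handled by caller
  key <- paste(i, j, sep = "|")
  tr <- graph$pairwise[[key]]
  if (is.null(tr))
    vx_stop("vx_contract_error", sprintf("transform '%s' missing from graph", key))
  tr
}

#' Build the template-space transforms for one subject
#'
#' Averages subject i's pairwise transforms over all subjects j (the
#' identity `W[i,i]` included) into `U_i(x) = (1/N) sum_j W_ij(x)`, the map
#' from subject i's space to the unbiased template space, then numerically
#' inverts it to obtain `V_i = U_i^{-1}` (template -> subject), the transform
#' through which images are pulled into template space.
#'
#' @param graph A `vxtransformgraph` containing `W[i,j]` for all j != i.
#' @param subject Subject identifier i.
#' @param geometry `vxgeometry` of subject i's image domain (the grid on
#'   which U and V are sampled).
#' @param tolerance,max_iter Passed to [vx_invert_transform()].
#' @return List with `U`, `V` (displacement-field `vxtransform`s) and
#'   `residual` (max inversion residual, mm).
#' @export
vx_build_template_transform <- function(graph, subject, geometry,
                                        tolerance = 0.01, max_iter = 50L) {
  others <- setdiff(graph$subjects, subject)
  trs <- lapply(others, function(j) vx_graph_get(graph, subject, j))
  U <- vx_average_transforms(trs, geometry, include_identity = TRUE)
  V <- vx_invert_transform(U, geometry, tolerance, max_iter)
  list(U = U, V = V, residual = attr(V, "residual"))
}

#' Average images into a template image
#'
#' Computes the voxelwise mean of each image resampled through its
#' template-to-subject transform `V_i` onto the template geometry (linear
#' interpolation): the template intensity is `(1/N) sum_i I_i(V_i(x))`.
#'
#' @param images List of `vximage`s.
#' @param transforms List of transforms `V_i` (template -> subject), one per
#'   image.
#' @param geometry Template `vxgeometry`.
#' @return The template `vximage`.
#' @export
vx_build_template_image <- function(images, transforms, geometry) {
  if (length(images) != length(transforms))
    vx_stop("vx_contract_error", "one transform per image is required")
  acc <- array(0, geometry$shape)
  for (i in seq_along(images)) {
    r <- vx_resample(images[[i]], transforms[[i]], geometry, "linear")
    acc <- acc + r$data
  }
  vx_image(acc / length(images), geometry$origin, geometry$spacing,
           geometry$direction, domain_id = "template")
}

#' Fuse propagated label images by majority voting
#'
#' Per voxel, the most frequent label wins; ties are broken toward the
#' smallest label value, which makes the result invariant to the order of
#' the atlases.
#'
#' @param propagated_labels List of `vxlabelimage`s on a common geometry.
#' @return The fused `vxlabelimage`.
#' @export
vx_majority_vote_fusion <- function(propagated_labels) {
  if (length(propagated_labels) < 1)
    vx_stop("vx_contract_error", "need at least one label image")
  g0 <- vx_geometry_of(propagated_labels[[1]])
  for (li in propagated_labels) {
    gi <- vx_geometry_of(li)
    if (!isTRUE(all.equal(g0, gi, tolerance = 1e-10)))
      vx_stop("vx_contract_error", "label images must share geometry")
  }
  stack <- vapply(propagated_labels, function(li) as.vector(li$data),
                  numeric(prod(g0$shape)))
  stack <- matrix(stack, ncol = length(propagated_labels))
  labels <- sort(unique(as.vector(stack)))
  best_count <- rep(-1L, nrow(stack))
  best_label <- rep(0L, nrow(stack))
  for (lab in labels) {                       # ascending: ties -> smallest
    cnt <- rowSums(stack == lab)
    take <- cnt > best_count
    best_label[take] <- lab
    best_count[take] <- cnt[take]
  }
  vx_label_image(array(best_label, g0$shape), g0$origin, g0$spacing,
                 g0$direction)
}

#' Modulate a warped probabilistic map by the Jacobian determinant
#'
#' Multiplies a probabilistic tissue map, already resampled into template
#' space through `transform`, voxelwise by the spatial Jacobian determinant
#' of that transform. This preserves the integrated tissue volume under the
#' warp: the modulated map integrated over template space equals the
#' original map integrated over subject space (within interpolation error)
#' for smooth invertible transforms.
#'
#' @param map `vximage` with values in `[0, 1]`, living on the template
#'   geometry.
#' @param transform The template -> subject transform used to warp it.
#' @return The modulated `vximage`. Negative determinants (local folding)
#'   raise a warning with their count.
#' @export
vx_modulate <- function(map, transform) {
  pts <- vx_grid_points(vx_geometry_of(map))
  dets <- vx_spatial_jacobian_determinant(transform, pts)
  nneg <- sum(dets < 0)
  if (nneg > 0)
    warning(sprintf("%d voxel(s) with negative Jacobian determinant (folding)", nneg))
  out <- map
  out$data <- map$data * array(dets, dim(map$data))
  out
}

#' Region-wise volume features from a probabilistic map
#'
#' For each region label r, sums the probabilistic map over the voxels
#' carrying that label, multiplies by the voxel volume and divides by the
#' intracranial volume: `feature_r = (sum_{label==r} map) * voxvol / icv`.
#'
#' @param gm_map Probabilistic `vximage` (e.g. gray-matter density).
#' @param labels `vxlabelimage` on the same geometry.
#' @param icv Normalizing volume (mm^3), e.g. intracranial volume.
#' @param region_labels Labels to report (default: all nonzero labels in
#'   `labels`); absent labels yield 0 with a warning.
#' @param exclude Labels to drop from the default report list.
#' @return Named numeric vector of features, one per region.
#' @export
vx_region_volume_features <- function(gm_map, labels, icv,
                                      region_labels = NULL, exclude = integer(0)) {
  stopifnot(icv > 0)
  if (!all(dim(gm_map$data) == dim(labels$data)))
    vx_stop("vx_contract_error", "map and labels must share geometry")
  if (is.null(region_labels))
    region_labels <- setdiff(sort(unique(as.vector(labels$data))), c(0L, exclude))
  else region_labels <- setdiff(region_labels, exclude)
  voxvol <- vx_voxel_volume(gm_map)
  sums <- rowsum(as.vector(gm_map$data), as.vector(labels$data))
  have <- as.integer(rownames(sums))
  out <- setNames(numeric(length(region_labels)), as.character(region_labels))
  for (i in seq_along(region_labels)) {
    r <- region_labels[i]
    j <- match(r, have)
    if (is.na(j)) {
      warning(sprintf("label %d absent; feature set to 0", r))
    } else out[i] <- sums[j, 1] * voxvol / icv
  }
  out
}

## Comparison measures ---------------------------------------------------------

#' Normalized root mean square error between two images
#'
#' `nRMSE = sqrt( sum((ref - test)^2) / sum(ref^2) )`.
#'
#' @param reference,test `vximage`s (or plain arrays) of identical shape.
#' @return Scalar nRMSE.
#' @export
vx_nrmse <- function(reference, test) {
  a <- if (inherits(reference, "vximage")) reference$data else reference
  b <- if (inherits(test, "vximage")) test$data else test
  if (!all(dim(a) == dim(b)))
    vx_stop("vx_contract_error", "shapes differ")
  denom <- sum(a * a)
  if (denom == 0)
    vx_stop("vx_degenerate_error", "reference image is identically zero")
  sqrt(sum((a - b)^2) / denom)
}

#' RMSE between two deformation fields
#'
#' Root mean square of the per-voxel Euclidean distance between two
#' displacement (or position) fields sampled on the same grid, optionally
#' within a mask.
#'
#' @param field_a,field_b Arrays of shape `c(shape, d)`.
#' @param mask Optional `vxlabelimage` (or array); only voxels with nonzero
#'   mask contribute.
#' @return Scalar RMSE (mm).
#' @export
vx_field_rmse <- function(field_a, field_b, mask = NULL) {
  if (!all(dim(field_a) == dim(field_b)))
    vx_stop("vx_contract_error", "field shapes differ")
  dmn <- dim(field_a)
  d <- dmn[length(dmn)]
  n <- prod(dmn) / d
  diff <- matrix(field_a - field_b, n, d)
  sq <- rowSums(diff * diff)
  if (!is.null(mask)) {
    mv <- if (inherits(mask, "vximage")) as.vector(mask$data) else as.vector(mask)
    keep <- mv != 0
    if (!any(keep)) vx_stop("vx_degenerate_error", "mask has no nonzero voxels")
    sq <- sq[keep]
  }
  sqrt(mean(sq))
}

#' Dice overlap coefficient for one label
#'
#' `2 |A n B| / (|A| + |B|)` for the voxel sets carrying `label` in each
#' image; defined as 1 when both sets are empty (perfect agreement of
#' absence).
#'
#' @param labels_a,labels_b `vxlabelimage`s on a common geometry.
#' @param label Label value to compare.
#' @return Scalar in `[0, 1]`.
#' @export
vx_dice <- function(labels_a, labels_b, label) {
  if (!all(dim(labels_a$data) == dim(labels_b$data)))
    vx_stop("vx_contract_error", "label images must share geometry")
  a <- labels_a$data == label
  b <- labels_b$data == label
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

## Feature tables ---------------------------------------------------------------

#' Subject-by-feature tables and z-score normalization
#'
#' A feature table holds one row per subject and one column per feature
#' (voxel-wise or region-wise). `vx_zscore_features()` normalizes every
#' column to zero mean and unit variance, with mean and standard deviation
#' fitted on `fit_rows` (e.g. the training subjects) and applied to all rows.
#' The population convention `sd = sqrt(sum((x - mean)^2) / n)` is used.
#' Columns constant on the fit rows are set to zero with a warning.
#'
#' @param values Numeric matrix with subject rownames.
#' @param normalization `"raw"` or `"z-scored"`.
#' @param table A `vxfeaturetable`.
#' @param fit_rows Row names or indices used to fit the normalization
#'   (default all rows).
#' @return A `vxfeaturetable`.
#' @export
vx_feature_table <- function(values, normalization = "raw") {
  stopifnot(is.matrix(values))
  structure(list(values = values, normalization = normalization),
            class = "vxfeaturetable")
}

#' @rdname vx_feature_table
#' @export
vx_zscore_features <- function(table, fit_rows = NULL) {
  v <- table$values
  if (is.null(fit_rows)) fit_rows <- seq_len(nrow(v))
  fit <- v[fit_rows, , drop = FALSE]
  if (nrow(fit) < 2)
    vx_stop("vx_contract_error", "need >= 2 fit rows")
  mu <- colMeans(fit)
  sd_pop <- sqrt(colMeans(sweep(fit, 2, mu)^2))
  out <- sweep(v, 2, mu)
  const <- sd_pop <= 0
  if (any(const)) {
    warning(sprintf("%d constant feature column(s) set to zero", sum(const)))
    out[, const] <- 0
    sd_pop[const] <- 1
  }
  out <- sweep(out, 2, sd_pop, "/")
  vx_feature_table(out, normalization = "z-scored")
}

#' @rdname vx_feature_table
#' @param path Tab-separated output file (header row = feature names, first
#'   column = subject).
#' @export
vx_write_feature_table <- function(table, path) {
  df <- data.frame(subject = rownames(table$values), table$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname vx_feature_table
#' @export
vx_read_feature_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  vx_feature_table(v)
}
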