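test_that("template transforms average and invert per the graph", {
  g <- vx_geometry(c(12, 12))
  pts <- voxreg:::vx_grid_points(g)
  subs <- c("s1", "s2", "s3")
  # all W identity -> U = V = identity
  pw <- list("s1|s2" = vx_identity_transform(2), "s1|s3" = vx_identity_transform(2))
  bt <- vx_build_template_transform(vx_transform_graph(subs, pw), "s1", g)
  expect_lt(max(abs(vx_map_point(bt$U, pts) - pts)), 1e-12)
  expect_lt(max(abs(vx_map_point(bt$V, pts) - pts)), 1e-10)
  # all W equal to one translation t (identity included): U = 2t/3, V = -2t/3
  t <- c(1.5, -0.9)
  pw2 <- list("s1|s2" = vx_translation(t), "s1|s3" = vx_translation(t))
  bt2 <- vx_build_template_transform(vx_transform_graph(subs, pw2), "s1", g,
                                     tolerance = 1e-8, max_iter = 200)
  expect_lt(max(abs(vx_map_point(bt2$U, pts) - sweep(pts, 2, 2 * t / 3, "+"))), 1e-12)
  expect_lt(max(abs(vx_map_point(bt2$V, pts) - sweep(pts, 2, 2 * t / 3, "-"))), 1e-6)
  # random smooth warps: round-trip residual within tolerance
  g2 <- vx_geometry(c(16, 16))
  pw3 <- list("s1|s2" = random_bspline(g2, 8, 1, seed = 70),
              "s1|s3" = random_bspline(g2, 8, 1, seed = 71))
  bt3 <- vx_build_template_transform(vx_transform_graph(subs, pw3), "s1", g2,
                                     tolerance = 0.01)
  pts2 <- voxreg:::vx_grid_points(g2)
  rt <- vx_map_point(bt3$U, vx_map_point(bt3$V, pts2))
  expect_lt(max(sqrt(rowSums((rt - pts2)^2))), 0.01 + 1e-9)
  expect_lte(bt3$residual, 0.01)
})

test_that("template image averaging matches the per-voxel oracle", {
  g <- vx_geometry(c(10, 10))
  imgs <- list(vx_image(matrix(2, 10, 10)), vx_image(matrix(4, 10, 10)))
  ids <- list(vx_identity_transform(2), vx_identity_transform(2))
  tmpl <- vx_build_template_image(imgs, ids, g)
  expect_true(all(tmpl$data == 3))
  # identical images + identity -> that image
  set.seed(72)
  im <- vx_image(matrix(runif(100), 10, 10))
  tmpl2 <- vx_build_template_image(list(im, im, im), rep(list(vx_identity_transform(2)), 3), g)
  expect_lt(max(abs(tmpl2$data - im$data)), 1e-10)
  # nontrivial transforms against a direct loop oracle
  trs <- list(vx_translation(c(0.7, -0.3)), random_bspline(g, 6, 0.8, seed = 73))
  tmpl3 <- vx_build_template_image(list(im, im), trs, g)
  pts <- voxreg:::vx_grid_points(g)
  ip <- vx_interpolator(im, "linear")
  oracle <- (vx_evaluate(ip, vx_map_point(trs[[1]], pts)) +
               vx_evaluate(ip, vx_map_point(trs[[2]], pts))) / 2
  expect_lt(max(abs(tmpl3$data - array(oracle, c(10, 10)))), 1e-10)
  expect_error(vx_build_template_image(list(im), trs, g), class = "vx_contract_error")
})

test_that("majority voting fuses labels with order-invariant smallest-label ties", {
  mk <- function(v) vx_label_image(array(v, c(2, 2)))
  a <- mk(c(1, 1, 2, 0)); b <- mk(c(1, 2, 2, 0)); c_ <- mk(c(2, 1, 2, 3))
  fused <- vx_majority_vote_fusion(list(a, b, c_))
  expect_equal(as.vector(fused$data), c(1, 1, 2, 0))
  # tie {1, 2} -> smallest label
  t1 <- mk(c(1, 0, 0, 0)); t2 <- mk(c(2, 0, 0, 0))
  expect_equal(vx_majority_vote_fusion(list(t1, t2))$data[1, 1], 1L)
  # atlas-order invariance over permutations
  perms <- list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))
  base <- vx_majority_vote_fusion(list(a, b, c_))
  for (p in perms)
    expect_identical(vx_majority_vote_fusion(list(a, b, c_)[p])$data, base$data)
  # all atlases agree -> that labeling
  expect_identical(vx_majority_vote_fusion(list(a, a, a))$data, a$data)
  bad <- vx_label_image(array(0L, c(3, 3)))
  expect_error(vx_majority_vote_fusion(list(a, bad)), class = "vx_contract_error")
})

test_that("modulation conserves integrated mass under smooth warps", {
  # identity: map unchanged
  g <- vx_geometry(c(20, 20))
  set.seed(74)
  map <- vx_image(matrix(runif(400), 20, 20))
  expect_identical(vx_modulate(map, vx_identity_transform(2))$data, map$data)
  # global shrink by s per axis: warped map x s^d integrates to the original
  s <- 0.8
  shrink <- vx_affine(s * diag(2), center = c(9.5, 9.5))
  mod <- vx_modulate(map, shrink)
  expect_equal(mod$data, map$data * s^2, tolerance = 1e-12)
  # smooth synthetic warp: compare template-space integral of the modulated
  # pullback with the subject-space integral of the original
  spec <- vx_fixture_spec(c(32, 32), seed = 75, warp_spacing = 12, warp_max_disp = 2.5)
  gg <- vx_geometry(c(32, 32))
  W <- voxreg:::vx_random_warp(gg, 12, 2.5, seed = 76)
  # probabilistic map supported well inside the domain
  pts <- voxreg:::vx_grid_points(gg)
  blob <- exp(-rowSums(sweep(pts, 2, c(15.5, 15.5))^2) / (2 * 4^2))
  subj <- vx_image(array(blob, c(32, 32)))
  warped <- vx_resample(subj, W, gg, "linear")       # map pulled into template
  modded <- vx_modulate(warped, W)
  orig_mass <- sum(subj$data) * voxreg:::vx_voxel_volume(gg)
  mod_mass <- sum(modded$data) * voxreg:::vx_voxel_volume(gg)
  expect_lt(abs(mod_mass / orig_mass - 1), 0.01)
})

test_that("region volume features follow the accumulation arithmetic", {
  lab <- vx_label_image(array(c(rep(1L, 10), rep(2L, 20), rep(0L, 34)), c(8, 8)),
                        spacing = c(1, 2))   # voxel volume 2 mm^2
  gm1 <- vx_image(array(1, c(8, 8)), spacing = c(1, 2))
  f <- vx_region_volume_features(gm1, lab, icv = 1000)
  expect_equal(unname(f["1"]), 10 * 2 / 1000)
  expect_equal(unname(f["2"]), 20 * 2 / 1000)
  # zero map -> zero features
  gm0 <- vx_image(array(0, c(8, 8)), spacing = c(1, 2))
  expect_true(all(vx_region_volume_features(gm0, lab, 1000) == 0))
  # per-voxel oracle on random data + exclusion + absent label warning
  set.seed(77)
  gmr <- vx_image(array(runif(64), c(8, 8)), spacing = c(1, 2))
  fr <- vx_region_volume_features(gmr, lab, 500, exclude = 2L)
  expect_identical(names(fr), "1")
  expect_equal(unname(fr["1"]), sum(gmr$data[lab$data == 1]) * 2 / 500)
  expect_warning(vx_region_volume_features(gmr, lab, 500, region_labels = c(1, 9)),
                 "absent")
})

test_that("nRMSE, field RMSE and Dice match hand calculations", {
  a <- vx_image(matrix(c(3, 0, 0, 0), 2, 2))
  expect_equal(vx_nrmse(a, a), 0)
  two <- a; two$data <- 2 * a$data
  expect_equal(vx_nrmse(a, two), 1)
  b <- vx_image(matrix(c(4, 0, 0, 0), 2, 2))
  expect_equal(vx_nrmse(a, b), 1 / 3)
  expect_error(vx_nrmse(vx_image(matrix(0, 2, 2)), a), class = "vx_degenerate_error")
  # field RMSE
  f1 <- array(0, c(4, 4, 2))
  f2 <- f1; f2[, , 1] <- 3; f2[, , 2] <- 4
  expect_equal(vx_field_rmse(f1, f1), 0)
  expect_equal(vx_field_rmse(f1, f2), 5)
  set.seed(78)
  fa <- array(rnorm(4 * 4 * 2), c(4, 4, 2)); fb <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  oracle <- sqrt(mean(apply((fa - fb)^2, c(1, 2), sum)))
  expect_equal(vx_field_rmse(fa, fb), oracle)
  msk <- vx_label_image(array(c(rep(1L, 8), rep(0L, 8)), c(4, 4)))
  oracle_m <- sqrt(mean(apply((fa - fb)^2, c(1, 2), sum)[msk$data == 1]))
  expect_equal(vx_field_rmse(fa, fb, msk), oracle_m)
  # Dice
  la <- vx_label_image(array(c(1, 1, 1, 1, 0, 0, 0, 0, 0), c(3, 3)))
  lb <- vx_label_image(array(c(1, 1, 0, 0, 1, 1, 0, 0, 0), c(3, 3)))
  expect_equal(vx_dice(la, la, 1), 1)
  expect_equal(vx_dice(la, lb, 1), 0.5)      # |A|=|B|=4, overlap 2
  expect_equal(vx_dice(la, lb, 7), 1)        # both empty -> 1
  disj <- vx_label_image(array(c(0, 0, 0, 0, 0, 1, 1, 1, 1), c(3, 3)))
  expect_equal(vx_dice(la, disj, 1), 0)
})

test_that("z-scoring uses population sd fitted on the training rows", {
  tb <- vx_feature_table(matrix(c(1, 3, 10, 20), 2, 2,
                                dimnames = list(c("a", "b"), c("f1", "f2"))))
  z <- vx_zscore_features(tb)
  expect_equal(unname(z$values[, "f1"]), c(-1, 1))   # sd_pop(1,3) = 1
  expect_equal(z$normalization, "z-scored")
  # idempotence
  z2 <- vx_zscore_features(z)
  expect_lt(max(abs(z2$values - z$values)), 1e-12)
  # fit rows only; applied to all rows; fit-row means are zero
  v <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("s", 1:5), paste0("f", 1:4)))
  z3 <- vx_zscore_features(vx_feature_table(v), fit_rows = 1:3)
  expect_lt(max(abs(colMeans(z3$values[1:3, ]))), 1e-12)
  expect_lt(max(abs(colMeans(z3$values[1:3, ]^2) - 1)), 1e-10)
  # constant column warning
  vc <- cbind(v, const = 1)
  expect_warning(vx_zscore_features(vx_feature_table(vc), fit_rows = 1:3), "constant")
  # TSV round trip
  td <- withr::local_tempdir()
  p <- file.path(td, "features.tsv")
  vx_write_feature_table(z3, p)
  back <- vx_read_feature_table(p)
  expect_equal(back$values, z3$values, tolerance = 1e-12)
})
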