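test_that("kernel weights follow the anisotropic Gaussian closed form", {
  p <- filter_params()
  k <- build_kernel(c(0, 0, 1), p, c(0.2, 0.2, 0.2))
  expect_equal(sum(k), 1)
  expect_true(all(k >= 0))
  c0 <- k[3, 3, 3]
  # one voxel (0.2 mm) along the radial axis: exp(-0.5 * (0.2/0.1)^2)
  expect_equal(k[3, 3, 4] / c0, exp(-2), tolerance = 1e-12)
  # one voxel in the tangent plane: exp(-0.5 * (0.2/1.0)^2)
  expect_equal(k[4, 3, 3] / c0, exp(-0.02), tolerance = 1e-12)
  # rotational symmetry about the radial axis
  expect_equal(k[4, 3, 3], k[3, 4, 3], tolerance = 1e-12)
  # full tangential support width: 5 voxels x 0.2 mm = 1 mm
  expect_equal(filter_support_mm(p, c(0.2, 0.2, 0.2)), 1.0)
  expect_error(build_kernel(c(0, 0, 0), p, c(0.2, 0.2, 0.2)), "nonzero")
  expect_error(filter_params(support = 4), "odd")
  expect_error(filter_params(sigma_radial = 0), "sigmas")
})

test_that("vectorized filtering equals explicit per-voxel kernel sums", {
  ph <- make_phantom(phantom_spec(hemi_width = 5L, length = 12L, n_areas = 3L,
                                  seed = 9L))
  g <- ph$grid
  fr <- cortical_frame(ph$gm_mask, ph$wm_mask, g)
  set.seed(2)
  vol <- array(rnorm(prod(g$shape)), g$shape)
  out <- apply_crf_filter(vol, fr)
  # check a handful of interior defined voxels against build_kernel directly
  idx <- which(fr$defined_mask)
  co <- vox_coords_test(idx, g$shape)
  interior <- idx[co[, 1] > 2 & co[, 1] < g$shape[1] - 1 &
                    co[, 3] > 2 & co[, 3] < g$shape[3] - 1]
  set.seed(3)
  for (v in sample(interior, 5)) {
    cv <- vox_coords_test(v, g$shape)
    r <- c(fr$radial[, , , 1][v], fr$radial[, , , 2][v], fr$radial[, , , 3][v])
    kern <- build_kernel(r, filter_params(), g$voxel_size)
    block <- vol[cv[1] + (-2:2), cv[2] + (-2:2), cv[3] + (-2:2)]
    expect_equal(out[v], sum(kern * block), tolerance = 1e-12)
  }
})

test_that("constant fields pass through exactly and shapes are checked", {
  ph <- make_phantom(phantom_spec(hemi_width = 5L, length = 12L, n_areas = 3L,
                                  seed = 9L))
  fr <- cortical_frame(ph$gm_mask, ph$wm_mask, ph$grid)
  vol <- array(3.25, ph$grid$shape)
  out <- apply_crf_filter(vol, fr)
  expect_equal(out, vol, tolerance = 1e-12)
  expect_error(apply_crf_filter(array(0, c(2, 2, 2)), fr), "shape mismatch")
  # voxels without a defined frame are untouched
  set.seed(4)
  vol2 <- array(rnorm(prod(ph$grid$shape)), ph$grid$shape)
  out2 <- apply_crf_filter(vol2, fr)
  expect_identical(out2[!fr$defined_mask], vol2[!fr$defined_mask])
})

test_that("iid noise variance is reduced by the kernel's sum of squares", {
  ph <- make_phantom(phantom_spec(hemi_width = 8L, length = 30L, seed = 5L))
  g <- ph$grid
  fr <- cortical_frame(ph$gm_mask, ph$wm_mask, g)
  nrep <- 100L
  set.seed(7)
  dat <- array(rnorm(prod(g$shape) * nrep), c(g$shape, nrep))
  sch <- gradient_scheme(rep(1000, nrep),
                         matrix(rep(c(0, 0, 1), nrep), ncol = 3, byrow = TRUE))
  dw <- structure(list(data = dat, scheme = sch, grid = g, s0 = 1),
                  class = "dwi_set")
  fd <- filter_dwi_set(dw, fr)
  sw2 <- filter_variance_gain(fr)
  idx <- which(fr$defined_mask)
  co <- vox_coords_test(idx, g$shape)
  interior <- idx[co[, 1] > 3 & co[, 1] < g$shape[1] - 2 &
                    co[, 3] > 3 & co[, 3] < g$shape[3] - 2]
  emp <- apply(fd$data, c(1, 2, 3), var)
  expect_lt(abs(mean(emp[interior]) / mean(sw2[interior]) - 1), 0.05)
})

test_that("the filter smooths tangentially, not across layers", {
  # coarse sampling (0.4 mm) so that the radial taps of the 0.1 mm Gaussian
  # are negligible and the orientation effect is isolated
  ph <- make_phantom(phantom_spec(hemi_width = 12L, length = 40L,
                                  voxel_size = 0.4, seed = 5L))
  g <- ph$grid
  fr <- cortical_frame(ph$gm_mask, ph$wm_mask, g)
  dep <- compute_depth(ph$gm_mask, ph$wm_mask, g, mode = "equidistant")
  lay <- equivolume_layers(dep, ph$gm_mask, 3L)
  means <- c(1, 2, 1.2)
  sig <- array(0, g$shape)
  sig[lay > 0L] <- means[lay[lay > 0L]]
  fok <- apply_crf_filter(sig, fr)
  fsw <- apply_crf_filter(sig, fr, filter_params(sigma_radial = 1.0,
                                                 sigma_tangential = 0.1))
  layer_means <- function(v) sapply(1:3, function(l) mean(v[lay == l]))
  truth <- layer_means(sig)
  rng <- diff(range(truth))
  dev_ok <- max(abs(layer_means(fok) - truth)) / rng
  dev_sw <- max(abs(layer_means(fsw) - truth)) / rng
  expect_lt(dev_ok, 0.02)
  expect_gt(dev_sw, 0.20)
})

test_that("4D filtering equals per-volume application and is deterministic", {
  ph <- make_phantom(phantom_spec(hemi_width = 5L, length = 12L, n_areas = 3L,
                                  seed = 9L))
  g <- ph$grid
  fr <- cortical_frame(ph$gm_mask, ph$wm_mask, g)
  set.seed(5)
  dat <- array(rnorm(prod(g$shape) * 3), c(g$shape, 3))
  sch <- gradient_scheme(c(100, 1000, 1000),
                         rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  dw <- structure(list(data = dat, scheme = sch, grid = g, s0 = 1),
                  class = "dwi_set")
  fd <- filter_dwi_set(dw, fr)
  expect_identical(fd$scheme, sch)
  for (v in 1:3)
    expect_equal(fd$data[, , , v], apply_crf_filter(dat[, , , v], fr),
                 tolerance = 1e-14)
  fd2 <- filter_dwi_set(dw, fr)
  expect_identical(fd$data, fd2$data)
  # scheme/stack mismatch rejected
  bad <- dw; bad$scheme <- gradient_scheme(1000, matrix(c(0, 0, 1), 1))
  expect_error(filter_dwi_set(bad, fr), "volume count")
  # repeated filtering keeps smoothing a layered signal (not idempotent)
  sig <- array(rep(seq_len(g$shape[3]) %% 4, each = g$shape[1] * g$shape[2]),
               g$shape)
  once <- apply_crf_filter(sig, fr)
  twice <- apply_crf_filter(once, fr)
  expect_gt(max(abs(twice - once)), 1e-6)
})

test_that("mask restriction renormalizes over cortical neighbors", {
  ph <- make_phantom(phantom_spec(hemi_width = 5L, length = 12L, n_areas = 3L,
                                  seed = 9L))
  fr <- cortical_frame(ph$gm_mask, ph$wm_mask, ph$grid)
  # signal constant inside GM, wild outside: restricted filter ignores outside
  vol <- array(100, ph$grid$shape)
  vol[ph$gm_mask] <- 2
  out <- apply_crf_filter(vol, fr, filter_params(mask_restrict = TRUE),
                          mask = ph$gm_mask)
  expect_equal(out[fr$defined_mask], rep(2, sum(fr$defined_mask)),
               tolerance = 1e-12)
})
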