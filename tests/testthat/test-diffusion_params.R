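test_that("closed-form symmetric eigenvalues match eigen()", {
  set.seed(1)
  for (i in 1:50) {
    A <- matrix(rnorm(9), 3)
    S <- crossprod(A) * 1e-3 + diag(1e-5, 3)
    D6 <- c(S[1, 1], S[2, 2], S[3, 3], S[1, 2], S[1, 3], S[2, 3])
    got <- unname(sort(cytoseg:::eig3sym_vals(matrix(D6, 1))[1, ],
                       decreasing = TRUE))
    ref <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("DTI scalars follow the eigenvalue formulas", {
  pm <- cytoseg:::param_maps_from_eigs(1.7e-3, 0.3e-3, 0.3e-3, 0.026)
  expect_equal(pm$MD, 0.76667e-3, tolerance = 1e-4)
  expect_equal(pm$AD, 1.7e-3)
  expect_equal(pm$RD, 0.3e-3)
  # sqrt(3/2)*sqrt(sum((l-MD)^2))/sqrt(sum(l^2)) for (1.7, 0.3, 0.3)e-3,
  # frozen from two independent evaluations of the formula
  expect_equal(pm$FA, 0.799023, tolerance = 1e-6)
  iso <- cytoseg:::param_maps_from_eigs(1e-3, 1e-3, 1e-3, 0.026)
  expect_equal(iso$FA, 0)
  expect_equal(iso$AD, iso$MD)
  expect_equal(iso$RD, iso$MD)
})

test_that("scalar maps are rotation invariant", {
  set.seed(2)
  base <- diag(c(1.7, 0.5, 0.2) * 1e-3)
  vals0 <- NULL
  for (i in 1:10) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    D <- Q %*% base %*% t(Q)
    D6 <- matrix(c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3]), 1)
    tf <- tensor_field(D6, idx = 1L, grid = vol_grid(c(1, 1, 1)))
    e <- tf$eigenvalues
    pm <- cytoseg:::param_maps_from_eigs(e[, 1], e[, 2], e[, 3], 0.026)
    v <- unlist(pm)
    if (is.null(vals0)) vals0 <- v else expect_equal(v, vals0, tolerance = 1e-10)
  }
})

test_that("zero-displacement probabilities have the Gaussian closed forms", {
  sch <- study_scheme()
  expect_equal(sch$tau_s, 0.026)
  iso <- cytoseg:::param_maps_from_eigs(1e-3, 1e-3, 1e-3, 0.026)
  expect_equal(iso$RTOP, (4 * pi * 0.026 * 1e-3)^(-3 / 2), tolerance = 1e-12)
  expect_equal(iso$RTOP, 1.693e5, tolerance = 1e-3)
  # RTOP = RTAP * RTPP identically
  set.seed(3)
  l1 <- runif(100, 0.5e-3, 2e-3)
  l2 <- runif(100, 0.2e-3, 1e-3)
  l3 <- runif(100, 0.1e-3, 1e-3)
  pm <- cytoseg:::param_maps_from_eigs(pmax(l1, l2, l3), l2, pmin(l1, l2, l3), 0.026)
  expect_lt(max(abs(pm$RTOP - pm$RTAP * pm$RTPP) / pm$RTOP), 1e-10)
})

test_that("propagator anisotropy matches a numeric Gaussian-overlap oracle", {
  pm <- cytoseg:::param_maps_from_eigs(1.7e-3, 0.2e-3, 0.2e-3, 0.026)
  expect_equal(pm$PA, 0.610, tolerance = 1e-3)
  iso <- cytoseg:::param_maps_from_eigs(0.7e-3, 0.7e-3, 0.7e-3, 0.026)
  expect_equal(iso$PA, 0)

  # oracle: cos(theta) = <p, p_iso> / sqrt(<p,p><p_iso,p_iso>) with
  # inner products evaluated by brute-force grid integration of the two
  # Gaussian propagators N(0, 2 tau D) and N(0, 2 tau MD I)
  tau <- 0.026
  l <- c(1.7, 0.2, 0.2) * 1e-3
  md <- mean(l)
  gauss3 <- function(x, y, z, v) {
    exp(-0.5 * (x^2 / v[1] + y^2 / v[2] + z^2 / v[3])) /
      sqrt((2 * pi)^3 * prod(v))
  }
  s <- sqrt(2 * tau * max(l))
  gr <- seq(-5 * s, 5 * s, length.out = 61)
  h <- diff(gr[1:2])
  gx <- array(gr, c(61, 61, 61))
  gy <- aperm(gx, c(2, 1, 3))
  gz <- aperm(gx, c(3, 2, 1))
  p1 <- gauss3(gx, gy, gz, 2 * tau * l)
  p2 <- gauss3(gx, gy, gz, 2 * tau * rep(md, 3))
  ip <- function(a, b) sum(a * b) * h^3
  cos_num <- ip(p1, p2) / sqrt(ip(p1, p1) * ip(p2, p2))
  pa_num <- sqrt(1 - cos_num^2)
  expect_equal(pm$PA, pa_num, tolerance = 1e-3)
})

test_that("PA grows with tensor elongation at fixed mean diffusivity", {
  md <- 0.8e-3
  ratios <- c(1.5, 2, 3, 5, 8, 12)
  pa <- sapply(ratios, function(rr) {
    # axially symmetric: l1 = rr * l3, l2 = l3, constrained to MD
    l3 <- 3 * md / (rr + 2)
    cytoseg:::param_maps_from_eigs(rr * l3, l3, l3, 0.026)$PA
  })
  expect_true(all(diff(pa) > 0))
})

test_that("weighted tensor fit is exact on noiseless data and guards inputs", {
  ph <- make_phantom(phantom_spec(hemi_width = 4L, length = 9L, n_areas = 3L,
                                  seed = 2L))
  dw <- simulate_dwis(ph, study_scheme(), snr = Inf)
  tf <- fit_dti(dw, ph$gm_mask)
  truthD <- do.call(cbind, ph$tensors)
  rel <- abs(tf$D - truthD[match(tf$idx, ph$tissue_idx), ]) / max(abs(truthD))
  expect_lt(max(rel), 1e-6)
  maps <- parameter_maps(tf)
  expect_true(all(is.finite(c(maps$FA[tf$idx], maps$PA[tf$idx], maps$RTOP[tf$idx]))))
  # isotropic voxel fits to FA ~ 0
  iso <- ph
  n <- length(iso$tissue_idx)
  iso$tensors <- list(xx = rep(1e-3, n), yy = rep(1e-3, n), zz = rep(1e-3, n),
                      xy = rep(0, n), xz = rep(0, n), yz = rep(0, n))
  dwi <- simulate_dwis(iso, study_scheme(), snr = Inf)
  tfi <- fit_dti(dwi, ph$gm_mask)
  expect_lt(max(dti_scalars(tfi)$FA[tfi$idx]), 1e-6)
  # insufficient directions rejected
  sch6 <- gradient_scheme(rep(1000, 6), fibdirs(6))
  dw6 <- simulate_dwis(ph, sch6, snr = Inf)
  expect_error(fit_dti(dw6), "insufficient directions")
  # all-zero (background) voxels are excluded from the fit mask
  zidx <- which(!(ph$gm_mask | ph$wm_mask))[1]
  tf_all <- fit_dti(dw)
  expect_false(tf_all$fit_mask[zidx])
})

test_that("tensor fits stay finite at the strongest diffusion weighting", {
  ph <- make_phantom(phantom_spec(hemi_width = 4L, length = 9L, n_areas = 3L,
                                  seed = 2L))
  dw <- simulate_dwis(ph, study_scheme(), snr = 30, seed = 12L)
  expect_equal(max(dw$scheme$b_values), 10000)
  tf <- fit_dti(dw, ph$gm_mask)
  expect_true(all(is.finite(tf$D)))
  expect_true(all(tf$eigenvalues >= 1e-7))
})

test_that("scalar maps are robust at moderate noise", {
  ph <- make_phantom(phantom_spec(hemi_width = 6L, length = 18L, seed = 13L))
  dw <- simulate_dwis(ph, study_scheme(), snr = 20, seed = 14L)
  tf <- fit_dti(dw, ph$gm_mask)
  maps <- parameter_maps(tf)
  sel <- tf$idx
  md_true <- ph$true_params$MD[sel]
  fa_true <- ph$true_params$FA[sel]
  expect_lt(median(abs(maps$MD[sel] - md_true) / md_true), 0.05)
  expect_lt(median(abs(maps$FA[sel] - fa_true) / pmax(fa_true, 1e-3)), 0.10)
})
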