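test_that("flat slab: equivolume depth equals equidistant depth", {
  ph <- make_phantom(phantom_spec(hemi_width = 8L, length = 30L, seed = 5L))
  g <- ph$grid
  deq <- compute_depth(ph$gm_mask, ph$wm_mask, g, mode = "equidistant")
  dev <- compute_depth(ph$gm_mask, ph$wm_mask, g, mode = "equivolume")
  sel <- dev$defined_mask & deq$defined_mask
  expect_gt(sum(sel), 0)
  expect_lt(max(abs(dev$depth[sel] - deq$depth[sel])), 0.02)
  # boundary ordering: near WM shallow, near pial deep
  dims <- g$shape
  co <- vox_coords_test(which(sel), dims)
  ytop <- ph$spec$wm_thickness
  near_wm <- co[, 2] == ytop + 1L
  near_pial <- co[, 2] == ytop + ph$spec$gm_thickness
  expect_true(all(deq$depth[which(sel)[near_wm]] < 0.15))
  expect_true(all(deq$depth[which(sel)[near_pial]] > 0.85))
})

test_that("spherical shell: equivolume depth follows the cube-root law", {
  ph <- make_phantom(phantom_spec("spherical-shell", inner_radius = 8,
                                  outer_radius = 12, n_areas = 3L, seed = 3L))
  g <- ph$grid
  dev <- compute_depth(ph$gm_mask, ph$wm_mask, g, mode = "equivolume")
  deq <- compute_depth(ph$gm_mask, ph$wm_mask, g, mode = "equidistant")
  dims <- g$shape
  ctr <- (dims + 1) / 2
  idx <- which(dev$defined_mask)
  co <- vox_coords_test(idx, dims)
  r <- sqrt(colSums((t(co) - ctr)^2))
  mid <- abs(r - 10) < 0.2
  # r = 10 is the equidistant midpoint but the equivolume 0.4013 point:
  # (10^3 - 8^3) / (12^3 - 8^3)
  expect_lt(abs(mean(deq$depth[idx[mid]]) - 0.5), 0.06)
  expect_lt(abs(mean(dev$depth[idx[mid]]) - 0.4013), 0.05)
  an <- pmin(pmax((r^3 - 8^3) / (12^3 - 8^3), 0), 1)
  expect_lt(median(abs(dev$depth[idx] - an)), 0.04)
})

test_that("radial field is the normalized depth gradient", {
  # synthetic slab depth increasing along +z
  g <- vol_grid(c(8, 8, 12), c(0.2, 0.2, 0.2))
  depth <- aperm(array(seq(0, 1, length.out = 12), c(12, 8, 8)), c(2, 3, 1))
  gm <- array(TRUE, c(8, 8, 12))
  fr <- compute_radial(depth, gm, g)
  idx <- which(fr$defined_mask)
  expect_lt(max(abs(fr$radial[, , , 3][idx] - 1)), 1e-9)
  expect_lt(max(abs(fr$radial[, , , 1][idx])), 1e-9)
  nrm <- sqrt(fr$radial[, , , 1][idx]^2 + fr$radial[, , , 2][idx]^2 +
                fr$radial[, , , 3][idx]^2)
  expect_lt(max(abs(nrm - 1)), 1e-6)
})

test_that("spherical shell: radial aligns with the analytic normal", {
  ph <- make_phantom(phantom_spec("spherical-shell", inner_radius = 8,
                                  outer_radius = 12, n_areas = 3L, seed = 3L))
  fr <- cortical_frame(ph$gm_mask, ph$wm_mask, ph$grid, mode = "equidistant")
  dims <- ph$grid$shape
  ctr <- (dims + 1) / 2
  idx <- which(fr$defined_mask)
  co <- vox_coords_test(idx, dims)
  rr <- t(co) - ctr
  rn <- sqrt(colSums(rr^2))
  dp <- (fr$radial[, , , 1][idx] * rr[1, ] + fr$radial[, , , 2][idx] * rr[2, ] +
           fr$radial[, , , 3][idx] * rr[3, ]) / rn
  expect_gte(mean(dp > cos(10 * pi / 180)), 0.99)
})

test_that("radial field varies smoothly on a folded ribbon", {
  ph <- make_phantom(phantom_spec("sinusoidal-ribbon", hemi_width = 8L,
                                  length = 60L, seed = 6L))
  fr <- cortical_frame(ph$gm_mask, ph$wm_mask, ph$grid)
  dims <- ph$grid$shape
  def <- fr$defined_mask
  rx <- fr$radial[, , , 1]; ry <- fr$radial[, , , 2]; rz <- fr$radial[, , , 3]
  worst <- 1
  for (ax in 1:3) {
    n <- dims[ax]
    pick <- function(v, head) switch(ax,
      if (head) v[-n, , , drop = FALSE] else v[-1, , , drop = FALSE],
      if (head) v[, -n, , drop = FALSE] else v[, -1, , drop = FALSE],
      if (head) v[, , -n, drop = FALSE] else v[, , -1, drop = FALSE])
    both <- pick(def, TRUE) & pick(def, FALSE)
    dotp <- pick(rx, TRUE) * pick(rx, FALSE) + pick(ry, TRUE) * pick(ry, FALSE) +
      pick(rz, TRUE) * pick(rz, FALSE)
    worst <- min(worst, min(dotp[both]))
  }
  expect_gt(worst, cos(60 * pi / 180))
})

test_that("equivolumetric layering is consistent on the large shell", {
  ph <- make_phantom(phantom_spec("spherical-shell", inner_radius = 12,
                                  outer_radius = 24, n_areas = 3L, seed = 3L))
  dev <- compute_depth(ph$gm_mask, ph$wm_mask, ph$grid, mode = "equivolume")
  lay <- equivolume_layers(dev, ph$gm_mask, 6L)
  vols <- tabulate(lay[lay > 0L], 6L)
  expect_lt(max(abs(vols - mean(vols))) / mean(vols), 0.05)
  # layer boundaries sit within one voxel of the analytic cube-root radii
  dims <- ph$grid$shape
  ctr <- (dims + 1) / 2
  idx <- which(ph$gm_mask & lay > 0L)
  co <- vox_coords_test(idx, dims)
  r <- sqrt(colSums((t(co) - ctr)^2))
  lv <- lay[idx]
  for (k in 1:5) {
    rk <- (12^3 + (k / 6) * (24^3 - 12^3))^(1 / 3)
    emp <- (quantile(r[lv == k], 0.99) + quantile(r[lv == k + 1], 0.01)) / 2
    expect_lt(abs(emp - rk), 1)
  }
  # equidistant layering under-fills the innermost layer on a curved shell
  deq <- compute_depth(ph$gm_mask, ph$wm_mask, ph$grid, mode = "equidistant")
  leq <- equivolume_layers(deq, ph$gm_mask, 6L)
  veq <- tabulate(leq[leq > 0L], 6L)
  expect_lt(veq[1], veq[6])
})

test_that("single-layer request covers all of gray matter", {
  ph <- make_phantom(phantom_spec(hemi_width = 5L, length = 9L, n_areas = 3L,
                                  seed = 2L))
  d <- compute_depth(ph$gm_mask, ph$wm_mask, ph$grid, mode = "equidistant")
  lay <- equivolume_layers(d, ph$gm_mask, 1L)
  expect_true(all(lay[d$defined_mask] == 1L))
  expect_error(equivolume_layers(d, ph$gm_mask, 0L), "n_layers")
})

test_that("depth increases along the radial direction", {
  ph <- make_phantom(phantom_spec("sinusoidal-ribbon", hemi_width = 8L,
                                  length = 40L, seed = 8L))
  g <- ph$grid
  d <- compute_depth(ph$gm_mask, ph$wm_mask, g, mode = "equivolume")
  fr <- compute_radial(d, ph$gm_mask)
  idx <- which(fr$defined_mask)
  dims <- g$shape
  co <- vox_coords_test(idx, dims)
  step <- 0.5
  pts <- co + step * cbind(fr$radial[, , , 1][idx], fr$radial[, , , 2][idx],
                           fr$radial[, , , 3][idx])
  filled <- d$depth_filled
  here <- trilinear_test(filled, co * 1.0, dims)
  there <- trilinear_test(filled, pts, dims)
  expect_gte(mean(there >= here - 1e-9), 0.99)
})

test_that("disjointness and reachability are enforced", {
  g <- vol_grid(c(6, 6, 6))
  m <- array(FALSE, c(6, 6, 6))
  gm <- m; gm[, 3:4, ] <- TRUE
  wm <- m; wm[, 1:3, ] <- TRUE
  expect_error(compute_depth(gm, wm, g), "disjoint")
})
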