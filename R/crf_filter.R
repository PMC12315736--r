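# Orientation-adaptive anisotropic Gaussian denoising.
#
# Each cortical voxel is replaced by a weighted sum of its support^3
# neighborhood, with Gaussian weights elongated in the plane tangent to the
# cortical surface: standard deviation sigma_radial along the local radial
# direction and sigma_tangential isotropically within the tangent plane
# (rotationally symmetric about the radial axis, so no tangent basis is
# needed). Weights are sampled at voxel-center offsets and renormalized to
# sum to one, which makes the filter exactly conservative on constant
# signals; at image borders only in-grid neighbors contribute. Voxels
# without a defined frame are passed through unchanged.

#' Filter parameters
#'
#' @param sigma_radial Gaussian standard deviation along the radial
#'   direction, mm (default 0.1).
#' @param sigma_tangential standard deviation in the tangent plane, mm
#'   (default 1.0).
#' @param support odd kernel width in voxels per axis (default 5).
#' @param mask_restrict if `TRUE`, neighbors outside the cortical mask get
#'   zero weight (with renormalization); by default out-of-cortex neighbors
#'   contribute.
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(sigma_radial = 0.1, sigma_tangential = 1.0,
                          support = 5L, mask_restrict = FALSE) {
  support <- as.integer(support)
  if (sigma_radial <= 0 || sigma_tangential <= 0) stop("sigmas must be > 0")
  if (support < 1L || support %% 2L == 0L) stop("support must be odd and >= 1")
  structure(list(sigma_radial = sigma_radial, sigma_tangential = sigma_tangential,
                 support = support, mask_restrict = isTRUE(mask_restrict)),
            class = "filter_params")
}

#' Tangential support width of the filter
#'
#' The maximum tangential blurring extent: kernel width times voxel size.
#' With the defaults (5-voxel support at 0.2 mm) this is 1 mm.
#'
#' @param params a [filter_params].
#' @param voxel_size voxel dimensions, mm.
#' @return support width in mm (per axis maximum).
#' @export
filter_support_mm <- function(params, voxel_size) {
  params$support * max(voxel_size)
}

#' Build the anisotropic Gaussian stencil for one voxel
#'
#' Weight at voxel-center offset x (mm) is proportional to
#' `exp(-0.5 * ((x.r)^2 / sr^2 + (|x|^2 - (x.r)^2) / st^2))` for radial unit
#' vector r; weights are normalized to sum to one.
#'
#' @param radial unit 3-vector (radial direction).
#' @param params a [filter_params].
#' @param voxel_size voxel dimensions, mm.
#' @return a `support^3` array of non-negative weights summing to 1.
#' @export
build_kernel <- function(radial, params, voxel_size) {
  nrm <- sqrt(sum(radial^2))
  if (!is.finite(nrm) || nrm < 1e-12) stop("radial vector must be nonzero")
  r <- radial / nrm
  half <- params$support %/% 2L
  off <- as.matrix(expand.grid(x = -half:half, y = -half:half, z = -half:half))
  xmm <- sweep(off, 2L, voxel_size, "*")
  dot <- xmm %*% r
  x2 <- rowSums(xmm^2)
  w <- exp(-0.5 * (dot^2 / params$sigma_radial^2 +
                     (x2 - dot^2) / params$sigma_tangential^2))
  array(w / sum(w), rep(params$support, 3L))
}

# precompute, for every defined-frame voxel, the per-offset weights and
# in-grid neighbor indices; shared across the volumes of a 4D stack
filter_stencils <- function(frame, params, grid, mask = NULL) {
  dims <- grid$shape
  idx <- which(frame$defined_mask)
  n <- length(idx)
  if (n == 0L) stop("no voxels with a defined cortical frame")
  r1 <- frame$radial[, , , 1][idx]
  r2 <- frame$radial[, , , 2][idx]
  r3 <- frame$radial[, , , 3][idx]
  coords <- vox_coords(idx, dims)
  half <- params$support %/% 2L
  off <- as.matrix(expand.grid(x = -half:half, y = -half:half, z = -half:half))
  sr2 <- params$sigma_radial^2
  st2 <- params$sigma_tangential^2
  restrict <- params$mask_restrict
  if (restrict && is.null(mask)) mask <- frame$defined_mask
  stencils <- vector("list", nrow(off))
  den <- numeric(n)
  for (o in seq_len(nrow(off))) {
    xmm <- off[o, ] * grid$voxel_size
    x2 <- sum(xmm^2)
    dot <- xmm[1] * r1 + xmm[2] * r2 + xmm[3] * r3
    w <- exp(-0.5 * (dot^2 / sr2 + (x2 - dot^2) / st2))
    nc1 <- coords[, 1] + off[o, 1]
    nc2 <- coords[, 2] + off[o, 2]
    nc3 <- coords[, 3] + off[o, 3]
    ok <- nc1 >= 1L & nc1 <= dims[1] & nc2 >= 1L & nc2 <= dims[2] &
      nc3 >= 1L & nc3 <= dims[3]
    ni <- (nc3[ok] - 1L) * (dims[1] * dims[2]) + (nc2[ok] - 1L) * dims[1] + nc1[ok]
    if (restrict) {
      keep <- mask[ni]
      oksub <- which(ok)[keep]
      ok <- rep(FALSE, n); ok[oksub] <- TRUE
      ni <- ni[keep]
    }
    wi <- w[ok]
    den[ok] <- den[ok] + wi
    stencils[[o]] <- list(rows = which(ok), ni = ni, w = wi)
  }
  list(idx = idx, den = den, stencils = stencils)
}

apply_stencils <- function(vol, st) {
  num <- numeric(length(st$idx))
  for (s in st$stencils) {
    num[s$rows] <- num[s$rows] + s$w * vol[s$ni]
  }
  out <- vol
  out[st$idx] <- num / st$den
  out
}

#' Apply the CRF-oriented anisotropic filter to one volume
#'
#' @param volume 3D array on the frame's grid.
#' @param frame a `cortical_frame` ([compute_radial]).
#' @param params a [filter_params].
#' @param grid a [vol_grid]; defaults to the frame's grid.
#' @param mask optional cortical mask used when `mask_restrict` is set.
#' @return filtered 3D array; voxels without a defined frame are unchanged.
#' @export
apply_crf_filter <- function(volume, frame, params = filter_params(),
                             grid = frame$grid, mask = NULL) {
  if (!all(dim(volume) == grid$shape))
    stop(sprintf("shape mismatch: volume %s vs frame %s",
                 paste(dim(volume), collapse = "x"),
                 paste(grid$shape, collapse = "x")))
  st <- filter_stencils(frame, params, grid, mask)
  apply_stencils(volume, st)
}

#' Filter every volume of a DWI set
#'
#' Applies [apply_crf_filter] to each diffusion-weighted volume independently
#' (the per-voxel stencils are shared across volumes); the gradient scheme is
#' unchanged.
#'
#' @param dwis a `dwi_set`.
#' @param frame a `cortical_frame`.
#' @param params a [filter_params].
#' @param mask optional cortical mask for `mask_restrict`.
#' @return a filtered `dwi_set`.
#' @export
filter_dwi_set <- function(dwis, frame, params = filter_params(), mask = NULL) {
  stopifnot(inherits(dwis, "dwi_set"))
  dims <- dim(dwis$data)
  if (!all(dims[1:3] == frame$grid$shape))
    stop("shape mismatch between DWI stack and cortical frame")
  if (dims[4] != length(dwis$scheme$b_values))
    stop(sprintf("volume count %d does not match scheme length %d",
                 dims[4], length(dwis$scheme$b_values)))
  st <- filter_stencils(frame, params, frame$grid, mask)
  out <- dwis$data
  for (v in seq_len(dims[4])) {
    out[, , , v] <- apply_stencils(dwis$data[, , , v], st)
  }
  cs_log("crf_filter", n_volumes = dims[4],
         sigma_radial = params$sigma_radial,
         sigma_tangential = params$sigma_tangential, support = params$support)
  structure(list(data = out, scheme = dwis$scheme, grid = dwis$grid,
                 s0 = dwis$s0), class = "dwi_set")
}

#' Per-voxel noise-variance gain of the filter
#'
#' For iid input noise the output noise variance at a voxel is the input
#' variance times the sum of squared (renormalized) stencil weights.
#'
#' @param frame a `cortical_frame`.
#' @param params a [filter_params].
#' @param grid a [vol_grid].
#' @param mask optional cortical mask for `mask_restrict`.
#' @return 3D array with sum(w^2) at defined-frame voxels (NA elsewhere).
#' @export
filter_variance_gain <- function(frame, params = filter_params(),
                                 grid = frame$grid, mask = NULL) {
  st <- filter_stencils(frame, params, grid, mask)
  sw2 <- numeric(length(st$idx))
  for (s in st$stencils) {
    sw2[s$rows] <- sw2[s$rows] + s$w^2
  }
  out <- array(NA_real_, grid$shape)
  out[st$idx] <- sw2 / st$den^2
  out
}
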