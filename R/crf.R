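# Cortical reference frame estimation from GM/WM masks.
#
# Depth is 0 at the GM/WM interface and 1 at the pial surface. The
# equidistant mode uses the ratio of Euclidean distance transforms to the two
# boundaries (voxel-size aware, with a half-voxel offset so the boundary sits
# on the voxel faces). The equivolumetric mode integrates a frustum model
# along the streamline of the radial field through each voxel: the local
# cross-sectional area of a cortical column evolves as
# dA/ds = A * div(radial), so the column volume below a voxel is the path
# integral of exp(div) and equivolume depth is the voxel's volume fraction
# within its column. On flat geometry the divergence vanishes and the two
# modes agree; on a spherical shell the construction reproduces the analytic
# cube-root layering.

edt_mm <- function(mask, grid) {
  array(edt_cpp(as.logical(mask), grid$shape, grid$voxel_size), grid$shape)
}

# separable Gaussian smoothing (sigma in voxels, truncated at 3 sigma);
# used to suppress the lattice bumpiness of voxel-center distance fields
# before differentiating them
gaussian_smooth3 <- function(vol, sigma_vox = 1) {
  if (sigma_vox <= 0) return(vol)
  rad <- max(1L, ceiling(3 * sigma_vox))
  w <- exp(-0.5 * ((-rad:rad) / sigma_vox)^2)
  w <- w / sum(w)
  d <- dim(vol)
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2L) next
    out <- array(0, d)
    den <- array(0, d)
    for (o in -rad:rad) {
      src <- pmin(pmax(seq_len(n) + o, 1L), n)
      inb <- seq_len(n) + o >= 1L & seq_len(n) + o <= n
      sl <- switch(ax, vol[src, , , drop = FALSE], vol[, src, , drop = FALSE],
                   vol[, , src, drop = FALSE])
      wv <- w[o + rad + 1L] * inb
      wa <- switch(ax,
                   array(wv, d),
                   aperm(array(wv, d[c(2, 1, 3)]), c(2, 1, 3)),
                   aperm(array(wv, d[c(3, 1, 2)]), c(2, 3, 1)))
      out <- out + sl * wa
      den <- den + wa
    }
    vol <- out / den
  }
  vol
}

# globally defined equidistant depth proxy: 0 inside WM, 1 in background,
# smooth ramp across GM (boundaries at voxel faces via half-voxel offset).
# The two distance fields are lightly smoothed: voxel-center EDT of a curved
# boundary carries lattice bumpiness of a fraction of a voxel, which would
# corrupt the gradient (radial) field.
depth_ramp <- function(gm_mask, wm_mask, grid, smooth_vox = 1) {
  h <- mean(grid$voxel_size)
  dw_raw <- edt_mm(wm_mask, grid)
  dp_raw <- edt_mm(!(gm_mask | wm_mask), grid)
  big <- max(grid$voxel_size) * max(grid$shape)
  dw_raw[!is.finite(dw_raw)] <- big
  dp_raw[!is.finite(dp_raw)] <- big
  dw_s <- gaussian_smooth3(dw_raw, smooth_vox)
  dp_s <- gaussian_smooth3(dp_raw, smooth_vox)
  dw <- pmax(dw_s - h / 2, 0)
  dp <- pmax(dp_s - h / 2, 0)
  den <- dw + dp
  bad <- !is.finite(den) | den <= 0
  den[bad] <- 1
  rho <- dw / den
  rho[bad & wm_mask] <- 0
  rho[bad & !wm_mask & !gm_mask] <- 1
  # signed through-cortex coordinate: monotone along the radial direction in
  # WM, GM and background alike (difference of two distance cones), so its
  # gradient and divergence stay well defined right up to both faces
  list(rho = rho, dw = dw, dp = dp, u = dw_s - dp_s,
       dw_face = dw_raw - h / 2, dp_face = dp_raw - h / 2,
       reachable = is.finite(dw) & is.finite(dp) & (dw + dp) > 0)
}

radial_from_depth <- function(depth_filled, grid) {
  g <- grad3(depth_filled, grid$voxel_size)
  nrm <- sqrt(g$gx^2 + g$gy^2 + g$gz^2)
  ok <- nrm >= 1e-8
  nz <- ifelse(ok, nrm, 1)
  list(rx = g$gx / nz, ry = g$gy / nz, rz = g$gz / nz, ok = ok, norm = nrm)
}

divergence_field <- function(rad, grid) {
  gx <- grad3(rad$rx, grid$voxel_size)$gx
  gy <- grad3(rad$ry, grid$voxel_size)$gy
  gz <- grad3(rad$rz, grid$voxel_size)$gz
  gx + gy + gz
}

# streamline equivolume depth for the voxels in `idx`. `rad` is the
# (smoothed-ramp) radial field and `divr` its divergence; the traces stop on
# the *unsmoothed* face-distance fields `dw_face` / `dp_face` (zero at the
# WM-facing / pial-facing boundary surfaces), accumulating the frustum
# cross-section factor exp(int div) along the way.
equivolume_from_streamlines <- function(idx, ramp, rad, divr, grid, step_vox = 0.25,
                                        max_steps = 800L) {
  dims <- grid$shape
  vox <- grid$voxel_size
  step_mm <- step_vox * mean(vox)
  n <- length(idx)
  start <- vox_coords(idx, dims)

  trace_dir <- function(sgn) {
    stopfield <- if (sgn < 0) ramp$dw_face else ramp$dp_face
    fields <- list(stopfield, rad$rx, rad$ry, rad$rz, divr)
    pos <- start * 1.0
    vol <- numeric(n)       # accumulated column volume in this direction
    area <- rep(1, n)       # cross-section factor relative to the voxel
    active <- rep(TRUE, n)
    smp <- trilinear(fields, pos, dims)
    sv_cur <- smp[, 1]      # distance to the stopping face (>= 0 inside GM)
    for (it in seq_len(max_steps)) {
      if (!any(active)) break
      a <- which(active)
      dirx <- smp[a, 2]; diry <- smp[a, 3]; dirz <- smp[a, 4]
      nrm <- sqrt(dirx^2 + diry^2 + dirz^2)
      dead <- nrm < 1e-8
      nrm[dead] <- 1
      # step in voxel coordinates so anisotropic grids stay isotropic in mm
      newpos <- pos[a, , drop = FALSE] + sgn * step_mm *
        cbind(dirx / nrm / vox[1], diry / nrm / vox[2], dirz / nrm / vox[3])
      smp_new <- trilinear(fields, newpos, dims)
      sv_new <- smp_new[, 1]
      div_new <- smp_new[, 5]
      area_new <- area[a] * exp(sgn * div_new * step_mm)
      seg <- 0.5 * (area[a] + area_new) * step_mm
      crossed <- sv_new <= 0
      # small tolerance: numerical dust in the radial components must not
      # strand border-column traces outside the grid
      eps <- 1e-6
      off_grid <- newpos[, 1] < 1 - eps | newpos[, 1] > dims[1] + eps |
        newpos[, 2] < 1 - eps | newpos[, 2] > dims[2] + eps |
        newpos[, 3] < 1 - eps | newpos[, 3] > dims[3] + eps
      newpos[, 1] <- pmin(pmax(newpos[, 1], 1), dims[1])
      newpos[, 2] <- pmin(pmax(newpos[, 2], 1), dims[2])
      newpos[, 3] <- pmin(pmax(newpos[, 3], 1), dims[3])
      stopnow <- crossed | off_grid | dead
      # partial last segment up to the face crossing
      denom <- sv_cur[a] - sv_new
      frac <- ifelse(denom > 1e-12, pmin(pmax(sv_cur[a] / denom, 0), 1), 1)
      vol[a] <- vol[a] + ifelse(stopnow & crossed, seg * frac, seg)
      pos[a, ] <- newpos
      area[a] <- area_new
      sv_cur[a] <- sv_new
      smp[a, ] <- smp_new
      active[a[stopnow]] <- FALSE
    }
    vol
  }
  v_below <- trace_dir(-1)
  v_above <- trace_dir(+1)
  tot <- v_below + v_above
  tot[tot <= 0] <- 1
  pmin(pmax(v_below / tot, 0), 1)
}

#' Cortical depth from GM and WM masks
#'
#' @param gm_mask,wm_mask logical 3D arrays (disjoint); GM must form a ribbon
#'   with both a WM-facing and an outer (pial) boundary.
#' @param grid a [vol_grid].
#' @param mode `"equivolume"` (depth = local columnar volume fraction,
#'   curvature-corrected) or `"equidistant"`
#'   (`d_wm / (d_wm + d_pial)` from Euclidean distance transforms).
#' @return an object of class `cortical_depth`: `depth` (3D array, NA outside
#'   the defined mask), `depth_filled` (globally defined ramp used for
#'   gradients: 0 in WM, 1 in background), `defined_mask`, `mode`, `grid`.
#' @export
compute_depth <- function(gm_mask, wm_mask, grid, mode = c("equivolume", "equidistant")) {
  mode <- match.arg(mode)
  gm_mask <- as.array(gm_mask) > 0
  wm_mask <- as.array(wm_mask) > 0
  if (any(gm_mask & wm_mask)) stop("gm_mask and wm_mask must be disjoint")
  ramp <- depth_ramp(gm_mask, wm_mask, grid)
  defined <- gm_mask & ramp$reachable
  n_excl <- sum(gm_mask) - sum(defined)
  if (n_excl > 0) cs_log("compute_depth", unreachable_excluded = n_excl)

  if (mode == "equidistant") {
    dvals <- ramp$rho[defined]
  } else {
    rad <- radial_from_depth(ramp$u, grid)
    divr <- divergence_field(rad, grid)
    # keep the divergence sane where the ramp is degenerate
    divr[!is.finite(divr)] <- 0
    lim <- 4 / min(grid$voxel_size)
    divr <- pmin(pmax(divr, -lim), lim)
    dvals <- equivolume_from_streamlines(which(defined), ramp, rad, divr, grid)
  }
  depth <- array(NA_real_, grid$shape)
  depth[defined] <- dvals
  # the filled volume feeds gradient (radial) estimation: keep the smooth
  # equidistant ramp there, since equivolume reparameterizes depth along each
  # column without changing the iso-depth surface orientations
  filled <- ramp$rho
  structure(list(depth = depth, depth_filled = filled, grad_field = ramp$u,
                 defined_mask = defined, mode = mode, grid = grid),
            class = "cortical_depth")
}

#' Radial orientation field from a depth volume
#'
#' The radial unit vector (pointing from white matter toward the pial
#' surface) is the normalized, voxel-size-aware central-difference gradient
#' of depth. Voxels with gradient norm below 1e-8 are excluded.
#'
#' @param depth a `cortical_depth` object, or a 3D depth array defined on (at
#'   least) the gray matter.
#' @param gm_mask logical 3D array of cortical voxels.
#' @param grid a [vol_grid] (taken from `depth` when it is a
#'   `cortical_depth`).
#' @return an object of class `cortical_frame`: `radial` (4D array, 3
#'   volumes), `depth`, `defined_mask`, `grid`.
#' @export
compute_radial <- function(depth, gm_mask, grid = NULL) {
  if (inherits(depth, "cortical_depth")) {
    grid <- depth$grid
    filled <- depth$grad_field %||% depth$depth_filled
    base_def <- depth$defined_mask
    dvol <- depth$depth
  } else {
    if (is.null(grid)) stop("grid required when depth is a plain array")
    filled <- depth
    filled[is.na(filled)] <- 0
    base_def <- gm_mask & !is.na(depth)
    dvol <- depth
  }
  gm_mask <- as.array(gm_mask) > 0
  rad <- radial_from_depth(filled, grid)
  defined <- base_def & gm_mask & rad$ok
  dropped <- sum(base_def & gm_mask) - sum(defined)
  if (dropped > 0) cs_log("compute_radial", zero_gradient_excluded = dropped)
  radial <- array(NA_real_, c(grid$shape, 3L))
  for (c3 in 1:3) {
    comp <- list(rad$rx, rad$ry, rad$rz)[[c3]]
    comp[!defined] <- NA_real_
    radial[, , , c3] <- comp
  }
  structure(list(radial = radial, depth = dvol, defined_mask = defined,
                 grid = grid), class = "cortical_frame")
}

#' Full cortical reference frame (depth + radial field)
#'
#' @inheritParams compute_depth
#' @return a `cortical_frame` with equivolume (or requested-mode) depth.
#' @export
cortical_frame <- function(gm_mask, wm_mask, grid, mode = c("equivolume", "equidistant")) {
  d <- compute_depth(gm_mask, wm_mask, grid, mode = mode)
  compute_radial(d, gm_mask)
}

#' Equivolumetric layer labels from a depth volume
#'
#' Layer k collects voxels with depth in `[(k-1)/n, k/n)`; depth exactly 1 is
#' assigned to layer n. With equivolume-mode depth the layers enclose equal
#' tissue volumes up to discretization.
#'
#' @param depth a `cortical_depth` or a 3D depth array.
#' @param gm_mask logical 3D array.
#' @param n_layers number of layers (>= 1).
#' @return integer 3D array with labels 1..n_layers (0 outside).
#' @export
equivolume_layers <- function(depth, gm_mask, n_layers = 6L) {
  if (n_layers < 1L) stop("n_layers must be >= 1")
  dvol <- if (inherits(depth, "cortical_depth")) depth$depth else depth
  gm_mask <- as.array(gm_mask) > 0
  sel <- gm_mask & !is.na(dvol)
  lab <- array(0L, dim(dvol))
  k <- pmin(floor(dvol[sel] * n_layers) + 1L, n_layers)
  lab[sel] <- as.integer(k)
  lab
}
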