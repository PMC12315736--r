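# Synthetic two-hemisphere cortical ribbon phantoms.
#
# The phantom stands in for a real high-resolution ex vivo dataset: a folded
# or flat cortical gray-matter ribbon over white matter, partitioned into
# areas (tangentially) and laminar classes (by depth), mirrored into two
# hemispheres whose class labels are renamed by a known permutation. Each
# class carries a diffusion-tensor signature (prolate/radial or
# oblate/tangential) plus a non-Gaussianity level, from which scalar
# parameter maps and diffusion-weighted signals are generated.

#' Phantom specification
#'
#' @param geometry `"slab"`, `"spherical-shell"` or `"sinusoidal-ribbon"`.
#' @param hemi_width tangential width of each hemisphere in voxels
#'   (slab/sinusoid).
#' @param gm_thickness cortical thickness in voxels.
#' @param wm_thickness white-matter slab thickness in voxels.
#' @param pad background padding above the pial surface in voxels.
#' @param length tangential extent along the third axis in voxels.
#' @param gap width in voxels of the midsagittal strip assigned to neither
#'   hemisphere (slab/sinusoid). Tissue is continuous across the midline (a
#'   lateral tissue gap would tilt the cortical frame), but the strip carries
#'   no hemisphere id or class label, so no labeled component can span
#'   hemispheres.
#' @param inner_radius,outer_radius shell radii in voxels (spherical-shell):
#'   white matter fills radii up to `inner_radius`, gray matter the shell
#'   between `inner_radius` (exclusive) and `outer_radius` (inclusive).
#' @param sine_amplitude,sine_period fold amplitude/period in voxels
#'   (sinusoidal-ribbon).
#' @param n_areas cortical areas per hemisphere (tangential partition).
#' @param n_layer_classes laminar classes per area (depth partition).
#' @param share_slots optional named integer vector mapping slot indices
#'   (`(area-1)*n_layer_classes + layer`) onto earlier slots so that two
#'   spatially disjoint blocks share one class. By default the 5 x 3 layout
#'   shares its last slot with slot 3, giving 14 distinct classes.
#' @param class_table optional data.frame overriding the built-in per-slot
#'   tensor signatures; must have columns `slot`, `lambda1`, `lambda2`,
#'   `lambda3` (mm^2/s), `orientation` (`"radial"`/`"tangential"`), `ng`.
#' @param class_separation minimum pairwise Mahalanobis distance between class
#'   signatures in the clustering feature space (PA, NG, RTAP, RTPP), measured
#'   against the total within-class standard deviation. Feature noise is
#'   scaled to achieve exactly this separation.
#' @param lambda_jitter coefficient of variation of the per-voxel tensor
#'   eigenvalue jitter (biological within-class variability). The jitter
#'   enters only the tensor field, hence the simulated-DWI route; the
#'   calibrated `noisy_params` maps are class-mean signature plus Gaussian
#'   noise, keeping the direct clustering route exactly mixture-distributed.
#' @param ng_sd per-voxel standard deviation of the non-Gaussianity map.
#' @param snr Rician signal-to-noise ratio at b ~ 0 for simulated DWIs
#'   (`Inf` disables noise).
#' @param s0 non-weighted signal level.
#' @param voxel_size isotropic voxel dimension in mm.
#' @param seed integer seed; the phantom is deterministic given the seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(geometry = c("slab", "spherical-shell", "sinusoidal-ribbon"),
                         hemi_width = 30L, gm_thickness = 12L, wm_thickness = 6L,
                         pad = 6L, length = 150L, gap = 3L,
                         inner_radius = 8, outer_radius = 12,
                         sine_amplitude = 3, sine_period = 40,
                         n_areas = 5L, n_layer_classes = 3L,
                         share_slots = NULL, class_table = NULL,
                         class_separation = 4, lambda_jitter = 0.06,
                         ng_sd = 0.005, snr = 30, s0 = 1,
                         voxel_size = 0.2, seed = 7L) {
  geometry <- match.arg(geometry)
  if (n_areas < 1L || n_layer_classes < 1L) stop("n_areas and n_layer_classes must be >= 1")
  if (class_separation <= 0) stop("class_separation must be > 0")
  if (snr <= 0) stop("snr must be > 0")
  thickness <- if (geometry == "spherical-shell") outer_radius - inner_radius else gm_thickness
  if (thickness / n_layer_classes < 1)
    stop("geometry too thin: needs at least one voxel per laminar class")
  n_slots <- n_areas * n_layer_classes
  if (is.null(share_slots)) {
    share_slots <- if (n_slots == 15L) c("15" = 3L) else integer(0)
  }
  structure(list(geometry = geometry, hemi_width = as.integer(hemi_width),
                 gm_thickness = as.integer(gm_thickness),
                 wm_thickness = as.integer(wm_thickness), pad = as.integer(pad),
                 length = as.integer(length), gap = as.integer(gap),
                 inner_radius = inner_radius, outer_radius = outer_radius,
                 sine_amplitude = sine_amplitude, sine_period = sine_period,
                 n_areas = as.integer(n_areas),
                 n_layer_classes = as.integer(n_layer_classes),
                 share_slots = share_slots, class_table = class_table,
                 class_separation = class_separation,
                 lambda_jitter = lambda_jitter, ng_sd = ng_sd,
                 snr = snr, s0 = s0, voxel_size = voxel_size,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# built-in per-slot tensor signatures: deep (layer 1) and deepest third
# strongly radial/prolate, middle third tangential/oblate, modulated by area
# so every slot is distinct in (PA, NG, RTAP, RTPP). Diffusivities are at
# fixed-tissue scale (perfusion fixation reduces diffusivity ~2.5x relative
# to in vivo), consistent with an ex vivo acquisition that pushes b to
# 10,000 s/mm^2: at in vivo diffusivities the upper shells of such a scheme
# would sit below the Rician noise floor.
default_class_table <- function(n_areas, n_layer_classes) {
  slots <- expand.grid(layer = seq_len(n_layer_classes), area = seq_len(n_areas))
  slots <- slots[, c("area", "layer")]
  n <- nrow(slots)
  tab <- data.frame(slot = seq_len(n), area = slots$area, layer = slots$layer)
  a <- tab$area; l <- tab$layer
  tangential <- (l %% 2L) == 0L     # even layers oblate/tangential
  sc <- 0.4e-3                      # fixed-tissue diffusivity scale
  l1 <- (0.70 + 0.12 * a + 0.30 * (l == 1) + 0.08 * (l == 3) + 0.05 * (l > 3)) * sc
  lt <- (0.32 + 0.040 * a + 0.020 * l) * sc
  tab$lambda1 <- ifelse(tangential, (0.78 + 0.05 * a) * sc, l1)
  tab$lambda2 <- ifelse(tangential, tab$lambda1, lt)
  tab$lambda3 <- ifelse(tangential, (0.38 + 0.03 * a) * sc, lt)
  tab$orientation <- ifelse(tangential, "tangential", "radial")
  tab$ng <- 0.10 + 0.06 * l + 0.018 * a
  tab
}

# map slots to class ids after sharing, renumbered consecutively from 1
slot_class_map <- function(n_slots, share_slots) {
  cls <- seq_len(n_slots)
  if (length(share_slots)) {
    idx <- as.integer(names(share_slots))
    cls[idx] <- cls[as.integer(share_slots)]
  }
  match(cls, sort(unique(cls)))
}

# analytic radial (WM -> pial) unit field for a geometry, as three 3D arrays
analytic_radial <- function(spec, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  rx <- array(0, dims); ry <- array(0, dims); rz <- array(0, dims)
  if (spec$geometry == "slab") {
    ry[] <- 1
  } else if (spec$geometry == "sinusoidal-ribbon") {
    zc <- aperm(array(seq_len(nz), c(nz, nx, ny)), c(2, 3, 1))
    slope <- spec$sine_amplitude * 2 * pi / spec$sine_period * cos(2 * pi * zc / spec$sine_period)
    nrm <- sqrt(1 + slope^2)
    ry <- 1 / nrm
    rz <- -slope / nrm
  } else {
    ctr <- (dims + 1) / 2
    xc <- array(seq_len(nx), dims) - ctr[1]
    yc <- aperm(array(seq_len(ny), c(ny, nx, nz)), c(2, 1, 3)) - ctr[2]
    zc <- aperm(array(seq_len(nz), c(nz, nx, ny)), c(2, 3, 1)) - ctr[3]
    r <- sqrt(xc^2 + yc^2 + zc^2)
    r[r < 1e-9] <- 1e-9
    rx <- xc / r; ry <- yc / r; rz <- zc / r
  }
  list(rx = rx, ry = ry, rz = rz)
}

phantom_geometry <- function(spec) {
  g <- spec$geometry
  if (g %in% c("slab", "sinusoidal-ribbon")) {
    amp <- if (g == "sinusoidal-ribbon") ceiling(spec$sine_amplitude) else 0
    nx <- 2L * spec$hemi_width + spec$gap
    ny <- spec$wm_thickness + spec$gm_thickness + spec$pad + 2L * amp
    nz <- spec$length
    dims <- c(nx, ny, nz)
    xi <- array(seq_len(nx), dims)
    yi <- aperm(array(seq_len(ny), c(ny, nx, nz)), c(2, 1, 3))
    zi <- aperm(array(seq_len(nz), c(nz, nx, ny)), c(2, 3, 1))
    offset <- if (g == "sinusoidal-ribbon")
      round(spec$sine_amplitude * sin(2 * pi * zi / spec$sine_period)) + amp
    else array(0L, dims)
    # tissue is continuous across the midline (no lateral background, which
    # would tilt the radial field); the hemisphere gap lives in the label
    # domain: a `gap`-voxel strip with hemisphere id 0 that belongs to
    # neither hemisphere, so no processed component can span hemispheres
    wm_top <- spec$wm_thickness + offset
    wm <- yi <= wm_top
    gm <- yi > wm_top & yi <= wm_top + spec$gm_thickness
    hemi <- array(0L, dims)
    hemi[xi <= spec$hemi_width] <- 1L
    hemi[xi > spec$hemi_width + spec$gap] <- 2L
    # depth index within GM (1..thickness) and tangential (area) coordinate
    depth_idx <- array(NA_integer_, dims)
    depth_idx[gm] <- (yi - wm_top)[gm]
    area_coord <- zi
    area_extent <- spec$length
  } else {
    side <- 2L * ceiling(spec$outer_radius + 3)
    dims <- rep(side, 3L)
    ctr <- (dims + 1) / 2
    xi <- array(seq_len(side), dims)
    yi <- aperm(array(seq_len(side), c(side, side, side)), c(2, 1, 3))
    zi <- aperm(array(seq_len(side), c(side, side, side)), c(2, 3, 1))
    r <- sqrt((xi - ctr[1])^2 + (yi - ctr[2])^2 + (zi - ctr[3])^2)
    wm <- r <= spec$inner_radius
    gm <- r > spec$inner_radius & r <= spec$outer_radius
    hemi <- array(0L, dims)
    hemi[xi < ctr[1]] <- 1L
    hemi[xi > ctr[1]] <- 2L
    thick <- spec$outer_radius - spec$inner_radius
    depth_idx <- array(NA_real_, dims)
    depth_idx[gm] <- pmin(pmax(ceiling((r - spec$inner_radius)[gm] / thick *
                                         spec$n_layer_classes), 1), spec$n_layer_classes)
    # areas as polar-angle bands about +z
    ang <- acos(pmin(pmax((zi - ctr[3]) / pmax(r, 1e-9), -1), 1))
    area_coord <- ang / pi
    area_extent <- 1
  }
  list(dims = dims, gm = gm, wm = wm, hemi = hemi,
       depth_idx = depth_idx, area_coord = area_coord, area_extent = area_extent)
}

#' Generate a phantom with known ground truth
#'
#' Builds the tissue masks, area and laminar-class label volumes (mirrored
#' across the midsagittal plane with the right-hemisphere class labels renamed
#' by a random permutation), the per-voxel diffusion tensor field, the
#' noise-free scalar parameter maps derived from it, and noisy parameter maps
#' whose added feature noise is scaled so that the minimum pairwise class
#' separation in (PA, NG, RTAP, RTPP) equals `spec$class_separation`
#' Mahalanobis units.
#'
#' @param spec a [phantom_spec].
#' @return an object of class `phantom_truth`: list with `grid`, `gm_mask`,
#'   `wm_mask`, `hemisphere`, `area_labels`, `layer_class_labels` (left ids
#'   1..K, right ids permuted), `permutation`, `tensors` (list of six
#'   component arrays), `eigenvalues` (3-column matrix over `tissue_idx`),
#'   `true_params`, `noisy_params` (named lists of 3D arrays), `class_table`,
#'   `feature_sd`, `radial` (analytic unit field) and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geo <- phantom_geometry(spec)
  dims <- geo$dims
  grid <- vol_grid(dims, rep(spec$voxel_size, 3))
  n_slots <- spec$n_areas * spec$n_layer_classes
  cmap <- slot_class_map(n_slots, spec$share_slots)
  ctab <- if (is.null(spec$class_table))
    default_class_table(spec$n_areas, spec$n_layer_classes) else spec$class_table
  ctab$class <- cmap[ctab$slot]
  # slots sharing a class share its diffusion signature
  if (length(spec$share_slots)) {
    sig_cols <- c("lambda1", "lambda2", "lambda3", "orientation", "ng")
    ctab[as.integer(names(spec$share_slots)), sig_cols] <-
      ctab[as.integer(spec$share_slots), sig_cols]
  }
  n_classes <- max(cmap)

  # tangential area partition and per-voxel slot/class (left-hemisphere ids)
  area_idx <- array(NA_integer_, dims)
  sel <- geo$gm
  area_idx[sel] <- pmin(pmax(ceiling(geo$area_coord[sel] / geo$area_extent *
                                       spec$n_areas), 1L), spec$n_areas)
  layer_idx <- array(NA_integer_, dims)
  if (spec$geometry == "spherical-shell") {
    layer_idx[sel] <- as.integer(geo$depth_idx[sel])
  } else {
    layer_idx[sel] <- pmin(pmax(ceiling(geo$depth_idx[sel] / spec$gm_thickness *
                                          spec$n_layer_classes), 1L), spec$n_layer_classes)
  }
  slot_idx <- array(NA_integer_, dims)
  slot_idx[sel] <- (area_idx[sel] - 1L) * spec$n_layer_classes + layer_idx[sel]

  # enforce exact mirror symmetry: right hemisphere copies the mirrored left
  mir <- rev(seq_len(dims[1]))
  mirror1 <- function(v) v[mir, , , drop = FALSE]
  right <- geo$hemi == 2L
  for (nm in c("area_idx", "slot_idx", "layer_idx")) {
    v <- get(nm); vm <- mirror1(v); v[right] <- vm[right]; assign(nm, v)
  }
  gm <- geo$gm; gm[right] <- mirror1(geo$gm)[right]
  wm <- geo$wm; wm[right] <- mirror1(geo$wm)[right]
  gm[is.na(slot_idx) & gm] <- FALSE

  truth <- with_seed(spec$seed, {
    permutation <- sample(n_classes)
    class_left <- array(0L, dims)
    class_left[gm] <- cmap[slot_idx[gm]]
    class_left[geo$hemi == 0L] <- 0L      # midline strip: no hemisphere
    class_vol <- class_left
    class_vol[right & gm] <- permutation[class_vol[right & gm]]
    area_vol <- array(0L, dims)
    area_vol[gm] <- area_idx[gm]
    area_vol[geo$hemi == 0L] <- 0L

    # per-voxel tensors: class eigen-signature + analytic orientation + jitter
    rad <- analytic_radial(spec, dims)
    tissue <- gm | wm
    tidx <- which(tissue)
    nt <- length(tidx)
    slot_v <- slot_idx[tidx]
    wm_v <- is.na(slot_v)
    # WM signature: strongly prolate, radially oriented (fixed-tissue scale)
    l1c <- ifelse(wm_v, 0.64e-3, ctab$lambda1[slot_v])
    l2c <- ifelse(wm_v, 0.12e-3, ctab$lambda2[slot_v])
    l3c <- ifelse(wm_v, 0.12e-3, ctab$lambda3[slot_v])
    tang <- !wm_v & ctab$orientation[ifelse(wm_v, 1L, slot_v)] == "tangential"
    f <- exp(rnorm(nt, 0, spec$lambda_jitter))   # overall scale jitter
    gax <- exp(rnorm(nt, 0, spec$lambda_jitter)) # axial-shape jitter
    # axially symmetric tensor about the radial direction r:
    #   radial classes  D = lt*I + (la - lt) r r^T (prolate, la = l1 > lt)
    #   tangential ones D = lt*I + (la - lt) r r^T (oblate,  la = l3 < lt = l1)
    la <- ifelse(tang, l3c * gax, l1c * gax) * f
    lt_ <- ifelse(tang, l1c, l2c) * f
    rxv <- rad$rx[tidx]; ryv <- rad$ry[tidx]; rzv <- rad$rz[tidx]
    dl <- la - lt_
    tensors <- list(
      xx = lt_ + dl * rxv * rxv, yy = lt_ + dl * ryv * ryv,
      zz = lt_ + dl * rzv * rzv, xy = dl * rxv * ryv,
      xz = dl * rxv * rzv, yz = dl * ryv * rzv)
    eigs <- cbind(pmax(la, lt_), lt_, pmin(la, lt_)) # sorted: axial vs doubled tangential
    colnames(eigs) <- c("l1", "l2", "l3")

    tau_s <- study_scheme()$tau_s
    gm_in_t <- !wm_v
    pm <- param_maps_from_eigs(eigs[gm_in_t, 1], eigs[gm_in_t, 2], eigs[gm_in_t, 3], tau_s)
    gm_idx <- tidx[gm_in_t]
    true_params <- lapply(pm, function(v) {
      a <- array(NA_real_, dims); a[gm_idx] <- v; a
    })
    ngv <- pmin(pmax(ctab$ng[slot_v[gm_in_t]] + rnorm(sum(gm_in_t), 0, spec$ng_sd), 0), 1)
    ng_map <- array(NA_real_, dims); ng_map[gm_idx] <- ngv
    true_params$NG <- ng_map

    # class mean signatures (noise-free closed forms) and separation scaling
    cl_eigs <- ctab[!duplicated(ctab$class), ]
    cl_eigs <- cl_eigs[order(cl_eigs$class), ]
    sig <- param_maps_from_eigs(cl_eigs$lambda1,
                                ifelse(cl_eigs$orientation == "tangential",
                                       cl_eigs$lambda1, cl_eigs$lambda2),
                                ifelse(cl_eigs$orientation == "tangential",
                                       cl_eigs$lambda3, cl_eigs$lambda3), tau_s)
    sig$NG <- cl_eigs$ng
    feat <- c("PA", "NG", "RTAP", "RTPP")
    mu <- sapply(feat, function(f) sig[[f]])          # n_classes x 4
    base_sd <- apply(mu, 2, sd)
    base_sd[base_sd < 1e-12] <- 1e-12
    # the calibrated noisy maps are class-mean signature + Gaussian noise
    # (exactly the mixture model the clustering assumes); the per-voxel
    # tensor jitter only enters the DWI simulation route
    cls_v <- cmap[slot_v[gm_in_t]]
    sep_at <- function(alpha) {
      dd <- as.matrix(stats::dist(sweep(mu, 2, alpha * base_sd, "/")))
      min(dd[upper.tri(dd)])
    }
    # Mahalanobis distance scales as 1/alpha, so one evaluation suffices
    alpha <- if (n_classes > 1) sep_at(1) / spec$class_separation else 1
    feature_sd <- setNames(alpha * base_sd, feat)

    noisy_params <- true_params
    all_sig <- param_maps_from_eigs(ctab$lambda1, ctab$lambda2, ctab$lambda3, tau_s)
    all_sig$NG <- ctab$ng
    for (nm in names(true_params)) {
      mean_v <- all_sig[[nm]][slot_v[gm_in_t]]
      s_add <- if (nm %in% feat) feature_sd[[nm]] else {
        alpha * max(sd(tapply(true_params[[nm]][gm_idx], cls_v, mean)), 1e-12)
      }
      noisy_params[[nm]][gm_idx] <- mean_v + rnorm(length(gm_idx), 0, s_add)
    }

    list(grid = grid, gm_mask = gm, wm_mask = wm, hemisphere = geo$hemi,
         area_labels = area_vol, layer_class_labels = class_vol,
         layer_class_left = class_left, permutation = permutation,
         tensors = tensors, tissue_idx = tidx, eigenvalues = eigs,
         radial = rad, true_params = true_params, noisy_params = noisy_params,
         class_table = ctab, n_classes = n_classes,
         feature_sd = feature_sd, spec = spec)
  })
  cs_log("phantom", geometry = spec$geometry, n_classes = truth$n_classes,
         gm_voxels = sum(truth$gm_mask), seed = spec$seed)
  structure(truth, class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %s, %d GM voxels, %d classes/hemisphere, seed %d\n",
              x$spec$geometry, sum(x$gm_mask), x$n_classes, x$spec$seed))
  invisible(x)
}

#' Simulate diffusion-weighted volumes from a phantom
#'
#' Monoexponential tensor forward model `S = s0 * exp(-b g' D g)` on tissue
#' voxels, with Rician noise: the magnitude of `(S + n1, n2)` where `n1`, `n2`
#' are zero-mean Gaussians with standard deviation `s0 / snr`.
#'
#' @param truth a [make_phantom] result.
#' @param scheme a [gradient_scheme]; defaults to [study_scheme].
#' @param snr Rician SNR at b ~ 0 (`Inf` for noise-free); defaults to the
#'   phantom spec value.
#' @param seed integer seed for the noise draw.
#' @return an object of class `dwi_set`: list with `data` (4D array),
#'   `scheme`, `grid`, `s0`.
#' @export
simulate_dwis <- function(truth, scheme = study_scheme(), snr = truth$spec$snr,
                          seed = truth$spec$seed + 1L) {
  stopifnot(inherits(truth, "phantom_truth"))
  dims <- truth$grid$shape
  nvol <- length(scheme$b_values)
  tidx <- truth$tissue_idx
  tn <- truth$tensors
  s0 <- truth$spec$s0
  dat <- array(0, c(dims, nvol))
  nxyz <- prod(dims)
  sig_mat <- matrix(0, length(tidx), nvol)
  for (v in seq_len(nvol)) {
    g <- scheme$directions[v, ]
    b <- scheme$b_values[v]
    q <- tn$xx * g[1]^2 + tn$yy * g[2]^2 + tn$zz * g[3]^2 +
      2 * (tn$xy * g[1] * g[2] + tn$xz * g[1] * g[3] + tn$yz * g[2] * g[3])
    sig_mat[, v] <- s0 * exp(-b * q)
  }
  if (is.finite(snr)) {
    sigma <- s0 / snr
    with_seed(seed, {
      for (v in seq_len(nvol)) {
        vol <- array(0, dims)
        vol[tidx] <- sig_mat[, v]
        n1 <- array(rnorm(nxyz, 0, sigma), dims)
        n2 <- array(rnorm(nxyz, 0, sigma), dims)
        dat[, , , v] <- sqrt((vol + n1)^2 + n2^2)
      }
    })
  } else {
    for (v in seq_len(nvol)) {
      vol <- array(0, dims)
      vol[tidx] <- sig_mat[, v]
      dat[, , , v] <- vol
    }
  }
  structure(list(data = dat, scheme = scheme, grid = truth$grid, s0 = s0),
            class = "dwi_set")
}

#' Write phantom truth volumes and manifest
#'
#' @param truth a [make_phantom] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_phantom <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- truth$grid
  write_volume(truth$gm_mask + 0L, g, file.path(dir, "gm_mask.nii.gz"))
  write_volume(truth$wm_mask + 0L, g, file.path(dir, "wm_mask.nii.gz"))
  write_volume(truth$hemisphere, g, file.path(dir, "hemisphere.nii.gz"))
  write_volume(truth$area_labels, g, file.path(dir, "area_labels.nii.gz"))
  write_volume(truth$layer_class_labels, g, file.path(dir, "layer_class_labels.nii.gz"))
  for (nm in names(truth$noisy_params)) {
    v <- truth$noisy_params[[nm]]
    v[is.na(v)] <- 0
    write_volume(v, g, file.path(dir, paste0(nm, ".nii.gz")))
  }
  man <- truth$class_table
  man$permuted_to <- truth$permutation[man$class]
  write.table(man, file.path(dir, "class_manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
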