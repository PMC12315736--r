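# Scalar microstructural parameter maps.
#
# DTI scalars (FA, MD, AD, RD) come from a log-linear weighted least-squares
# tensor fit. The zero-displacement probabilities (RTOP, RTAP, RTPP) and the
# propagator anisotropy (PA) are computed in the Gaussian (tensor) limit of
# the diffusion propagator, where they have closed forms in the tensor
# eigenvalues and the diffusion time tau = Delta - delta/3. Non-Gaussianity
# is identically zero in this limit and is therefore never computed from
# DWIs; it enters the pipeline only as a supplied or simulated map.

# closed-form eigenvalues of symmetric 3x3 tensors, vectorized (Cardano);
# rows of D6 are (xx, yy, zz, xy, xz, yz)
eig3sym_vals <- function(D6) {
  xx <- D6[, 1]; yy <- D6[, 2]; zz <- D6[, 3]
  xy <- D6[, 4]; xz <- D6[, 5]; yz <- D6[, 6]
  q <- (xx + yy + zz) / 3
  p1 <- xy^2 + xz^2 + yz^2
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  iso <- p < .Machine$double.eps * pmax(abs(q), 1)
  ps <- ifelse(iso, 1, p)
  bxx <- (xx - q) / ps; byy <- (yy - q) / ps; bzz <- (zz - q) / ps
  bxy <- xy / ps; bxz <- xz / ps; byz <- yz / ps
  detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  out <- cbind(l1, l2, l3)
  out[iso, ] <- q[iso]
  out
}

# shared closed forms: scalar maps from sorted eigenvalues (mm^2/s) at
# diffusion time tau (s). Used both by the fitted-tensor path and by the
# phantom generator so the two agree by construction.
param_maps_from_eigs <- function(l1, l2, l3, tau) {
  md <- (l1 + l2 + l3) / 3
  num <- (l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2
  den <- l1^2 + l2^2 + l3^2
  fa <- sqrt(1.5) * sqrt(num / pmax(den, .Machine$double.xmin))
  rtpp <- (4 * pi * tau * l1)^(-1 / 2)
  rtap <- (4 * pi * tau)^(-1) * (l2 * l3)^(-1 / 2)
  rtop <- (4 * pi * tau)^(-3 / 2) * (l1 * l2 * l3)^(-1 / 2)
  detD <- l1 * l2 * l3
  cross <- (l1 + md) * (l2 + md) * (l3 + md)
  cos2 <- 8 * sqrt(detD * md^3) / pmax(cross, .Machine$double.xmin)
  pa <- sqrt(pmin(pmax(1 - cos2, 0), 1))
  list(FA = pmin(fa, 1), MD = md, AD = l1, RD = (l2 + l3) / 2,
       PA = pa, RTAP = rtap, RTPP = rtpp, RTOP = rtop)
}

dti_design_matrix <- function(scheme) {
  g <- scheme$directions
  b <- scheme$b_values
  cbind(1,
        -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Fit diffusion tensors by log-linear weighted least squares
#'
#' Solves `ln S = ln S0 - b g' D g` per voxel: an ordinary least-squares pass
#' followed by one reweighting pass with weights equal to the squared
#' predicted signal (the standard WLS correction for log-transformed Rician
#' data). Voxels with all-zero signal are excluded from the fit mask.
#' Eigenvalues are clamped to at least `1e-7` mm^2/s.
#'
#' @param dwis a `dwi_set` (4D data + [gradient_scheme]).
#' @param mask optional logical 3D array restricting the fit.
#' @return an object of class `tensor_field`: `idx` (linear voxel indices),
#'   `D` (n x 6 matrix, columns xx,yy,zz,xy,xz,yz), `s0`, `eigenvalues`
#'   (n x 3, sorted decreasing, clamped), `fit_mask`, `grid`.
#' @export
fit_dti <- function(dwis, mask = NULL) {
  stopifnot(inherits(dwis, "dwi_set"))
  scheme <- dwis$scheme
  X <- dti_design_matrix(scheme)
  if (nrow(X) < 7L || qr(X)$rank < 7L)
    stop("insufficient directions: need >= 7 volumes spanning >= 6 non-coplanar directions")
  dims <- dim(dwis$data)[1:3]
  nvol <- dim(dwis$data)[4]
  if (is.null(mask)) mask <- array(TRUE, dims)
  idx <- which(mask)
  S <- matrix(dwis$data[outer(idx, (seq_len(nvol) - 1L) * prod(dims), "+")],
              nrow = length(idx))
  nonzero <- rowSums(S > 0) == nvol
  if (!all(nonzero)) {
    cs_log("fit_dti", excluded_all_zero = sum(!nonzero))
    idx <- idx[nonzero]
    S <- S[nonzero, , drop = FALSE]
  }
  eps <- .Machine$double.xmin
  Y <- log(pmax(S, eps))                       # n x nvol
  XtX <- crossprod(X)
  B <- t(solve(XtX, t(X) %*% t(Y)))            # n x 7, OLS pass
  # one reweighting pass, weights = squared predicted signal
  W <- exp(2 * (B %*% t(X)))                   # n x nvol
  pairs <- which(upper.tri(matrix(0, 7, 7), diag = TRUE), arr.ind = TRUE)
  P <- X[, pairs[, 1]] * X[, pairs[, 2]]       # nvol x 28
  A <- W %*% P                                 # n x 28 packed X'WX
  R <- (W * Y) %*% X                           # n x 7  X'Wy
  n <- nrow(Y)
  Bw <- matrix(0, n, 7)
  M <- matrix(0, 7, 7)
  lower <- pairs[, c(2, 1)]
  for (v in seq_len(n)) {
    M[pairs] <- A[v, ]
    M[lower] <- A[v, ]
    Bw[v, ] <- tryCatch(solve(M, R[v, ]), error = function(e) B[v, ])
  }
  D <- Bw[, 2:7, drop = FALSE]
  colnames(D) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  eig <- eig3sym_vals(D)
  eig <- pmax(eig, 1e-7)
  eig <- t(apply(eig, 1L, sort, decreasing = TRUE))
  fit_mask <- array(FALSE, dims)
  fit_mask[idx] <- TRUE
  structure(list(idx = idx, D = D, s0 = exp(Bw[, 1]), eigenvalues = eig,
                 fit_mask = fit_mask, grid = dwis$grid, tau_s = scheme$tau_s),
            class = "tensor_field")
}

#' Tensor field from known per-voxel tensors
#'
#' Convenience constructor used when tensors come from a phantom or an
#' external fit rather than [fit_dti].
#'
#' @param D n x 6 matrix (xx,yy,zz,xy,xz,yz) in mm^2/s.
#' @param idx linear voxel indices of the rows.
#' @param grid a [vol_grid].
#' @param s0 optional per-voxel non-weighted signal (default 1).
#' @param tau_s diffusion time in seconds.
#' @return a `tensor_field`.
#' @export
tensor_field <- function(D, idx, grid, s0 = rep(1, nrow(D)), tau_s = 0.026) {
  eig <- pmax(eig3sym_vals(D), 1e-7)
  eig <- t(apply(eig, 1L, sort, decreasing = TRUE))
  fit_mask <- array(FALSE, grid$shape)
  fit_mask[idx] <- TRUE
  structure(list(idx = idx, D = D, s0 = s0, eigenvalues = eig,
                 fit_mask = fit_mask, grid = grid, tau_s = tau_s),
            class = "tensor_field")
}

scatter_maps <- function(values, tf) {
  lapply(values, function(v) {
    a <- array(NA_real_, tf$grid$shape)
    a[tf$idx] <- v
    a
  })
}

#' DTI scalar maps from a tensor field
#'
#' MD = (l1+l2+l3)/3, AD = l1, RD = (l2+l3)/2,
#' FA = sqrt(3/2) * sqrt(sum((li-MD)^2)) / sqrt(sum(li^2)).
#'
#' @param tensors a `tensor_field`.
#' @return named list of 3D arrays `FA`, `MD`, `AD`, `RD` (NA outside the fit
#'   mask).
#' @export
dti_scalars <- function(tensors) {
  e <- tensors$eigenvalues
  pm <- param_maps_from_eigs(e[, 1], e[, 2], e[, 3], tensors$tau_s)
  scatter_maps(pm[c("FA", "MD", "AD", "RD")], tensors)
}

#' Zero-displacement probability maps in the Gaussian limit
#'
#' For a Gaussian propagator with tensor eigenvalues l1 >= l2 >= l3 at
#' diffusion time tau: RTPP = (4 pi tau l1)^(-1/2) (mm^-1),
#' RTAP = (4 pi tau)^(-1) (l2 l3)^(-1/2) (mm^-2),
#' RTOP = (4 pi tau)^(-3/2) (l1 l2 l3)^(-1/2) (mm^-3), so RTOP = RTAP * RTPP
#' identically.
#'
#' @param tensors a `tensor_field`.
#' @param tau diffusion time in seconds; defaults to the scheme value stored
#'   in the field (Delta - delta/3, converted to s).
#' @return named list of 3D arrays `RTOP`, `RTAP`, `RTPP`.
#' @export
gaussian_zero_displacement <- function(tensors, tau = tensors$tau_s) {
  if (tau <= 0) stop("tau must be > 0")
  e <- tensors$eigenvalues
  pm <- param_maps_from_eigs(e[, 1], e[, 2], e[, 3], tau)
  scatter_maps(pm[c("RTOP", "RTAP", "RTPP")], tensors)
}

#' Propagator anisotropy in the Gaussian limit
#'
#' The angular similarity between the voxel propagator and its closest
#' isotropic counterpart (the Gaussian with tensor MD * I) is
#' `cos(theta) = 2^(3/2) (|D| |D_iso|)^(1/4) / |D + D_iso|^(1/2)` with
#' determinants of the 3x3 tensors; `PA = sqrt(1 - cos^2(theta))`. Reported
#' without any sigmoidal rescaling (the rescaling is monotone and therefore
#' irrelevant to clustering in normalized feature space).
#'
#' @param tensors a `tensor_field`.
#' @return named list with the 3D array `PA`.
#' @export
gaussian_pa <- function(tensors) {
  e <- tensors$eigenvalues
  pm <- param_maps_from_eigs(e[, 1], e[, 2], e[, 3], tensors$tau_s)
  scatter_maps(pm["PA"], tensors)
}

#' All scalar parameter maps from a tensor field
#'
#' @param tensors a `tensor_field`.
#' @param tau diffusion time (s).
#' @return named list of 3D arrays FA, MD, AD, RD, PA, RTAP, RTPP, RTOP.
#' @export
parameter_maps <- function(tensors, tau = tensors$tau_s) {
  e <- tensors$eigenvalues
  scatter_maps(param_maps_from_eigs(e[, 1], e[, 2], e[, 3], tau), tensors)
}

#' Write parameter maps as NIfTI volumes plus a manifest
#'
#' @param maps named list of 3D arrays.
#' @param grid a [vol_grid].
#' @param dir output directory.
#' @param tau_s diffusion time recorded in the manifest.
#' @return the directory, invisibly.
#' @export
write_parameter_maps <- function(maps, grid, dir, tau_s = NA_real_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  units <- c(FA = "1", MD = "mm^2/s", AD = "mm^2/s", RD = "mm^2/s", PA = "1",
             NG = "1", RTOP = "mm^-3", RTAP = "mm^-2", RTPP = "mm^-1")
  for (nm in names(maps)) {
    v <- maps[[nm]]
    v[is.na(v)] <- 0
    write_volume(v, grid, file.path(dir, paste0(nm, ".nii.gz")))
  }
  man <- data.frame(map = names(maps),
                    unit = ifelse(names(maps) %in% names(units),
                                  units[names(maps)], ""),
                    tau_s = tau_s)
  write.table(man, file.path(dir, "maps_manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
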