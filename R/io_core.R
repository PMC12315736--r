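# Volume and acquisition-scheme I/O, run configuration.
#
# Conventions used throughout the package: voxel indices are 1-based in R
# arrays, kernel/depth geometry is computed in mm from the voxel dimensions,
# world coordinates are mm RAS, and label 0 is reserved for background in
# every label volume.

#' Voxel grid geometry
#'
#' @param shape integer length-3 array dimensions (voxels).
#' @param voxel_size numeric length-3 voxel dimensions in mm.
#' @param affine optional 4x4 voxel-to-world (mm, RAS) matrix; defaults to a
#'   diagonal scaling by `voxel_size`.
#' @return an object of class `vol_grid`.
#' @export
vol_grid <- function(shape, voxel_size = c(0.2, 0.2, 0.2), affine = NULL) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be three integers >= 1")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths (mm)")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible 4x4 matrix")
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "vol_grid")
}

#' @export
print.vol_grid <- function(x, ...) {
  cat(sprintf("<vol_grid> %s voxels @ %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(format(x$voxel_size), collapse = "x")))
  invisible(x)
}

grid_from_nifti <- function(img) {
  d <- dim(img)
  pix <- attr(img, "pixdim")
  if (is.null(pix)) pix <- RNifti::pixdim(img)
  vol_grid(d[1:3], abs(pix[1:3]), affine = tryCatch({
    xf <- RNifti::xform(img)
    rbind(cbind(xf[1:3, 1:3], xf[1:3, 4]), c(0, 0, 0, 1))
  }, error = function(e) NULL))
}

#' Read a NIfTI volume
#'
#' Accepts 3D scalar/label volumes and 4D stacks; other dimensionalities are
#' rejected. Integer label volumes survive a write/read round trip unchanged.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a list with `data` (array), `grid` ([vol_grid]) and `n_volumes`
#'   (1 for 3D images).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop("not a readable NIfTI file: ", path, " (", conditionMessage(e), ")"))
  d <- dim(img)
  if (length(d) < 3L || length(d) > 4L)
    stop(sprintf("expected a 3D or 4D NIfTI image, got %dD", length(d)))
  dat <- as.array(img)
  attributes(dat) <- list(dim = d)
  list(data = dat, grid = grid_from_nifti(img),
       n_volumes = if (length(d) == 4L) d[4L] else 1L)
}

#' Write a NIfTI volume
#'
#' Integer-valued data are stored as 32-bit integers (exact round trip for
#' label volumes); floating data as doubles.
#'
#' @param data 3D or 4D array.
#' @param grid [vol_grid] supplying voxel size and affine.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, grid, path) {
  d <- dim(data)
  if (is.null(d) || length(d) < 3L || length(d) > 4L)
    stop(sprintf("expected a 3D or 4D array, got %dD", max(1L, length(d))))
  is_int <- is.integer(data) ||
    (is.numeric(data) && all(is.finite(data)) && all(data == round(data)) &&
       max(abs(range(data))) < 2^31)
  img <- RNifti::asNifti(data, reference = NULL)
  pd <- grid$voxel_size
  img <- RNifti::`pixdim<-`(img, pd)
  RNifti::writeNifti(img, path, datatype = if (is_int) "int32" else "double")
  invisible(path)
}

#' Diffusion gradient scheme
#'
#' @param b_values numeric vector of b-values (s/mm^2), one per volume.
#' @param directions matrix (n x 3) of gradient directions; rows for weighted
#'   volumes are normalized to unit length.
#' @param delta_small gradient pulse duration (ms).
#' @param delta_big gradient pulse separation (ms).
#' @param b0_threshold volumes with b-value at or below this are treated as
#'   non-diffusion-weighted (default 50 s/mm^2).
#' @return an object of class `gradient_scheme` with fields `b_values`,
#'   `directions`, `is_b0`, `delta_small`, `delta_big`, `tau_ms`
#'   (diffusion time Delta - delta/3) and `tau_s`.
#' @export
gradient_scheme <- function(b_values, directions, delta_small = 6, delta_big = 28,
                            b0_threshold = 50) {
  b_values <- as.numeric(b_values)
  directions <- as.matrix(directions)
  if (ncol(directions) != 3L) stop("directions must be an n x 3 matrix")
  if (nrow(directions) != length(b_values))
    stop(sprintf("length mismatch: %d b-values vs %d directions",
                 length(b_values), nrow(directions)))
  if (any(!is.finite(b_values)) || any(b_values < 0))
    stop("b_values must be finite and >= 0")
  if (delta_big <= delta_small / 3)
    stop("delta_big must exceed delta_small/3 (diffusion time must be positive)")
  is_b0 <- b_values <= b0_threshold
  nrm <- sqrt(rowSums(directions^2))
  bad <- !is_b0 & (nrm < 1e-12 | !is.finite(nrm))
  if (any(bad))
    stop("zero-norm direction for diffusion-weighted volume(s): ",
         paste(which(bad), collapse = ", "))
  renorm <- !is_b0 & abs(nrm - 1) > 1e-6
  if (any(renorm)) {
    warning(sprintf("%d direction(s) not unit norm; normalizing", sum(renorm)))
  }
  scale <- ifelse(is_b0 | nrm < 1e-12, 1, nrm)
  directions <- directions / scale
  tau_ms <- delta_big - delta_small / 3
  structure(list(b_values = b_values, directions = directions, is_b0 = is_b0,
                 delta_small = delta_small, delta_big = delta_big,
                 b0_threshold = b0_threshold,
                 tau_ms = tau_ms, tau_s = tau_ms / 1000),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("<gradient_scheme> %d volumes, shells: %s; delta=%g ms, Delta=%g ms, tau=%g ms\n",
              length(x$b_values),
              paste(sort(unique(round(x$b_values))), collapse = ","),
              x$delta_small, x$delta_big, x$tau_ms))
  invisible(x)
}

#' Shell table of a gradient scheme
#'
#' @param scheme a [gradient_scheme].
#' @param round_to b-values are grouped after rounding to this unit.
#' @return data.frame with columns `b` and `n_directions`.
#' @export
shell_table <- function(scheme, round_to = 1) {
  b <- round(scheme$b_values / round_to) * round_to
  tab <- table(b)
  data.frame(b = as.numeric(names(tab)), n_directions = as.integer(tab))
}

#' Read an FSL-style bval/bvec pair
#'
#' @param bval_path text file with one row of b-values.
#' @param bvec_path text file with three rows (x, y, z components).
#' @param ... passed to [gradient_scheme] (pulse timings, b0 threshold).
#' @return a [gradient_scheme].
#' @export
read_gradient_scheme <- function(bval_path, bvec_path, ...) {
  for (p in c(bval_path, bvec_path)) if (!file.exists(p)) stop("file not found: ", p)
  parse_tokens <- function(path) {
    toks <- scan(path, what = character(), quiet = TRUE)
    vals <- suppressWarnings(as.numeric(toks))
    if (any(is.na(vals))) stop("non-numeric token in ", path, ": ",
                               paste(toks[is.na(vals)], collapse = " "))
    vals
  }
  bvals <- parse_tokens(bval_path)
  bv <- parse_tokens(bvec_path)
  if (length(bv) != 3L * length(bvals))
    stop(sprintf("length mismatch: %d b-values but %d bvec entries (expected %d)",
                 length(bvals), length(bv), 3L * length(bvals)))
  dirs <- t(matrix(bv, nrow = 3L, byrow = TRUE))
  gradient_scheme(bvals, dirs, ...)
}

#' Write an FSL-style bval/bvec pair
#'
#' @param scheme a [gradient_scheme].
#' @param bval_path,bvec_path output paths.
#' @return invisibly, the two paths.
#' @export
write_gradient_scheme <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$b_values, trim = TRUE), collapse = " "), bval_path)
  writeLines(apply(t(scheme$directions), 1L, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Multi-shell acquisition scheme of the study design
#'
#' Reconstructs the acquisition bookkeeping of the targeted experiment: six
#' b-value shells at 100, 1000, 2500, 4500, 7000 and 10000 s/mm^2 carrying
#' 3, 9, 15, 21, 28 and 36 uniformly spread directions (112 diffusion-weighted
#' volumes in total), with pulse duration delta = 6 ms and separation
#' Delta = 28 ms.
#'
#' @return a [gradient_scheme] with 112 volumes.
#' @export
study_scheme <- function() {
  shells <- c(100, 1000, 2500, 4500, 7000, 10000)
  counts <- c(3, 9, 15, 21, 28, 36)
  b <- rep(shells, counts)
  dirs <- do.call(rbind, lapply(counts, fibonacci_directions))
  gradient_scheme(b, dirs, delta_small = 6, delta_big = 28)
}

#' Default run configuration
#'
#' All stage parameters with their default values: CRF filter standard
#' deviations 0.1 mm (radial) and 1.0 mm (tangential) on a 5-voxel support,
#' GMM features PA, NG, RTAP, RTPP with k = 14 (BIC search range 8..20),
#' morphological size threshold 100 voxels with 26-connectivity components and
#' face-adjacency boundary counting, and 6 equivolumetric layers.
#'
#' @param ... named overrides of individual fields.
#' @return an object of class `run_config` (a named list).
#' @export
default_config <- function(...) {
  cfg <- list(
    sigma_radial = 0.1,          # mm
    sigma_tangential = 1.0,      # mm
    support = 5L,                # kernel width, voxels per axis
    mask_restrict = FALSE,
    size_threshold = 100L,       # voxels
    component_connectivity = 26L,
    n_layers = 6L,
    features = c("PA", "NG", "RTAP", "RTPP"),
    k = 14L,
    k_range = c(8L, 20L),
    n_init = 5L,
    b0_threshold = 50,
    depth_mode = "equivolume",
    param_route = "supplied",    # "supplied" maps (external propagator fit
                                 # emulated by the phantom) or "fitted"
                                 # (Gaussian-limit maps from the DWIs)
    seed = 42L,
    paths = list()
  )
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, over)
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Unknown fields are rejected; missing fields take their defaults, so a dumped
#' configuration reloads to identical stage parameters.
#'
#' @param path YAML file written by [write_config].
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  for (f in c("support", "size_threshold", "component_connectivity", "n_layers",
              "k", "k_range", "n_init", "seed"))
    if (!is.null(raw[[f]])) raw[[f]] <- as.integer(raw[[f]])
  if (!is.null(raw$features)) raw$features <- as.character(raw$features)
  do.call(default_config, raw)
}

#' Read/write a two-column label-name table
#'
#' Tab-separated table with columns `label_id` and `name`.
#' @param path file path.
#' @return data.frame with `label_id` (integer) and `name` (character).
#' @export
read_label_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("label_id", "name") %in% names(tab)))
    stop("label table must have columns label_id and name")
  tab$label_id <- as.integer(tab$label_id)
  tab
}

#' @rdname read_label_table
#' @param table data.frame with columns `label_id` and `name`.
#' @export
write_label_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
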