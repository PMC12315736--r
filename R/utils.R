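# internal helpers shared across modules

#' Evaluate code with a locally seeded RNG
#'
#' Sets the random seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded stages never perturb the global stream.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# structured log line: "[stage] key=value key=value"; silent unless
# options(cytoseg.verbose = TRUE)
cs_log <- function(stage, ...) {
  if (!isTRUE(getOption("cytoseg.verbose", FALSE))) return(invisible(NULL))
  kv <- list(...)
  txt <- if (length(kv)) {
    paste(names(kv), vapply(kv, function(x) paste(format(x, digits = 6), collapse = ","),
                            character(1)), sep = "=", collapse = " ")
  } else ""
  message(sprintf("[%s] %s", stage, txt))
  invisible(NULL)
}

# linear index helpers for 3D arrays ----------------------------------------

# linear indices of all voxels as (i,j,k) matrix
vox_coords <- function(idx, dim) {
  idx0 <- idx - 1L
  nx <- dim[1L]; nxy <- dim[1L] * dim[2L]
  k <- idx0 %/% nxy
  j <- (idx0 - k * nxy) %/% nx
  i <- idx0 - k * nxy - j * nx
  cbind(i + 1L, j + 1L, k + 1L)
}

vox_index <- function(coords, dim) {
  (coords[, 3L] - 1L) * (dim[1L] * dim[2L]) + (coords[, 2L] - 1L) * dim[1L] + coords[, 1L]
}

# trilinear interpolation of one or more 3D fields at continuous voxel
# coordinates (1-based, voxel centers at integers). `fields` is a list of 3D
# arrays sharing `dim`; returns a matrix n x length(fields). Points outside
# the grid are clamped to the boundary.
trilinear <- function(fields, pts, dim) {
  if (is.array(fields)) fields <- list(fields)
  x <- pmin(pmax(pts[, 1L], 1), dim[1L])
  y <- pmin(pmax(pts[, 2L], 1), dim[2L])
  z <- pmin(pmax(pts[, 3L], 1), dim[3L])
  x0 <- pmin(floor(x), dim[1L] - 1L); y0 <- pmin(floor(y), dim[2L] - 1L)
  z0 <- pmin(floor(z), dim[3L] - 1L)
  if (dim[1L] == 1L) x0 <- rep(1, length(x))
  if (dim[2L] == 1L) y0 <- rep(1, length(y))
  if (dim[3L] == 1L) z0 <- rep(1, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  nx <- dim[1L]; nxy <- dim[1L] * dim[2L]
  base <- (z0 - 1) * nxy + (y0 - 1) * nx + x0
  dx <- if (dim[1L] > 1L) 1 else 0
  dy <- if (dim[2L] > 1L) nx else 0
  dz <- if (dim[3L] > 1L) nxy else 0
  w000 <- (1 - fx) * (1 - fy) * (1 - fz); w100 <- fx * (1 - fy) * (1 - fz)
  w010 <- (1 - fx) * fy * (1 - fz);       w110 <- fx * fy * (1 - fz)
  w001 <- (1 - fx) * (1 - fy) * fz;       w101 <- fx * (1 - fy) * fz
  w011 <- (1 - fx) * fy * fz;             w111 <- fx * fy * fz
  out <- matrix(0, nrow = nrow(pts), ncol = length(fields))
  for (f in seq_along(fields)) {
    v <- fields[[f]]
    out[, f] <- w000 * v[base] + w100 * v[base + dx] +
      w010 * v[base + dy] + w110 * v[base + dx + dy] +
      w001 * v[base + dz] + w101 * v[base + dx + dz] +
      w011 * v[base + dy + dz] + w111 * v[base + dx + dy + dz]
  }
  out
}

# central-difference spatial gradient of a 3D field (per-axis spacing in mm);
# one-sided differences at the grid border. Returns list(gx, gy, gz).
grad3 <- function(vol, spacing) {
  d <- dim(vol)
  g <- vector("list", 3L)
  for (ax in 1:3) {
    n <- d[ax]
    if (n == 1L) { g[[ax]] <- array(0, d); next }
    ip <- pmin(seq_len(n) + 1L, n)
    im <- pmax(seq_len(n) - 1L, 1L)
    step <- (ip - im) * spacing[ax]
    idx_p <- switch(ax, vol[ip, , , drop = FALSE], vol[, ip, , drop = FALSE], vol[, , ip, drop = FALSE])
    idx_m <- switch(ax, vol[im, , , drop = FALSE], vol[, im, , drop = FALSE], vol[, , im, drop = FALSE])
    diffv <- idx_p - idx_m
    stepa <- switch(ax,
                    array(step, d),
                    aperm(array(step, d[c(2, 1, 3)]), c(2, 1, 3)),
                    aperm(array(step, d[c(3, 1, 2)]), c(2, 3, 1)))
    g[[ax]] <- diffv / stepa
  }
  names(g) <- c("gx", "gy", "gz")
  g
}

# deterministic quasi-uniform unit vectors on the sphere (Fibonacci lattice)
fibonacci_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- pi * (3 - sqrt(5)) * (i - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
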