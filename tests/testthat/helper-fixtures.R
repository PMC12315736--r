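# shared fixtures and independent oracles

# small two-hemisphere slab phantom (fast; keeps the 5 areas x 3 layers = 14
# class layout of the default, every block >= 100 voxels)
tiny_phantom <- function(seed = 11L, ...) {
  make_phantom(phantom_spec(hemi_width = 10L, length = 45L, gm_thickness = 12L,
                            seed = seed, ...))
}

# all permutations of 1..n (brute-force assignment oracle)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- all_perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) out <- rbind(out, cbind(i, p + (p >= i)))
  unname(out)
}

# brute-force maximum-total-affinity one-to-one assignment of nr rows to
# distinct columns (nr <= nc)
brute_force_assignment <- function(A) {
  nr <- nrow(A); nc <- ncol(A)
  pm <- all_perms(nc)[, seq_len(nr), drop = FALSE]
  best <- -Inf
  for (r in seq_len(nrow(pm))) {
    tot <- sum(A[cbind(seq_len(nr), pm[r, ])])
    if (tot > best) best <- tot
  }
  best
}

fibdirs <- function(n) cytoseg:::fibonacci_directions(n)

# thin wrappers over internal geometry helpers
vox_coords_test <- function(idx, dims) cytoseg:::vox_coords(idx, dims)
trilinear_test <- function(field, pts, dims) {
  cytoseg:::trilinear(list(field), pts, dims)[, 1]
}

# mirror a volume across the midsagittal (first) axis
mirror_x <- function(vol) {
  vol[rev(seq_len(dim(vol)[1])), , , drop = FALSE]
}

# partition agreement that ignores label names
partitions_identical <- function(a, b) {
  ct <- table(a, b)
  all(rowSums(ct > 0) == 1) && all(colSums(ct > 0) == 1)
}
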