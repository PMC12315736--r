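# Segmentation scoring against ground truth.

#' Adjusted Rand index from a contingency matrix
#'
#' @param counts matrix of overlap counts between two partitions.
#' @return ARI in \[-1, 1\]; 1 for identical partitions, ~0 for independent
#'   ones. Invariant under label permutation of either partition.
#' @export
ari_from_counts <- function(counts) {
  n <- sum(counts)
  if (n < 2) return(NA_real_)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(counts))
  sum_a <- sum(comb2(rowSums(counts)))
  sum_b <- sum(comb2(colSums(counts)))
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < .Machine$double.eps) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Boundary voxels of a label volume
#'
#' A voxel is a boundary voxel iff it is labeled and at least one of its six
#' face neighbors carries a *different nonzero* label (interfaces with
#' background are not boundaries). Invariant under label renaming.
#'
#' @param labels integer 3D array.
#' @return logical 3D array.
#' @export
boundary_voxels <- function(labels) {
  dims <- dim(labels)
  out <- array(FALSE, dims)
  for (ax in 1:3) {
    n <- dims[ax]
    if (n < 2L) next
    hi <- switch(ax, labels[-1, , , drop = FALSE], labels[, -1, , drop = FALSE],
                 labels[, , -1, drop = FALSE])
    lo <- switch(ax, labels[-n, , , drop = FALSE], labels[, -n, , drop = FALSE],
                 labels[, , -n, drop = FALSE])
    diffpair <- hi != lo & hi > 0L & lo > 0L
    mark_hi <- array(FALSE, dims); mark_lo <- array(FALSE, dims)
    switch(ax,
           { mark_hi[-1, , ] <- diffpair; mark_lo[-n, , ] <- diffpair },
           { mark_hi[, -1, ] <- diffpair; mark_lo[, -n, ] <- diffpair },
           { mark_hi[, , -1] <- diffpair; mark_lo[, , -n] <- diffpair })
    out <- out | mark_hi | mark_lo
  }
  out
}

#' Mean symmetric surface distance between two boundary sets
#'
#' Average of the mean distance from each set to the other, computed with
#' voxel-size-aware Euclidean distance transforms. Zero iff the sets
#' coincide; symmetric in its arguments.
#'
#' @param bound_a,bound_b logical 3D arrays.
#' @param grid a [vol_grid].
#' @return distance in mm (0 if both sets are empty, NA if exactly one is).
#' @export
boundary_distance <- function(bound_a, bound_b, grid) {
  na <- sum(bound_a); nb <- sum(bound_b)
  if (na == 0 && nb == 0) return(0)
  if (na == 0 || nb == 0) return(NA_real_)
  d_to_b <- edt_mm(bound_b, grid)
  d_to_a <- edt_mm(bound_a, grid)
  (mean(d_to_b[bound_a]) + mean(d_to_a[bound_b])) / 2
}

#' Score a predicted segmentation against ground truth
#'
#' Labels are first matched one-to-one by the Kuhn-Munkres assignment on the
#' prediction-truth contingency matrix, then the per-label Dice coefficients
#' of the matched pairs are computed; the adjusted Rand index is computed on
#' the raw partitions (matching-free), and the boundary distance compares
#' the 6-neighbor interface sets.
#'
#' @param pred,truth integer 3D arrays on the same grid.
#' @param grid a [vol_grid].
#' @param mask optional logical 3D array restricting the comparison.
#' @return an object of class `segmentation_score`: `mean_dice`, `dice`
#'   (per matched truth label), `ari`, `boundary_distance_mm`, `matching`.
#' @export
score_against_truth <- function(pred, truth, grid, mask = NULL) {
  if (!all(dim(pred) == dim(truth))) stop("grid mismatch between pred and truth")
  ct <- cross_tabulate(truth, pred, mask)
  ari <- ari_from_counts(ct$counts)
  asg <- kuhn_munkres_match(ct$counts)
  one2one <- asg$pairs[asg$pairs$round == 1L, , drop = FALSE]
  truth_sizes <- rowSums(ct$counts)
  pred_sizes <- colSums(ct$counts)
  dice <- 2 * one2one$overlap /
    (truth_sizes[one2one$row] + pred_sizes[one2one$col])
  names(dice) <- ct$row_labels[one2one$row]
  # truth labels that received no match score zero
  all_dice <- setNames(numeric(length(ct$row_labels)),
                       as.character(ct$row_labels))
  all_dice[names(dice)] <- dice
  bd <- boundary_distance(boundary_voxels(pred), boundary_voxels(truth), grid)
  structure(list(mean_dice = mean(all_dice), dice = all_dice, ari = ari,
                 boundary_distance_mm = bd, matching = asg),
            class = "segmentation_score")
}

#' @export
print.segmentation_score <- function(x, ...) {
  cat(sprintf("<segmentation_score> mean Dice %.3f, ARI %.3f, boundary distance %.3f mm\n",
              x$mean_dice, x$ari, x$boundary_distance_mm))
  invisible(x)
}

#' Write a segmentation score as TSV
#' @param score a `segmentation_score`.
#' @param path output path.
#' @export
write_score <- function(score, path) {
  tab <- data.frame(metric = c("mean_dice", "ari", "boundary_distance_mm",
                               paste0("dice_label_", names(score$dice))),
                    value = c(score$mean_dice, score$ari,
                              score$boundary_distance_mm, unname(score$dice)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
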