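# Label harmonization across hemispheres.
#
# Refined cluster labels are arbitrary within each hemisphere. Both label
# sets are cross-tabulated against a symmetric reference: the composite
# area-by-equivolumetric-layer segmentation. Because the reference rows are
# identical (and identically ordered) in both hemispheres, the product
# M = C_L' C_R of the two contingency matrices is an affinity between left
# and right cluster labels, and the Kuhn-Munkres assignment on M matches
# them; leftover labels (the larger side) are then attached greedily in
# decreasing size order. Only label identities change - the geometry of
# every labeled region is untouched.

#' Composite area-by-layer atlas labels
#'
#' Splits every labeled area into `n_layers` equivolumetric layers and
#' encodes the composite label as `area_id * 100 + layer_id`.
#'
#' @param area_labels integer 3D array of atlas areas (0 = background).
#' @param depth a `cortical_depth` or 3D equivolume depth array.
#' @param gm_mask logical 3D array.
#' @param n_layers layers per area (default 6; must be <= 99 for the
#'   encoding).
#' @return integer 3D array of composite labels.
#' @export
make_layer_atlas <- function(area_labels, depth, gm_mask, n_layers = 6L) {
  n_layers <- as.integer(n_layers)
  if (n_layers < 1L || n_layers > 99L)
    stop("n_layers must be in 1..99 (composite encoding area*100 + layer)")
  layers <- equivolume_layers(depth, gm_mask, n_layers)
  sel <- area_labels > 0L & layers > 0L
  out <- array(0L, dim(area_labels))
  out[sel] <- area_labels[sel] * 100L + layers[sel]
  out
}

#' Cross-tabulate two label volumes
#'
#' `counts[i, j]` is the number of voxels (within `mask`) carrying row label
#' i in `seg_a` and column label j in `seg_b`; background (0) is excluded
#' from both sides.
#'
#' @param seg_a,seg_b integer 3D arrays on the same grid.
#' @param mask optional logical 3D array.
#' @return an object of class `contingency`: `counts` (matrix),
#'   `row_labels`, `col_labels`.
#' @export
cross_tabulate <- function(seg_a, seg_b, mask = NULL) {
  if (!all(dim(seg_a) == dim(seg_b)))
    stop("grid mismatch between segmentations")
  sel <- seg_a > 0L & seg_b > 0L
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(seg_a))) stop("grid mismatch with mask")
    sel <- sel & (as.array(mask) > 0)
  }
  a <- as.integer(seg_a[sel]); b <- as.integer(seg_b[sel])
  ra <- sort(unique(a)); rb <- sort(unique(b))
  counts <- matrix(0L, length(ra), length(rb),
                   dimnames = list(ra, rb))
  tab <- table(factor(a, levels = ra), factor(b, levels = rb))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, row_labels = ra, col_labels = rb),
            class = "contingency")
}

#' @export
print.contingency <- function(x, ...) {
  cat(sprintf("<contingency> %d x %d labels, %d voxels\n",
              length(x$row_labels), length(x$col_labels), sum(x$counts)))
  invisible(x)
}

#' Write a contingency matrix as TSV (label-id header row/column)
#' @param ct a `contingency`.
#' @param path output path.
#' @export
write_contingency <- function(ct, path) {
  tab <- as.data.frame(ct$counts)
  tab <- cbind(label = ct$row_labels, tab)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hemisphere correspondence matrix
#'
#' `M = C_L' C_R` for two contingency matrices sharing the identical ordered
#' reference (row) label list: an affinity between left and right cluster
#' labels.
#'
#' @param c_left,c_right `contingency` objects (reference labels as rows).
#' @return list with `M` (matrix, left labels x right labels), `left_labels`,
#'   `right_labels`.
#' @export
hemisphere_correspondence <- function(c_left, c_right) {
  if (!identical(c_left$row_labels, c_right$row_labels)) {
    extra_l <- setdiff(c_left$row_labels, c_right$row_labels)
    extra_r <- setdiff(c_right$row_labels, c_left$row_labels)
    stop("reference label lists differ between hemispheres; only-left: {",
         paste(extra_l, collapse = ","), "}, only-right: {",
         paste(extra_r, collapse = ","), "}",
         if (!length(extra_l) && !length(extra_r))
           " (same set, different order)" else "")
  }
  M <- crossprod(c_left$counts, c_right$counts)
  dimnames(M) <- list(c_left$col_labels, c_right$col_labels)
  list(M = M, left_labels = c_left$col_labels, right_labels = c_right$col_labels)
}

#' Kuhn-Munkres label assignment with greedy completion
#'
#' Round 1 solves the optimal one-to-one assignment maximizing total
#' affinity on the rectangular matrix (exact Kuhn-Munkres / Jonker-Volgenant).
#' Remaining unmatched row labels are then assigned in decreasing size order,
#' each to the column with its largest affinity (many-to-one), one per
#' subsequent round. Rows whose affinity is entirely zero stay unmatched.
#'
#' @param affinity non-negative matrix (rows x columns).
#' @param row_sizes optional row sizes used to order the greedy rounds;
#'   defaults to the affinity row sums.
#' @return an object of class `label_assignment`: `pairs` (data.frame `row`,
#'   `col`, `overlap`, `round`), `unmatched_rows`. Row/column names of
#'   `affinity` are used as labels when present.
#' @export
kuhn_munkres_match <- function(affinity, row_sizes = NULL) {
  affinity <- as.matrix(affinity)
  if (!length(affinity)) stop("empty affinity matrix")
  if (any(affinity < 0)) stop("affinity must be non-negative")
  nr <- nrow(affinity); nc <- ncol(affinity)
  rn <- rownames(affinity); cn <- colnames(affinity)
  if (is.null(rn)) rn <- as.character(seq_len(nr))
  if (is.null(cn)) cn <- as.character(seq_len(nc))
  # exact one-to-one round on the rectangular matrix (maximize = minimize -A)
  if (nr <= nc) {
    asg <- hungarian_cpp(-affinity)
    pairs <- data.frame(row = seq_len(nr), col = asg)
  } else {
    asg <- hungarian_cpp(-t(affinity))
    pairs <- data.frame(row = asg, col = seq_len(nc))
  }
  pairs$overlap <- affinity[cbind(pairs$row, pairs$col)]
  # assigning a zero-overlap pair is meaningless; release those rows
  keep <- pairs$overlap > 0
  round1 <- pairs[keep, , drop = FALSE]
  round1$round <- 1L
  leftover <- setdiff(seq_len(nr), round1$row)
  if (is.null(row_sizes)) row_sizes <- rowSums(affinity)
  leftover <- leftover[order(-row_sizes[leftover])]
  rounds <- round1
  rnd <- 1L
  unmatched <- integer(0)
  for (r in leftover) {
    if (all(affinity[r, ] == 0)) {
      unmatched <- c(unmatched, r)
      next
    }
    rnd <- rnd + 1L
    j <- which.max(affinity[r, ])
    rounds <- rbind(rounds, data.frame(row = r, col = j,
                                       overlap = affinity[r, j], round = rnd))
  }
  rounds$row_label <- rn[rounds$row]
  rounds$col_label <- cn[rounds$col]
  structure(list(pairs = rounds, unmatched_rows = rn[unmatched],
                 n_rows = nr, n_cols = nc),
            class = "label_assignment")
}

#' @export
print.label_assignment <- function(x, ...) {
  cat(sprintf("<label_assignment> %d/%d rows matched (%d one-to-one), %d unmatched\n",
              nrow(x$pairs), x$n_rows, sum(x$pairs$round == 1L),
              length(x$unmatched_rows)))
  invisible(x)
}

#' Write a label assignment as TSV
#' @param assignment a `label_assignment`.
#' @param path output path.
#' @export
write_assignment <- function(assignment, path) {
  write.table(assignment$pairs[, c("row_label", "col_label", "overlap", "round")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonize cluster labels across hemispheres
#'
#' Cross-tabulates each hemisphere's cluster labels against the shared
#' area-by-layer atlas, forms `M = C_L' C_R`, assigns right labels to left
#' labels by [kuhn_munkres_match] (rows = right labels, so every right label
#' receives a left id; many-to-one allowed after the optimal round), and
#' rewrites the right-hemisphere volume onto the left's label ids. The voxel
#' geometry of every label is unchanged - only ids are renamed.
#'
#' @param left_labels,right_labels integer 3D arrays of refined cluster
#'   labels.
#' @param layer_atlas composite area-by-layer label volume
#'   ([make_layer_atlas]); must be symmetric across hemispheres.
#' @param mask_left,mask_right logical 3D arrays selecting each hemisphere's
#'   cortical voxels.
#' @return list with `right_relabeled` (3D array), `assignment`
#'   (`label_assignment`, rows = right labels), `M`, `c_left`, `c_right`.
#' @export
harmonize_hemispheres <- function(left_labels, right_labels, layer_atlas,
                                  mask_left, mask_right) {
  c_left <- cross_tabulate(layer_atlas, left_labels, mask_left)
  c_right <- cross_tabulate(layer_atlas, right_labels, mask_right)
  if (!identical(c_left$row_labels, c_right$row_labels)) {
    common <- intersect(c_left$row_labels, c_right$row_labels)
    if (!length(common))
      stop("hemispheres share no atlas-layer labels")
    subset_ct <- function(ct) {
      keep <- ct$row_labels %in% common
      structure(list(counts = ct$counts[keep, , drop = FALSE],
                     row_labels = ct$row_labels[keep],
                     col_labels = ct$col_labels), class = "contingency")
    }
    c_left <- subset_ct(c_left); c_right <- subset_ct(c_right)
  }
  corr <- hemisphere_correspondence(c_left, c_right)
  right_sizes <- colSums(c_right$counts)
  asg <- kuhn_munkres_match(t(corr$M), row_sizes = right_sizes)
  # map right label -> left label id
  right_ids <- as.integer(corr$right_labels)
  left_ids <- as.integer(corr$left_labels)
  map <- setNames(rep(NA_integer_, length(right_ids)), right_ids)
  map[asg$pairs$row_label] <- left_ids[asg$pairs$col]
  # unmatched right labels keep fresh ids beyond the left range
  un <- asg$unmatched_rows
  if (length(un)) {
    map[un] <- max(left_ids) + seq_along(un)
    cs_log("harmonize_hemispheres", unmatched_right = length(un))
  }
  out <- right_labels + 0L
  nz <- which(out > 0L)
  pos <- match(out[nz], right_ids)
  known <- !is.na(pos)
  out[nz[known]] <- map[pos[known]]
  list(right_relabeled = out, assignment = asg, M = corr$M,
       c_left = c_left, c_right = c_right)
}
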