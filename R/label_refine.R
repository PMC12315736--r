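# 3D morphological label refinement.
#
# GMM clusters are spatially agnostic, so one cluster can comprise several
# disconnected cytoarchitectonic domains. Refinement first relabels every
# connected component of every cluster as its own label, then iteratively
# merges components smaller than the size threshold into the face-adjacent
# neighbor with the largest shared boundary. Components use 26-connectivity
# (avoiding spurious splits of thin curved laminae); shared boundaries are
# counted over 6-face adjacency, approximating shared surface area.

#' Morphology parameters
#'
#' @param size_threshold components with fewer voxels than this are merged
#'   (default 100); components at or above the threshold are retained.
#' @param component_connectivity 6, 18 or 26 (default 26).
#' @return an object of class `morphology_params`.
#' @export
morphology_params <- function(size_threshold = 100L, component_connectivity = 26L) {
  size_threshold <- as.integer(size_threshold)
  if (size_threshold < 1L) stop("size_threshold must be >= 1")
  if (!component_connectivity %in% c(6L, 18L, 26L))
    stop("component_connectivity must be 6, 18 or 26")
  structure(list(size_threshold = size_threshold,
                 component_connectivity = as.integer(component_connectivity)),
            class = "morphology_params")
}

#' Split disconnected components of each label
#'
#' Every connected component of every nonzero input label receives a unique
#' output label; the voxel set is unchanged.
#'
#' @param labels integer 3D array (0 = background).
#' @param params a [morphology_params].
#' @return list with `labels` (relabeled volume) and `provenance`
#'   (data.frame: `new_label`, `source_label`, `size`).
#' @export
split_components <- function(labels, params = morphology_params()) {
  dims <- dim(labels)
  comp <- array(label_components_cpp(as.integer(labels), dims,
                                     params$component_connectivity), dims)
  nz <- comp > 0L
  sizes <- tabulate(comp[nz])
  source_lab <- integer(length(sizes))
  first <- which(nz)[!duplicated(comp[nz])]
  source_lab[comp[first]] <- labels[first]
  prov <- data.frame(new_label = seq_along(sizes), source_label = source_lab,
                     size = sizes)
  list(labels = comp, provenance = prov)
}

#' Merge sub-threshold components into their dominant neighbor
#'
#' Iteratively takes the smallest component below the size threshold and
#' merges it into the adjacent label sharing the most voxel faces (ties
#' broken toward the lower label id); sizes and adjacency are recomputed
#' after every merge, and the loop ends when no sub-threshold component with
#' a neighbor remains. Components without any neighbor are kept and logged.
#'
#' @param labels integer 3D array of component labels
#'   (typically [split_components] output).
#' @param params a [morphology_params].
#' @return list with `labels`, `merged` (data.frame: `label`, `merged_into`,
#'   `size`) and `orphans` (labels kept despite being sub-threshold).
#' @export
merge_small_components <- function(labels, params = morphology_params()) {
  labels <- labels + 0L
  dims <- dim(labels)
  nx <- dims[1]; nxy <- dims[1] * dims[2]
  merged_lab <- integer(0); merged_into <- integer(0); merged_size <- integer(0)
  orphans <- integer(0)
  sizes <- tabulate(labels[labels > 0L])
  repeat {
    present <- which(sizes > 0L)
    small <- setdiff(present[sizes[present] < params$size_threshold], orphans)
    if (!length(small)) break
    victim <- small[which.min(sizes[small])]
    vox <- which(labels == victim)
    co <- vox_coords(vox, dims)
    # face neighbors of the victim component, with grid-border guards
    nb <- integer(0)
    for (ax in 1:3) {
      stride <- c(1L, nx, nxy)[ax]
      for (sgn in c(-1L, 1L)) {
        ok <- if (sgn < 0) co[, ax] > 1L else co[, ax] < dims[ax]
        nb <- c(nb, labels[vox[ok] + sgn * stride])
      }
    }
    nb <- nb[nb > 0L & nb != victim]
    if (!length(nb)) {
      orphans <- c(orphans, victim)
      cs_log("merge_small_components", orphan = victim, size = sizes[victim])
      next
    }
    cnt <- tabulate(nb)
    best <- which(cnt == max(cnt))[1L]   # ties go to the lower label id
    labels[vox] <- best
    merged_lab <- c(merged_lab, victim)
    merged_into <- c(merged_into, best)
    merged_size <- c(merged_size, sizes[victim])
    sizes[best] <- sizes[best] + sizes[victim]
    sizes[victim] <- 0L
  }
  list(labels = labels,
       merged = data.frame(label = merged_lab, merged_into = merged_into,
                           size = merged_size),
       orphans = orphans)
}

#' Refine a cluster label volume (split, then merge)
#'
#' Composition of [split_components] and [merge_small_components], with
#' summary statistics: initial cluster count, post-split and post-merge
#' component counts, and the fraction of labeled voxels that belonged to
#' sub-threshold components (the "noisy voxel" fraction).
#'
#' @param labels integer 3D array (0 = background).
#' @param params a [morphology_params].
#' @return an object of class `refined_labels`: `labels`, `provenance`,
#'   `merged`, `orphans`, `stats` (named list).
#' @export
refine <- function(labels, params = morphology_params()) {
  sp <- split_components(labels, params)
  sub <- sp$provenance$size < params$size_threshold
  frac_noisy <- if (sum(sp$provenance$size) > 0)
    sum(sp$provenance$size[sub]) / sum(sp$provenance$size) else 0
  mg <- merge_small_components(sp$labels, params)
  final_ids <- sort(unique(mg$labels[mg$labels > 0L]))
  # compact final label ids to 1..n
  out <- mg$labels
  if (length(final_ids)) {
    remap <- integer(max(final_ids))
    remap[final_ids] <- seq_along(final_ids)
    out[out > 0L] <- remap[out[out > 0L]]
  }
  prov <- sp$provenance
  prov$final_label <- ifelse(prov$new_label %in% mg$merged$label, NA_integer_,
                             ifelse(prov$new_label %in% final_ids,
                                    match(prov$new_label, final_ids), NA_integer_))
  stats <- list(initial_clusters = length(setdiff(unique(as.integer(labels)), 0L)),
                post_split = nrow(sp$provenance),
                post_merge = length(final_ids),
                subthreshold_fraction = frac_noisy)
  cs_log("refine", initial = stats$initial_clusters, post_split = stats$post_split,
         post_merge = stats$post_merge,
         subthreshold_fraction = round(frac_noisy, 4))
  structure(list(labels = out, provenance = prov, merged = mg$merged,
                 orphans = mg$orphans, stats = stats), class = "refined_labels")
}

#' Write refinement provenance as TSV
#' @param refined a `refined_labels`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_refinement <- function(refined, path) {
  write.table(refined$provenance, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
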