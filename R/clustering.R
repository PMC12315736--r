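# Voxelwise Gaussian mixture clustering of normalized scalar features.
#
# Clustering is deliberately spatially agnostic: the feature matrix carries
# no voxel coordinates, and each hemisphere is clustered independently on
# z-scored features. The mixture is fit with full covariances by batch EM
# (k-means++ seeding, several restarts keeping the best likelihood), so the
# result is invariant to the ordering of the input voxels; the component
# count is selected by the Bayesian Information Criterion.

#' Build a z-scored feature matrix from parameter maps
#'
#' Rows are the voxels of `gm_mask` intersected with `hemisphere_mask`;
#' columns are the named maps, z-scored per hemisphere. Voxels with any
#' non-finite feature are excluded (their count is logged).
#'
#' @param params named list of 3D arrays (e.g. `PA`, `NG`, `RTAP`, `RTPP`).
#' @param gm_mask logical 3D array of cortical voxels.
#' @param hemisphere_mask logical 3D array selecting one hemisphere.
#' @param feature_names which maps to use, in column order (default
#'   `c("PA","NG","RTAP","RTPP")`).
#' @param hemisphere label stored on the object (`"left"`/`"right"`).
#' @return an object of class `feature_matrix`: `values` (n x d, z-scored),
#'   `voxel_index` (linear indices), `feature_names`, `center`, `scale`,
#'   `hemisphere`, `grid_shape`.
#' @export
build_feature_matrix <- function(params, gm_mask, hemisphere_mask,
                                 feature_names = c("PA", "NG", "RTAP", "RTPP"),
                                 hemisphere = "left") {
  missing_maps <- setdiff(feature_names, names(params))
  if (length(missing_maps))
    stop("requested feature map(s) missing: ", paste(missing_maps, collapse = ", "))
  sel <- as.array(gm_mask) > 0 & as.array(hemisphere_mask) > 0
  idx <- which(sel)
  raw <- sapply(feature_names, function(f) params[[f]][idx])
  if (!is.matrix(raw)) raw <- matrix(raw, ncol = length(feature_names),
                                     dimnames = list(NULL, feature_names))
  finite <- rowSums(!is.finite(raw)) == 0
  if (!all(finite)) {
    cs_log("build_feature_matrix", nonfinite_excluded = sum(!finite))
    raw <- raw[finite, , drop = FALSE]
    idx <- idx[finite]
  }
  if (nrow(raw) < 2L) stop("fewer than two usable voxels in the selection")
  ctr <- colMeans(raw)
  scl <- apply(raw, 2L, sd)
  if (any(scl < 1e-12))
    stop("zero-variance feature: ",
         paste(feature_names[scl < 1e-12], collapse = ", "))
  vals <- sweep(sweep(raw, 2L, ctr), 2L, scl, "/")
  structure(list(values = vals, voxel_index = idx,
                 feature_names = feature_names, center = ctr, scale = scl,
                 hemisphere = hemisphere, grid_shape = dim(gm_mask)),
            class = "feature_matrix")
}

# k-means++ seeding: spread initial centers with probability proportional to
# squared distance from the chosen set
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  if (k > 1L) for (j in 2:k) {
    p <- d2 / sum(d2)
    i <- sample.int(n, 1L, prob = p)
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
  }
  centers
}

# one EM run from given responsibilities; the batch loop itself is compiled
# (gmm_em_cpp) - it is the performance-critical inner kernel of the pipeline
gmm_em <- function(X, resp, max_iter, tol, reg) {
  fit <- gmm_em_cpp(X, resp, as.integer(max_iter), tol, reg)
  if (fit$n_reseed > 0)
    cs_log("fit_gmm", reseeded_components = fit$n_reseed)
  fit
}

# split-and-merge refinement: plain EM at moderate separation regularly
# converges to solutions that fuse one close component pair while splitting
# another component in two. Propose merging the closest pair (Mahalanobis
# under the pooled covariance) while splitting a high-spread component along
# its principal axis, rerun EM, and keep the move only if the likelihood
# improves. Deterministic given the input fit.
split_merge_refine <- function(X, fit, max_iter, tol, reg, rounds = 5L) {
  k <- length(fit$weights)
  if (k < 3L) return(fit)
  for (r in seq_len(rounds)) {
    means <- fit$means
    covs <- fit$covariances
    dmin <- Inf; mi <- 1L; mj <- 2L
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      Sp <- (covs[, , i] + covs[, , j]) / 2
      dd <- tryCatch(
        as.numeric(crossprod(means[i, ] - means[j, ],
                             solve(Sp, means[i, ] - means[j, ]))),
        error = function(e) Inf)
      if (dd < dmin) { dmin <- dd; mi <- i; mj <- j }
    }
    crit <- vapply(seq_len(k), function(j) {
      fit$weights[j] * max(eigen(covs[, , j], symmetric = TRUE,
                                 only.values = TRUE)$values)
    }, numeric(1))
    improved <- FALSE
    for (sc in order(-crit)[seq_len(min(3L, k))]) {
      if (sc %in% c(mi, mj)) next
      resp <- fit$resp
      resp[, mi] <- resp[, mi] + resp[, mj]
      eg <- eigen(covs[, , sc], symmetric = TRUE)
      side <- (X %*% eg$vectors[, 1] -
                 sum(means[sc, ] * eg$vectors[, 1])) > 0
      resp[, mj] <- fit$resp[, sc] * side
      resp[, sc] <- fit$resp[, sc] * !side
      cand <- gmm_em(X, resp, max_iter, tol, reg)
      if (cand$loglik > fit$loglik + 1e-8 * abs(fit$loglik)) {
        cs_log("fit_gmm", split_merge_gain = cand$loglik - fit$loglik,
               merged = paste(mi, mj), split = sc)
        fit <- cand
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  fit
}

#' Fit a full-covariance Gaussian mixture model
#'
#' Batch EM from k-means++ seeds (polished by a short Lloyd pass), `n_init`
#' restarts keeping the best log-likelihood, covariance regularization on the
#' diagonal, convergence on relative log-likelihood change. Components are
#' reordered canonically (lexicographically by mean vector), which makes hard
#' labels reproducible and invariant to voxel-order permutations for
#' well-separated data.
#'
#' @param features a `feature_matrix`, or a plain numeric matrix.
#' @param k number of mixture components.
#' @param seed integer seed (the fit is deterministic given the seed).
#' @param n_init number of restarts (default 5).
#' @param max_iter EM iteration cap (default 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-7).
#' @param reg diagonal covariance regularization (default 1e-6).
#' @return an object of class `gmm_result`: `k`, `means`, `covariances`,
#'   `weights`, `labels` (1..k, maximum posterior), `loglik`, `bic`,
#'   `n_parameters`, `n`, `d`.
#' @export
fit_gmm <- function(features, k, seed = 42L, n_init = 5L, max_iter = 500L,
                    tol = 1e-7, reg = 1e-6) {
  X <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  n <- nrow(X); d <- ncol(X)
  if (k < 1L) stop("k must be >= 1")
  if (n <= 10 * k * d)
    stop(sprintf("too few voxels (%d) for k=%d with %d features", n, k, d))
  best <- NULL
  with_seed(seed, {
    for (init in seq_len(n_init)) {
      centers <- kmeanspp_centers(X, k)
      assign0 <- rep(1L, n)
      if (k > 1L) {
        km <- suppressWarnings(
          kmeans(X, centers = centers, iter.max = 50L, algorithm = "Lloyd"))
        assign0 <- km$cluster
      }
      # hard responsibilities from the k-means partition
      resp <- matrix(0, n, k)
      resp[cbind(seq_len(n), assign0)] <- 1
      fit <- gmm_em(X, resp, max_iter = max_iter, tol = tol, reg = reg)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    best <- split_merge_refine(X, best, max_iter = max_iter, tol = tol,
                               reg = reg)
  })
  # canonical component order: lexicographic by mean vector
  ord <- do.call(order, as.data.frame(best$means))
  means <- best$means[ord, , drop = FALSE]
  weights <- as.numeric(best$weights)[ord]
  covs <- lapply(ord, function(j) best$covariances[, , j])
  labels <- max.col(best$resp[, ord, drop = FALSE], ties.method = "first")
  p <- (k - 1) + k * d + k * d * (d + 1) / 2
  bic <- -2 * best$loglik + p * log(n)
  structure(list(k = k, means = means, covariances = covs, weights = weights,
                 labels = labels, loglik = best$loglik, bic = bic,
                 n_parameters = p, n = n, d = d, n_iter = best$n_iter,
                 feature_names = if (inherits(features, "feature_matrix"))
                   features$feature_names else colnames(X)),
            class = "gmm_result")
}

#' @export
print.gmm_result <- function(x, ...) {
  cat(sprintf("<gmm_result> k=%d, n=%d, d=%d, logL=%.2f, BIC=%.2f\n",
              x$k, x$n, x$d, x$loglik, x$bic))
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' Fits the GMM for every k in `k_range` and minimizes
#' `BIC = -2 logL + p log(n)` with
#' `p = (k-1) + k d + k d (d+1)/2` free parameters.
#'
#' @param features a `feature_matrix` or numeric matrix.
#' @param k_range integer vector of candidate component counts (default
#'   8..20).
#' @param seed integer seed.
#' @param ... passed to [fit_gmm].
#' @return list with `best_k`, `best_fit` (the winning `gmm_result`) and
#'   `table` (data.frame k / loglik / n_parameters / bic).
#' @export
select_k_bic <- function(features, k_range = 8:20, seed = 42L, ...) {
  k_range <- as.integer(k_range)
  if (!length(k_range)) stop("k_range must be non-empty")
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    fits[[i]] <- fit_gmm(features, k_range[i], seed = seed + k_range[i], ...)
    cs_log("select_k_bic", k = k_range[i], bic = fits[[i]]$bic)
  }
  tab <- data.frame(k = k_range,
                    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
                    n_parameters = vapply(fits, `[[`, numeric(1), "n_parameters"),
                    bic = vapply(fits, `[[`, numeric(1), "bic"))
  best <- which.min(tab$bic)
  list(best_k = k_range[best], best_fit = fits[[best]], table = tab)
}

#' Scatter hard cluster labels back into a 3D volume
#'
#' @param result a `gmm_result` (or an integer label vector).
#' @param features the `feature_matrix` the labels belong to.
#' @param grid_shape 3-vector of volume dimensions; defaults to the shape
#'   recorded on the feature matrix.
#' @return integer 3D array, 0 outside the clustered voxels.
#' @export
labels_to_volume <- function(result, features, grid_shape = features$grid_shape) {
  labels <- if (inherits(result, "gmm_result")) result$labels else as.integer(result)
  if (length(labels) != length(features$voxel_index))
    stop("label count does not match the feature matrix voxel index")
  if (any(features$voxel_index > prod(grid_shape)))
    stop("voxel index out of bounds for grid shape")
  vol <- array(0L, grid_shape)
  vol[features$voxel_index] <- labels
  vol
}
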