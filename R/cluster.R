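# K-means clustering of ILR budget coordinates -------------------------------

# Draw n_init sets of k distinct initial centers, reproducibly.
.init_centers <- function(X, k, n_init, seed) {
  ux <- unique(X)
  if (nrow(ux) < k) {
    stop("fewer distinct points than clusters requested", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(n_init), function(i) {
    ux[sample.int(nrow(ux), k), , drop = FALSE]
  })
}

.lloyd <- function(X, centers) {
  suppressWarnings(kmeans(X, centers = centers, iter.max = 200L,
                          algorithm = "Lloyd"))
}

.finish_model <- function(fit, k, n_init, seed, ids) {
  sizes <- fit$size
  ord <- order(-sizes, apply(fit$centers, 1L, paste, collapse = ","))
  letters_k <- LETTERS[seq_len(k)]
  relabel <- character(k)
  relabel[ord] <- letters_k
  assignments <- setNames(relabel[fit$cluster], ids)
  centers <- fit$centers[ord, , drop = FALSE]
  rownames(centers) <- letters_k
  structure(list(k = k, centers = centers, assignments = assignments,
                 inertia = fit$tot.withinss, sizes = setNames(sizes[ord], letters_k),
                 n_init = n_init, seed = seed),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("k-means model: k = %d, inertia = %.4f, sizes: %s\n",
              x$k, x$inertia,
              paste(sprintf("%s=%d", names(x$sizes), x$sizes), collapse = " ")))
  invisible(x)
}

#' Cross-sectional k-means on coordinate vectors
#'
#' Lloyd's algorithm, restarted from `n_init` random draws of k distinct
#' observations, keeping the solution with the smallest within-cluster
#' inertia. Deterministic given `seed`. Cluster labels `A`, `B`, ... are
#' assigned by descending cluster size (ties broken by the lexicographic
#' order of the center coordinates).
#'
#' @param X numeric matrix, one row per sow (e.g. ILR coordinates on D0).
#' @param k number of clusters, `1 <= k <= nrow(X)`.
#' @param n_init number of random restarts.
#' @param seed integer seed (mandatory).
#' @param extra_centers optional list of additional initial-center matrices
#'   to try alongside the random restarts (used by [cluster_sweep()]).
#' @return A `cluster_model`: `k`, `centers`, named `assignments` (letters),
#'   `inertia`, `sizes`, `n_init`, `seed`.
#' @export
cluster_cross_sectional <- function(X, k, n_init = 50L, seed,
                                    extra_centers = NULL) {
  X <- as.matrix(X)
  if (k > nrow(X)) stop("k exceeds the number of observations", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  inits <- c(.init_centers(X, k, n_init, seed), extra_centers)
  best <- NULL
  for (cen in inits) {
    fit <- .lloyd(X, cen)
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  .finish_model(best, k, n_init, seed, ids)
}

#' Longitudinal k-means on per-sow trajectories
#'
#' Clusters complete multi-day trajectories of ILR coordinates using the
#' joint Euclidean distance over the flattened day-by-coordinate array
#' (kml3d-style). By construction this is identical to
#' [cluster_cross_sectional()] applied to the flattened matrix under the
#' same seed protocol.
#'
#' @param trajs named list of numeric matrices (days x coordinates), all of
#'   identical dimension, one per sow.
#' @inheritParams cluster_cross_sectional
#' @return A `cluster_model`.
#' @export
cluster_longitudinal <- function(trajs, k, n_init = 50L, seed,
                                 extra_centers = NULL) {
  dims <- vapply(trajs, function(m) dim(as.matrix(m)), integer(2))
  if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L) {
    stop("ragged trajectories: all sows need the same days and coordinates",
         call. = FALSE)
  }
  X <- t(vapply(trajs, function(m) as.vector(t(as.matrix(m))),
                numeric(dims[1, 1] * dims[2, 1])))
  rownames(X) <- names(trajs)
  cluster_cross_sectional(X, k, n_init = n_init, seed = seed,
                          extra_centers = extra_centers)
}

#' Fit a sweep of k values with nested initialization
#'
#' Fits k-means for each k in `ks`; for k > min(ks) the restart pool is
#' augmented with the previous best solution's centers plus the point
#' farthest from its assigned center, which guarantees the inertia profile
#' is non-increasing in k.
#'
#' @param X coordinate matrix (or flattened trajectories).
#' @param ks consecutive integer vector of cluster numbers.
#' @inheritParams cluster_cross_sectional
#' @return Named list of `cluster_model`s; names are the k values.
#' @export
cluster_sweep <- function(X, ks = 1:6, n_init = 50L, seed) {
  X <- as.matrix(X)
  ks <- sort(ks)
  out <- list()
  prev <- NULL
  for (k in ks) {
    extra <- NULL
    if (!is.null(prev) && k == prev$k + 1L) {
      lab <- prev$assignments
      cen_of <- prev$centers[lab, , drop = FALSE]
      d2 <- rowSums((X - cen_of)^2)
      far <- X[which.max(d2), , drop = FALSE]
      cand <- rbind(prev$centers, far)
      if (nrow(unique(cand)) == k) extra <- list(unname(cand))
    }
    m <- cluster_cross_sectional(X, k, n_init = n_init, seed = seed + k,
                                 extra_centers = extra)
    out[[as.character(k)]] <- m
    prev <- m
  }
  out
}

#' Elbow rule for the number of clusters
#'
#' Given within-cluster inertias for consecutive k, returns the interior k
#' maximizing the second difference
#' (I\[k-1\] - I\[k\]) - (I\[k\] - I\[k+1\]), i.e. the sharpest bend of the
#' inertia profile; ties are broken toward the smaller k.
#'
#' @param inertias named numeric vector, names = consecutive integer k,
#'   at least 3 values.
#' @return The selected k (integer).
#' @export
elbow_select_k <- function(inertias) {
  ks <- as.integer(names(inertias))
  if (length(ks) < 3L) stop("need inertias for at least 3 consecutive k",
                            call. = FALSE)
  o <- order(ks)
  ks <- ks[o]; inertias <- as.numeric(inertias[o])
  if (any(diff(ks) != 1L)) stop("k values must be consecutive", call. = FALSE)
  interior <- 2:(length(ks) - 1L)
  d2 <- (inertias[interior - 1L] - inertias[interior]) -
    (inertias[interior] - inertias[interior + 1L])
  ks[interior[which.max(d2)]]
}
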