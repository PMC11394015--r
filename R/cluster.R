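#' Clustering parameters for HDBSCAN
#'
#' @param min_cluster_size Smallest allowed cluster (>= 2). Default 100, the
#'   value used for AZ extraction.
#' @param min_samples Neighbourhood size k for core distances (>= 1).
#'   Default 25.
#' @return A `clustering_params` list.
#' @export
clustering_params <- function(min_cluster_size = 100L, min_samples = 25L) {
  min_cluster_size <- as.integer(min_cluster_size)
  min_samples <- as.integer(min_samples)
  stopifnot(min_cluster_size >= 2, min_samples >= 1)
  structure(list(min_cluster_size = min_cluster_size,
                 min_samples = min_samples),
            class = "clustering_params")
}

# core distance of each point: distance to its min_samples-th nearest
# neighbour counting the point itself (so min_samples = 1 gives 0)
.core_distances <- function(xy, min_samples) {
  n <- nrow(xy)
  k <- min(min_samples - 1L, n - 1L)
  if (k < 1L) return(rep(0, n))
  FNN::knn.dist(xy, k = k)[, k]
}

#' HDBSCAN clustering of 2D points
#'
#' Hierarchical density-based clustering with noise: core distances from the
#' `min_samples`-nearest neighbour (counting the point itself), minimum
#' spanning tree of the mutual-reachability graph, condensed cluster tree at
#' `min_cluster_size`, and excess-of-mass cluster selection. The root is never
#' selected, so a structureless point set yields no clusters. Output is
#' deterministic for a fixed input.
#'
#' @param xy n x 2 numeric matrix (nm).
#' @param params A [clustering_params()].
#' @return Integer vector of cluster labels (1, 2, ...), `NA` for noise.
#' @export
hdbscan_points <- function(xy, params = clustering_params()) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < params$min_cluster_size) {
    warning("fewer points (", n, ") than min_cluster_size (",
            params$min_cluster_size, "); no clusters")
    return(rep(NA_integer_, n))
  }
  core <- .core_distances(xy, params$min_samples)
  mst <- prim_mutual_reachability_mst(xy[, 1], xy[, 2], core)
  hdbscan_labels_from_mst(mst$from, mst$to, mst$weight, n,
                          params$min_cluster_size)
}

#' Extract clusters from a localization table
#'
#' Runs HDBSCAN on the (x, y) coordinates only (frame and intensity are not
#' used for clustering) and packages the result as a list of clusters. At
#' level `"AZ"` the defaults (100, 25) extract active zones; at level `"SC"`
#' pass dye-calibrated parameters.
#'
#' @param table A [loc_table()].
#' @param params A [clustering_params()].
#' @param level `"AZ"` or `"SC"`.
#' @return An `az_clusters` object: list with `labels` (per-row labels, NA =
#'   noise), `clusters` (list of integer index vectors into `table`), `level`,
#'   `params`, `selection_method = "excess_of_mass"`.
#' @export
cluster_localizations <- function(table, params = clustering_params(),
                                  level = c("AZ", "SC")) {
  level <- match.arg(level)
  labels <- hdbscan_points(cbind(table$x, table$y), params)
  ids <- sort(unique(labels[!is.na(labels)]))
  clusters <- lapply(ids, function(l) which(labels == l))
  names(clusters) <- ids
  structure(list(labels = labels, clusters = clusters, level = level,
                 params = params, selection_method = "excess_of_mass"),
            class = "az_clusters")
}

#' @export
print.az_clusters <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("%s-level HDBSCAN (mcs = %d, ms = %d): %d clusters, %d noise points\n",
              x$level, x$params$min_cluster_size, x$params$min_samples,
              length(x$clusters), sum(is.na(x$labels))))
  if (length(sizes))
    cat(sprintf("  cluster sizes: median %d, range %d-%d\n",
                as.integer(stats::median(sizes)), min(sizes), max(sizes)))
  invisible(x)
}

#' The published HDBSCAN sweep grids
#'
#' Minimum cluster size: 10-90 in steps of 10 plus 100-500 in steps of 100;
#' minimum samples: 2, 5-25 in steps of 5, and 30-100 in steps of 10.
#'
#' @return List with integer vectors `min_cluster_size`, `min_samples`.
#' @export
sweep_grids <- function() {
  list(min_cluster_size = c(seq(10L, 90L, 10L), seq(100L, 500L, 100L)),
       min_samples = c(2L, seq(5L, 25L, 5L), seq(30L, 100L, 10L)))
}

#' Sweep HDBSCAN parameters over images
#'
#' Evaluates every (min_cluster_size, min_samples) combination of the grids on
#' each table and reports the median AZ count per image, the robustness
#' diagnostic used to choose the final clustering parameters. Counts are of
#' raw clusters (before area filtering). The mutual-reachability MST is reused
#' across `min_cluster_size` values at fixed `min_samples`.
#'
#' @param tables List of [loc_table()]s (one per image).
#' @param grids List with `min_cluster_size` and `min_samples` vectors;
#'   default [sweep_grids()].
#' @return A `sweep_result`: list with `median_az_count` (matrix mcs x ms),
#'   `counts` (per-image 3D array), and the grids.
#' @export
parameter_sweep <- function(tables, grids = sweep_grids()) {
  stopifnot(length(tables) >= 1)
  mcs <- as.integer(grids$min_cluster_size)
  ms <- as.integer(grids$min_samples)
  counts <- array(0L, dim = c(length(mcs), length(ms), length(tables)),
                  dimnames = list(mcs, ms, NULL))
  for (ti in seq_along(tables)) {
    xy <- cbind(tables[[ti]]$x, tables[[ti]]$y)
    n <- nrow(xy)
    for (mi in seq_along(ms)) {
      if (n < 2) next
      core <- .core_distances(xy, ms[mi])
      mst <- prim_mutual_reachability_mst(xy[, 1], xy[, 2], core)
      for (ci in seq_along(mcs)) {
        if (n < mcs[ci]) { counts[ci, mi, ti] <- 0L; next }
        lab <- hdbscan_labels_from_mst(mst$from, mst$to, mst$weight, n, mcs[ci])
        counts[ci, mi, ti] <- length(unique(lab[!is.na(lab)]))
      }
    }
  }
  med <- apply(counts, c(1, 2), stats::median)
  structure(list(median_az_count = med, counts = counts,
                 min_cluster_size = mcs, min_samples = ms),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("HDBSCAN parameter sweep: %d x %d combinations over %d image(s)\n",
              length(x$min_cluster_size), length(x$min_samples),
              dim(x$counts)[3]))
  invisible(x)
}

#' Contour plot of a parameter sweep
#' @param x A `sweep_result`.
#' @param ... Passed to [graphics::contour()].
#' @method plot sweep_result
#' @export
plot.sweep_result <- function(x, ...) {
  graphics::contour(x$min_cluster_size, x$min_samples, x$median_az_count,
                    xlab = "minimum cluster size", ylab = "minimum samples",
                    main = "median AZ count per image", ...)
  invisible(x)
}
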