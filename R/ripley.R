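#' Ripley's K, L and H functions without edge correction
#'
#' For one AZ's points, \eqn{K(r) = A \sum_{i \ne j} 1(d_{ij} \le r) / (n(n-1))},
#' \eqn{L(r) = \sqrt{K(r)/\pi}}, \eqn{H(r) = L(r) - r}. No edge correction is
#' applied. For a homogeneous Poisson pattern observed on area A, H(r) is
#' approximately 0; a positive peak of H indicates clustering with a
#' characteristic radius near the peak location.
#'
#' @param points n x 2 matrix of coordinates (nm), n >= 2.
#' @param r Radius grid (nm), default 0-150 nm in 1 nm steps.
#' @param area Reference area A (nm^2) of the pattern's support, e.g. the
#'   AZ's alpha-shape area.
#' @param normalization `"ordered-pairs"` divides by n(n-1) (default);
#'   `"n-squared"` divides by n^2.
#' @param focal Optional integer indices of focal points. When given, the
#'   border-method (minus-sampling) estimator is used: neighbours are counted
#'   from the focal points to all points, and `area` must be the area of the
#'   full observation window. Use focal points at least `max(r)` away from
#'   the window edge to obtain an unbiased K for patterns extending beyond
#'   the focal region (the construction used for Poisson null calibration).
#' @return An `h_curve`: list with `r`, `K`, `L`, `H`, `n`, `area`.
#' @export
ripley_h <- function(points, r = 0:150, area,
                     normalization = c("ordered-pairs", "n-squared"),
                     focal = NULL) {
  normalization <- match.arg(normalization)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 2) stop("Ripley's K undefined for fewer than 2 points")
  stopifnot(area > 0, all(r >= 0))
  if (is.null(focal)) {
    cnt <- ripley_k_counts(points[, 1], points[, 2], as.numeric(r))
    denom <- if (normalization == "ordered-pairs") n * (n - 1) else n^2
  } else {
    focal <- as.integer(focal)
    stopifnot(all(focal >= 1), all(focal <= n), length(focal) >= 1)
    cnt <- ripley_k_counts_focal(points[, 1], points[, 2], focal - 1L,
                                 as.numeric(r))
    denom <- if (normalization == "ordered-pairs")
      length(focal) * (n - 1) else length(focal) * n
  }
  K <- area * cnt / denom
  L <- sqrt(K / pi)
  structure(list(r = as.numeric(r), K = K, L = L, H = L - r, n = n,
                 area = area, normalization = normalization),
            class = "h_curve")
}

#' @export
print.h_curve <- function(x, ...) {
  i <- which.max(x$H)
  cat(sprintf("H curve on %d points (A = %.3g nm^2): max H = %.2f nm at r = %g nm\n",
              x$n, x$area, x$H[i], x$r[i]))
  invisible(x)
}

#' @method plot h_curve
#' @export
plot.h_curve <- function(x, ...) {
  graphics::plot(x$r, x$H, type = "l", xlab = "r (nm)", ylab = "H(r) (nm)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Average H curves and locate the maximum
#'
#' Pointwise mean of per-AZ H functions on a common radius grid; the radius of
#' the mean curve's maximum indicates the characteristic subcluster radius.
#' Ties are broken toward the smaller radius.
#'
#' @param curves List of `h_curve` objects sharing the same `r` grid.
#' @return List with `mean_curve` (an `h_curve` with `n` = number of curves),
#'   `h_max_radius` (nm), `h_max` (nm), `tie` (TRUE if the maximum is not
#'   unique).
#' @export
average_h_and_max <- function(curves) {
  stopifnot(length(curves) >= 1)
  r <- curves[[1]]$r
  for (cu in curves)
    if (!isTRUE(all.equal(cu$r, r))) stop("curves must share one radius grid")
  Hm <- rowMeans(vapply(curves, function(cu) cu$H, numeric(length(r))))
  Km <- rowMeans(vapply(curves, function(cu) cu$K, numeric(length(r))))
  imax <- which(Hm == max(Hm))
  mean_curve <- structure(list(r = r, K = Km, L = Hm + r, H = Hm,
                               n = length(curves), area = NA_real_,
                               normalization = curves[[1]]$normalization),
                          class = "h_curve")
  list(mean_curve = mean_curve, h_max_radius = r[imax[1]], h_max = Hm[imax[1]],
       tie = length(imax) > 1)
}

#' Second-level clustering: subclusters within one AZ
#'
#' Runs HDBSCAN with SC-level parameters on the members of one AZ and
#' measures each subcluster's alpha-shape area at a fixed alpha (default
#' 300 nm^2 for all dyes) and its equivalent-circle radius
#' \eqn{\sqrt{area/\pi}}.
#'
#' @param az_points n x 2 matrix: coordinates of one AZ's localizations (nm).
#' @param params SC-level [clustering_params()], e.g. (22, 5) for AF647,
#'   (44, 11) for CF568, (15, 3) for CF583R.
#' @param sc_alpha Alpha (nm^2) for SC areas, default 300.
#' @return A data.frame with one row per SC: `sc_id`, `n_localizations`,
#'   `area_nm2`, `radius_nm`; 0 rows when the AZ yields no SC.
#' @export
subcluster <- function(az_points, params, sc_alpha = 300) {
  az_points <- as.matrix(az_points)
  empty <- data.frame(sc_id = integer(0), n_localizations = integer(0),
                      area_nm2 = numeric(0), radius_nm = numeric(0))
  if (nrow(az_points) < params$min_cluster_size) return(empty)
  labels <- suppressWarnings(hdbscan_points(az_points, params))
  ids <- sort(unique(labels[!is.na(labels)]))
  if (length(ids) == 0) return(empty)
  out <- lapply(seq_along(ids), function(i) {
    idx <- which(labels == ids[i])
    a <- alpha_shape_area(az_points[idx, , drop = FALSE], sc_alpha)$area
    data.frame(sc_id = i, n_localizations = length(idx), area_nm2 = a,
               radius_nm = sqrt(a / pi))
  })
  do.call(rbind, out)
}

#' Subcluster all AZs of an image
#'
#' @param az_list List of n x 2 matrices (one per AZ).
#' @param params SC-level [clustering_params()].
#' @param sc_alpha Alpha (nm^2) for SC areas, default 300.
#' @return A data.frame with columns `az_id`, `sc_id`, `n_localizations`,
#'   `area_nm2`, `radius_nm`.
#' @export
subcluster_all <- function(az_list, params, sc_alpha = 300) {
  out <- lapply(seq_along(az_list), function(a) {
    sc <- subcluster(az_list[[a]], params, sc_alpha)
    if (nrow(sc)) cbind(az_id = a, sc) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(az_id = integer(0), sc_id = integer(0),
                      n_localizations = integer(0), area_nm2 = numeric(0),
                      radius_nm = numeric(0))
  out
}

#' Calibrate SC-level clustering parameters to a target radius
#'
#' Grid search over (min_cluster_size, min_samples) pairs choosing the pair
#' whose median equivalent-circle SC radius over all AZs is closest to
#' `target_radius` (typically the H-function maximum). Ties are broken toward
#' the smaller min_cluster_size, then the smaller min_samples. Per AZ and
#' min_samples, the mutual-reachability MST is computed once and reused
#' across min_cluster_size values.
#'
#' @param az_list List of n x 2 matrices (one per AZ).
#' @param target_radius Target median SC radius (nm), > 0.
#' @param mcs_grid Candidate minimum cluster sizes; default 3-60.
#' @param ms_grid Candidate minimum samples; default 2-60 (pairs with
#'   `ms > mcs` are skipped).
#' @param sc_alpha Alpha (nm^2) for SC areas, default 300.
#' @return A `calibration` list: `params` (the winning
#'   [clustering_params()]), `achieved_radius`, `target_radius`, and `table`
#'   (every evaluated pair with its median radius and SC count).
#' @export
calibrate_sc_params <- function(az_list, target_radius,
                                mcs_grid = 3:60, ms_grid = 2:60,
                                sc_alpha = 300) {
  stopifnot(target_radius > 0, length(az_list) >= 1)
  az_list <- lapply(az_list, as.matrix)
  rows <- list(); ri <- 0L
  for (ms in sort(unique(as.integer(ms_grid)))) {
    # per-AZ MST reused over min_cluster_size
    msts <- lapply(az_list, function(p) {
      if (nrow(p) < 2) return(NULL)
      core <- .core_distances(p, ms)
      prim_mutual_reachability_mst(p[, 1], p[, 2], core)
    })
    for (mcs in sort(unique(as.integer(mcs_grid)))) {
      if (ms > mcs) next
      radii <- numeric(0); nsc <- 0L
      for (a in seq_along(az_list)) {
        p <- az_list[[a]]
        if (is.null(msts[[a]]) || nrow(p) < mcs) next
        lab <- hdbscan_labels_from_mst(msts[[a]]$from, msts[[a]]$to,
                                       msts[[a]]$weight, nrow(p), mcs)
        for (l in unique(lab[!is.na(lab)])) {
          ar <- alpha_shape_area(p[which(lab == l), , drop = FALSE],
                                 sc_alpha)$area
          radii <- c(radii, sqrt(ar / pi))
          nsc <- nsc + 1L
        }
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(min_cluster_size = mcs, min_samples = ms,
                               n_sc = nsc,
                               median_radius = if (nsc > 0)
                                 stats::median(radii) else NA_real_)
    }
  }
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$median_radius)
  if (!any(ok))
    stop("no (min_cluster_size, min_samples) pair yielded any subcluster; ",
         "evaluated ", nrow(tab), " pairs on ", length(az_list), " AZ(s)")
  cand <- tab[ok, ]
  dev <- abs(cand$median_radius - target_radius)
  ord <- order(dev, cand$min_cluster_size, cand$min_samples)
  best <- cand[ord[1], ]
  structure(list(params = clustering_params(best$min_cluster_size,
                                            best$min_samples),
                 achieved_radius = best$median_radius,
                 target_radius = target_radius, table = tab),
            class = "sc_calibration")
}

#' @export
print.sc_calibration <- function(x, ...) {
  cat(sprintf(paste0("SC calibration: mcs = %d, ms = %d; median radius ",
                     "%.1f nm (target %.1f nm)\n"),
              x$params$min_cluster_size, x$params$min_samples,
              x$achieved_radius, x$target_radius))
  invisible(x)
}
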