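# Delaunay triangles of a 2D point set with per-triangle area and squared
# circumradius. Returns a list (i, j, k, area, circum2, points = the
# de-duplicated coordinates the indices refer to) or NULL when no
# triangulation exists (< 3 unique points, collinear sets, ...).
.delaunay_triangles <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) return(NULL)
  up <- unique(points)
  if (nrow(up) < 3) return(NULL)
  tm <- try(suppressWarnings(
    interp::tri.mesh(up[, 1], up[, 2], duplicate = "remove")), silent = TRUE)
  if (inherits(tm, "try-error")) return(NULL)
  tr <- try(interp::triangles(tm), silent = TRUE)
  if (inherits(tr, "try-error") || nrow(tr) == 0) return(NULL)
  i <- tr[, "node1"]; j <- tr[, "node2"]; k <- tr[, "node3"]
  ax <- up[i, 1]; ay <- up[i, 2]
  bx <- up[j, 1]; by <- up[j, 2]
  cx <- up[k, 1]; cy <- up[k, 2]
  area <- abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) / 2
  a2 <- (bx - cx)^2 + (by - cy)^2
  b2 <- (ax - cx)^2 + (ay - cy)^2
  c2 <- (ax - bx)^2 + (ay - by)^2
  circum2 <- ifelse(area > 0, a2 * b2 * c2 / (16 * area^2), Inf)
  list(i = i, j = j, k = k, area = area, circum2 = circum2, points = up)
}

#' Area of the 2D alpha shape of a point set
#'
#' Delaunay triangulation, keeping triangles whose squared circumradius is at
#' most `alpha` (so `alpha` has units of nm^2, the convention
#' `alpha = x^2 nm^2`); the area is the summed area of kept triangles and the
#' boundary is the set of edges bordering exactly one kept triangle.
#' Degenerate inputs (fewer than 3 distinct points, collinear sets, no kept
#' triangle) give area 0, never an error.
#'
#' @param points n x 2 matrix of coordinates (nm).
#' @param alpha Squared-circumradius threshold (nm^2), > 0; `Inf` gives the
#'   convex hull.
#' @return List with `area` (nm^2) and `boundary` (m x 4 matrix of boundary
#'   segment endpoints x0, y0, x1, y1; may have 0 rows).
#' @export
alpha_shape_area <- function(points, alpha) {
  stopifnot(alpha > 0)
  tri <- .delaunay_triangles(points)
  empty <- list(area = 0,
                boundary = matrix(numeric(0), 0, 4,
                                  dimnames = list(NULL, c("x0", "y0", "x1", "y1"))))
  if (is.null(tri)) return(empty)
  keep <- tri$circum2 <= alpha
  if (!any(keep)) return(empty)
  # boundary: edges used by exactly one kept triangle
  up <- tri$points
  i <- tri$i[keep]; j <- tri$j[keep]; k <- tri$k[keep]
  a <- c(i, j, k); b <- c(j, k, i)
  e <- cbind(pmin(a, b), pmax(a, b))
  key <- e[, 1] * (nrow(up) + 1) + e[, 2]
  once <- !(duplicated(key) | duplicated(key, fromLast = TRUE))
  eb <- e[once, , drop = FALSE]
  boundary <- cbind(up[eb[, 1], 1], up[eb[, 1], 2],
                    up[eb[, 2], 1], up[eb[, 2], 2])
  colnames(boundary) <- c("x0", "y0", "x1", "y1")
  list(area = sum(tri$area[keep]), boundary = boundary)
}

#' The published alpha sweep grid
#'
#' `alpha = x^2` nm^2 for x from 5 to 200 nm in steps of 5.
#' @return Numeric vector of alpha values (nm^2), strictly increasing.
#' @export
alpha_grid <- function() seq(5, 200, by = 5)^2

#' Select the alpha parameter by the plateau rule
#'
#' For every alpha on the grid, the median AZ area over all supplied AZ point
#' sets is computed; the selected alpha is the first grid value at which the
#' percentage increase of the median area relative to the previous grid value
#' falls below `threshold` (default 5%). Delaunay triangulations are computed
#' once per AZ and reused across the grid.
#'
#' @param az_points List of n x 2 matrices, one per AZ.
#' @param grid Increasing alpha values (nm^2); default [alpha_grid()].
#' @param threshold Percent-increase threshold, default 5.
#' @return An `alpha_curve`: data.frame-backed list with `grid`,
#'   `median_area`, `q25_area`, `q75_area`, `pct_increase` (NA at the first
#'   grid point) and `selected_alpha`.
#' @export
select_alpha <- function(az_points, grid = alpha_grid(), threshold = 5) {
  stopifnot(length(az_points) >= 1, length(grid) >= 2, all(diff(grid) > 0))
  tris <- lapply(az_points, .delaunay_triangles)
  areas <- vapply(tris, function(tr) {
    if (is.null(tr)) return(rep(0, length(grid)))
    # monotone in alpha by construction: cumulative area over sorted circum2
    o <- order(tr$circum2)
    cum <- cumsum(tr$area[o])
    idx <- findInterval(grid, tr$circum2[o])
    ifelse(idx > 0, cum[pmax(idx, 1)], 0)
  }, numeric(length(grid)))
  if (is.null(dim(areas))) areas <- matrix(areas, nrow = length(grid))
  med <- apply(areas, 1, stats::median)
  q25 <- apply(areas, 1, stats::quantile, probs = 0.25, names = FALSE)
  q75 <- apply(areas, 1, stats::quantile, probs = 0.75, names = FALSE)
  sel <- select_alpha_from_curve(med, grid, threshold)
  structure(list(grid = grid, median_area = med, q25_area = q25,
                 q75_area = q75, pct_increase = sel$pct_increase,
                 selected_alpha = sel$selected_alpha, threshold = threshold),
            class = "alpha_curve")
}

#' The plateau selection rule on a precomputed area curve
#'
#' Percent increase at grid step k is
#' `100 * (median_k - median_{k-1}) / median_{k-1}`; the selected alpha is the
#' first grid value whose increase falls below `threshold`. A constant
#' positive curve selects the second grid value (the first computable step,
#' 0% increase). Steps whose previous median is zero are not computable: a
#' jump from zero counts as an infinite increase and a zero-to-zero step is
#' skipped, so the rule never selects an alpha at which the shape is still
#' empty.
#'
#' @param median_areas Median area at each grid value (non-decreasing).
#' @param grid Increasing alpha values (nm^2), same length.
#' @param threshold Percent threshold, default 5.
#' @return List with `selected_alpha`, `selected_index`, `pct_increase`
#'   (NA at the first grid point).
#' @export
select_alpha_from_curve <- function(median_areas, grid, threshold = 5) {
  stopifnot(length(median_areas) == length(grid), length(grid) >= 2)
  med <- as.numeric(median_areas)
  prev <- utils::head(med, -1)
  inc <- diff(med)
  pct <- c(NA_real_, ifelse(prev > 0, 100 * inc / prev,
                            ifelse(inc == 0, NA_real_, Inf)))
  below <- which(!is.na(pct) & pct < threshold)
  if (length(below) == 0)
    stop("no alpha step fell below ", threshold,
         "% area increase; curve medians: ",
         paste(signif(med, 4), collapse = ", "))
  list(selected_alpha = grid[below[1]], selected_index = below[1],
       pct_increase = pct)
}

#' @export
print.alpha_curve <- function(x, ...) {
  cat(sprintf("Alpha selection: alpha = %g nm^2 (x = %g nm), threshold %g%%\n",
              x$selected_alpha, sqrt(x$selected_alpha), x$threshold))
  invisible(x)
}

#' Plot the alpha curve (median area and percent increase vs alpha)
#' @param x An `alpha_curve`.
#' @param ... Passed to plot.
#' @method plot alpha_curve
#' @export
plot.alpha_curve <- function(x, ...) {
  op <- graphics::par(mar = c(5, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(x$grid, x$median_area / 1e6, type = "b", pch = 16, log = "x",
                 xlab = expression(alpha ~ (nm^2)),
                 ylab = expression("median AZ area" ~ (mu * m^2)), ...)
  graphics::arrows(x$grid, x$q25_area / 1e6, x$grid, x$q75_area / 1e6,
                   length = 0.02, angle = 90, code = 3, col = "magenta")
  graphics::abline(v = x$selected_alpha, lty = 2)
  graphics::par(new = TRUE)
  graphics::plot(x$grid[-1], x$pct_increase[-1], type = "b", col = "blue",
                 pch = 1, log = "x", axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, col.axis = "blue")
  graphics::mtext("% area increase per step", side = 4, line = 2.5,
                  col = "blue")
  invisible(x)
}

#' Per-AZ morphometry records
#'
#' Computes per-cluster localization counts and alpha-shape areas, and marks
#' which AZs pass the area window.
#'
#' @param clusters An `az_clusters` from [cluster_localizations()].
#' @param table The clustered [loc_table()].
#' @param alpha Alpha value (nm^2) for area computation.
#' @param area_window_um2 Exclusion window: AZs with area <= lower or >= upper
#'   (in um^2) are dropped. Default `c(0.03, 0.3)`.
#' @return An `az_records` data.frame: `az_id`, `n_localizations`,
#'   `area_um2`, `kept`.
#' @export
az_summary <- function(clusters, table, alpha,
                       area_window_um2 = c(0.03, 0.3)) {
  if (length(clusters$clusters) == 0) {
    return(structure(data.frame(az_id = integer(0),
                                n_localizations = integer(0),
                                area_um2 = numeric(0), kept = logical(0)),
                     class = c("az_records", "data.frame")))
  }
  recs <- lapply(seq_along(clusters$clusters), function(i) {
    idx <- clusters$clusters[[i]]
    a <- alpha_shape_area(cbind(table$x[idx], table$y[idx]), alpha)$area
    data.frame(az_id = i, n_localizations = length(idx), area_um2 = a / 1e6)
  })
  out <- do.call(rbind, recs)
  out$kept <- out$area_um2 > area_window_um2[1] & out$area_um2 < area_window_um2[2]
  structure(out, class = c("az_records", "data.frame"))
}

#' Apply the AZ area exclusion window
#'
#' Exclusion is by closed bounds: areas `<= lower` or `>= upper` are dropped,
#' i.e. kept iff `lower < area < upper` (strict). A pure predicate: applying
#' it twice equals applying it once.
#'
#' @param records An `az_records` data.frame with column `area_um2`.
#' @param window Lower/upper bounds in um^2, default `c(0.03, 0.3)`.
#' @return The records with `kept` recomputed and excluded rows dropped.
#' @export
apply_area_filter <- function(records, window = c(0.03, 0.3)) {
  kept <- records$area_um2 > window[1] & records$area_um2 < window[2]
  records$kept <- kept
  out <- records[kept, , drop = FALSE]
  structure(out, class = c("az_records", "data.frame"))
}
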