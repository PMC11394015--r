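#' Construct a set of polygonal regions of interest
#'
#' ROIs delimit presynaptic boutons in the rendered image; at most `max_count`
#' polygons are analysed per image (default 6, matching the limit of terminal
#' type Ib boutons considered per NMJ image).
#'
#' @param polygons List of n x 2 matrices of vertices (nm); polygons are
#'   closed implicitly and must be simple with >= 3 vertices.
#' @param max_count Maximum number of polygons allowed.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(polygons, max_count = 6L) {
  if (length(polygons) > max_count)
    stop(sprintf("ROI set has %d polygons; at most %d allowed",
                 length(polygons), max_count))
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 3)
      stop("each ROI polygon needs an n x 2 matrix with >= 3 vertices")
    storage.mode(p) <- "double"
    if (.polygon_self_intersects(p)) stop("ROI polygon is self-intersecting")
    p
  })
  structure(list(polygons = polygons, max_count = as.integer(max_count)),
            class = "roi_set")
}

# brute segment-pair check; fine for hand-drawn ROIs (tens of vertices)
.polygon_self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), ])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]  # skip adjacent (shared-vertex) pairs
    for (j in js) {
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- cross(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- cross(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- cross(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0) != (d2 > 0)) && ((d3 > 0) != (d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Read ROI polygons from CSV
#'
#' Expects columns `roi` (polygon id), `x`, `y` (vertex coordinates in nm),
#' one vertex per row, vertices of each polygon contiguous and in order.
#'
#' @param path CSV path.
#' @param max_count Maximum polygons allowed (default 6).
#' @return A [roi_set()].
#' @export
read_rois <- function(path, max_count = 6L) {
  df <- utils::read.csv(path)
  for (need in c("roi", "x", "y"))
    if (!need %in% names(df)) stop("ROI file missing column '", need, "'")
  polys <- lapply(split(df[c("x", "y")], df$roi), as.matrix)
  roi_set(unname(polys), max_count = max_count)
}

#' Write ROI polygons to CSV
#' @param rois A [roi_set()].
#' @param path Output path.
#' @export
write_rois <- function(rois, path) {
  df <- do.call(rbind, lapply(seq_along(rois$polygons), function(i) {
    p <- rois$polygons[[i]]
    data.frame(roi = i, x = p[, 1], y = p[, 2])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Crop a localization table to ROI polygons
#'
#' Keeps localizations inside the union of the ROI polygons; points exactly on
#' a polygon boundary (edge or vertex) count as inside.
#'
#' @param table A [loc_table()].
#' @param rois A [roi_set()].
#' @return The cropped [loc_table()].
#' @export
crop_to_rois <- function(table, rois) {
  stopifnot(inherits(rois, "roi_set"))
  if (nrow(table) == 0) return(table)
  inside <- rep(FALSE, nrow(table))
  for (p in rois$polygons) {
    hit <- sp::point.in.polygon(table$x, table$y, p[, 1], p[, 2])
    inside <- inside | hit > 0  # 1 interior, 2 edge, 3 vertex
  }
  table[inside, , drop = FALSE]
}
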