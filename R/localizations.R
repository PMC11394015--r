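#' Construct a localization table
#'
#' The universal currency of the pipeline: one row per fitted single-molecule
#' localization, with planar coordinates in nanometres, the (0-based) camera
#' frame index and the fitted intensity in camera A/D counts.
#'
#' @param x,y Coordinates in nm (finite, >= 0). Origin at the top-left of the
#'   camera field, y increasing downward.
#' @param frame Integer frame indices, 0-based, each `< n_frames`.
#' @param intensity Fitted amplitude in camera A/D counts (positive).
#' @param n_frames Total number of acquisition frames. Defaults to
#'   `max(frame) + 1`.
#' @param source_id Image/specimen label carried through summaries.
#' @param extras Optional data.frame of additional per-localization columns,
#'   preserved opaquely through filtering operations.
#' @return A `loc_table`: a data.frame with columns `x`, `y`, `frame`,
#'   `intensity` (plus extras) and attributes `n_frames`, `source_id`.
#' @export
loc_table <- function(x, y, frame, intensity, n_frames = NULL,
                      source_id = "image", extras = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  frame <- as.integer(frame); intensity <- as.numeric(intensity)
  n <- length(x)
  if (length(y) != n || length(frame) != n || length(intensity) != n)
    stop("x, y, frame, intensity must have equal length")
  if (n > 0 && (!all(is.finite(x)) || !all(is.finite(y))))
    stop("all coordinates must be finite")
  if (is.null(n_frames)) n_frames <- if (n == 0) 0L else max(frame) + 1L
  n_frames <- as.integer(n_frames)
  if (n > 0 && (any(frame < 0L) || any(frame >= n_frames)))
    stop("frame indices must lie in [0, n_frames)")
  df <- data.frame(x = x, y = y, frame = frame, intensity = intensity)
  if (!is.null(extras)) {
    stopifnot(is.data.frame(extras), nrow(extras) == n)
    df <- cbind(df, extras)
  }
  structure(df, n_frames = n_frames, source_id = source_id,
            class = c("loc_table", "data.frame"))
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("Localization table '%s': %d localizations, %d frames\n",
              attr(x, "source_id"), nrow(x), attr(x, "n_frames")))
  if (nrow(x) > 0) {
    cat(sprintf("  x: %.1f-%.1f nm, y: %.1f-%.1f nm, intensity: %.0f-%.0f A/D\n",
                min(x$x), max(x$x), min(x$y), max(x$y),
                min(x$intensity), max(x$intensity)))
  }
  invisible(x)
}

# keep class + attributes through row subsetting
#' @export
`[.loc_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("x", "y", "frame", "intensity") %in% names(out))) {
    attr(out, "n_frames") <- attr(x, "n_frames")
    attr(out, "source_id") <- attr(x, "source_id")
    class(out) <- c("loc_table", "data.frame")
  }
  out
}

.rapidstorm_map <- c("Position-0-0" = "x", "Position-1-0" = "y",
                     "ImageNumber-0-0" = "frame", "Amplitude-0-0" = "intensity")

#' Read a localization table
#'
#' Supports two dialects: `"generic-csv"` (comma-separated with named columns
#' `x_nm`/`x`, `y_nm`/`y`, `frame`, `intensity`) and `"rapidstorm-txt"`
#' (whitespace-separated values preceded by a header comment naming the column
#' identities: `Position-0-0` = x in nm, `Position-1-0` = y in nm,
#' `ImageNumber-0-0` = frame, `Amplitude-0-0` = A/D count). Unknown columns are
#' preserved as opaque extras.
#'
#' @param path File path.
#' @param dialect `"generic-csv"` or `"rapidstorm-txt"`.
#' @param n_frames Total frames; defaults to `max(frame) + 1` on the data.
#' @param source_id Label for the image; defaults to the file name.
#' @return A [loc_table()].
#' @export
read_localizations <- function(path, dialect = c("generic-csv", "rapidstorm-txt"),
                               n_frames = NULL, source_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(source_id)) source_id <- basename(path)

  if (dialect == "generic-csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    nm <- names(df)
    pick <- function(cands, what) {
      hit <- intersect(cands, nm)
      if (length(hit) == 0)
        stop(sprintf("missing mandatory column '%s' (accepted names: %s)",
                     what, paste(cands, collapse = ", ")))
      hit[1]
    }
    cx <- pick(c("x_nm", "x"), "x")
    cy <- pick(c("y_nm", "y"), "y")
    cf <- pick("frame", "frame")
    ci <- pick(c("intensity", "adc"), "intensity")
    used <- c(cx, cy, cf, ci)
  } else {
    header <- readLines(path, n = 1L)
    if (!grepl("^#", header))
      stop("rapidstorm-txt requires a leading '#' header comment line")
    cols <- strsplit(sub("^#\\s*", "", header), "\\s+")[[1]]
    df <- utils::read.table(path, header = FALSE, skip = 1L,
                            col.names = cols, check.names = FALSE)
    names(df) <- cols
    for (need in names(.rapidstorm_map))
      if (!need %in% cols)
        stop("missing mandatory column '", need, "' in rapidSTORM header")
    nm <- names(df)
    cx <- "Position-0-0"; cy <- "Position-1-0"
    cf <- "ImageNumber-0-0"; ci <- "Amplitude-0-0"
    used <- c(cx, cy, cf, ci)
  }

  for (cc in used) {
    v <- df[[cc]]
    if (nrow(df) == 0) { df[[cc]] <- numeric(0); next }
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop(sprintf("non-numeric value in column '%s' at data line %d", cc,
                   if (is.na(bad)) NA_integer_ else bad))
    }
  }
  extras <- df[setdiff(nm, used)]
  if (ncol(extras) == 0) extras <- NULL
  loc_table(df[[cx]], df[[cy]], df[[cf]], df[[ci]],
            n_frames = n_frames, source_id = source_id, extras = extras)
}

#' Write a localization table
#'
#' Numeric fields are written with 17 significant digits so a write/read cycle
#' round-trips every double bit-identically.
#'
#' @param table A [loc_table()].
#' @param path Output path.
#' @param dialect `"generic-csv"` or `"rapidstorm-txt"`.
#' @export
write_localizations <- function(table, path,
                                dialect = c("generic-csv", "rapidstorm-txt")) {
  dialect <- match.arg(dialect)
  fmt <- function(v) {
    if (is.integer(v)) as.character(v) else sprintf("%.17g", v)
  }
  df <- as.data.frame(table)
  if (dialect == "generic-csv") {
    out <- df
    names(out)[match(c("x", "y"), names(out))] <- c("x_nm", "y_nm")
    body <- do.call(paste, c(lapply(out, fmt), sep = ","))
    writeLines(c(paste(names(out), collapse = ","), body), path)
  } else {
    rs_names <- names(.rapidstorm_map)[match(c("x", "y", "frame", "intensity"),
                                             .rapidstorm_map)]
    extras <- setdiff(names(df), c("x", "y", "frame", "intensity"))
    out <- df[c("x", "y", "frame", "intensity", extras)]
    header <- paste("#", paste(c(rs_names, extras), collapse = " "))
    body <- do.call(paste, c(lapply(out, fmt), sep = " "))
    writeLines(c(header, body), path)
  }
  invisible(path)
}

#' Filter localizations by minimum intensity
#'
#' Retains localizations whose A/D count is at least `min_adc` (inclusive).
#' The default per-dye thresholds are 3000 A/D for AF647 and 1000 A/D for
#' CF568/CF583R; see [dye_preset()].
#'
#' @param table A [loc_table()].
#' @param min_adc Inclusion threshold in A/D counts (>= 0).
#' @return The filtered [loc_table()], original order preserved.
#' @export
filter_min_intensity <- function(table, min_adc) {
  stopifnot(min_adc >= 0)
  table[table$intensity >= min_adc, , drop = FALSE]
}

#' Render a binned localization count image
#'
#' Pixel (i, j) (1-based row/column) counts localizations with
#' y in \[(i-1)p, ip) and x in \[(j-1)p, jp), half-open bins; the image total
#' equals the number of localizations.
#'
#' @param table A [loc_table()].
#' @param pixel_size_nm Pixel edge length p in nm (default 10).
#' @param field_size_nm Optional field extent (nm); defaults to covering the
#'   data.
#' @return Integer matrix of counts (rows = y bins, columns = x bins); a
#'   0 x 0 matrix for an empty table.
#' @export
render_binned_image <- function(table, pixel_size_nm = 10,
                                field_size_nm = NULL) {
  stopifnot(pixel_size_nm > 0)
  if (nrow(table) == 0) {
    if (is.null(field_size_nm)) return(matrix(0L, 0, 0))
    k <- ceiling(field_size_nm / pixel_size_nm)
    return(matrix(0L, k, k))
  }
  if (is.null(field_size_nm)) {
    nr <- floor(max(table$y) / pixel_size_nm) + 1L
    nc <- floor(max(table$x) / pixel_size_nm) + 1L
  } else {
    nr <- nc <- as.integer(ceiling(field_size_nm / pixel_size_nm))
  }
  i <- floor(table$y / pixel_size_nm) + 1L
  j <- floor(table$x / pixel_size_nm) + 1L
  keep <- i >= 1L & i <= nr & j >= 1L & j <= nc
  img <- matrix(0L, nr, nc)
  tab <- table(factor((j[keep] - 1L) * nr + i[keep], levels = seq_len(nr * nc)))
  img[] <- as.integer(tab)
  img
}

#' Write a binned image as 16-bit TIFF
#'
#' Counts above 65535 are clipped.
#'
#' @param img Integer count matrix from [render_binned_image()].
#' @param path Output .tif path.
#' @export
write_binned_tiff <- function(img, path) {
  m <- pmin(img, 65535L) / 65535
  tiff::writeTIFF(m, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Per-image summary quantities
#'
#' Mean brightness (A/D counts) and the number of localizations captured per
#' 100 camera frames, computed on the (already ROI-cropped and
#' intensity-filtered) table.
#'
#' @param table A [loc_table()].
#' @return A one-row data.frame with `source_id`, `n_localizations`,
#'   `mean_brightness` (NA when empty) and `locs_per_100_frames`.
#' @export
image_summary <- function(table) {
  n <- nrow(table)
  nf <- attr(table, "n_frames")
  data.frame(
    source_id = attr(table, "source_id"),
    n_localizations = n,
    mean_brightness = if (n == 0) NA_real_ else mean(table$intensity),
    locs_per_100_frames = if (nf > 0) n / nf * 100 else 0,
    stringsAsFactors = FALSE
  )
}
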