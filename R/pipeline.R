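#' Pipeline configuration
#'
#' Collects every stage parameter of the per-dye workflow with defaults equal
#' to the published analysis constants: per-dye A/D thresholds (3000 for
#' AF647, 1000 for CF568/CF583R via the preset), AZ-level HDBSCAN (100, 25),
#' the alpha sweep x = 5..200 nm with the 5% plateau rule, the AZ area window
#' (0.03, 0.3) um^2, SC areas at alpha = 300 nm^2, and an H-function radius
#' grid of 0-150 nm.
#'
#' Input is either a set of localization files (`input_paths` + `dialect`,
#' optionally `roi_paths`) or simulated scenes (`simulate = TRUE`,
#' `n_images`); simulation draws per-image seeds from `seed`.
#'
#' @param preset Dye preset name (`"AF647"`, `"CF568"`, `"CF583R"`).
#' @param input_paths Character vector of localization table paths (one per
#'   image), or `NULL` to simulate.
#' @param dialect Input dialect for [read_localizations()].
#' @param roi_paths Optional ROI CSV paths parallel to `input_paths`.
#' @param simulate Generate input scenes instead of reading files.
#' @param n_images Number of simulated images.
#' @param n_az AZs per simulated image.
#' @param min_adc Intensity threshold override; default from the preset.
#' @param az_params AZ-level [clustering_params()].
#' @param alpha_values Alpha sweep grid (nm^2).
#' @param alpha_threshold Plateau threshold (percent).
#' @param area_window_um2 AZ area exclusion window (um^2).
#' @param r_grid H-function radius grid (nm).
#' @param sc_params SC-level [clustering_params()] or `NULL` to calibrate
#'   against the H maximum.
#' @param calibration_grids List with `mcs` and `ms` vectors for
#'   [calibrate_sc_params()].
#' @param sc_alpha Alpha (nm^2) for SC areas.
#' @param pixel_size_nm Rendered image pixel size (nm).
#' @param out_dir Output directory.
#' @param seed Master seed for all randomness.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preset = "AF647", input_paths = NULL,
                            dialect = "generic-csv", roi_paths = NULL,
                            simulate = is.null(input_paths), n_images = 3L,
                            n_az = 30L, min_adc = NULL,
                            az_params = clustering_params(100L, 25L),
                            alpha_values = alpha_grid(), alpha_threshold = 5,
                            area_window_um2 = c(0.03, 0.3), r_grid = 0:150,
                            sc_params = NULL,
                            calibration_grids = list(mcs = seq(4L, 60L, 4L),
                                                     ms = c(2L, 3L, 5L, 8L,
                                                            12L, 18L, 25L)),
                            sc_alpha = 300, pixel_size_nm = 10,
                            out_dir = tempfile("aznano-run-"), seed = 1L) {
  if (!simulate) {
    stopifnot(length(input_paths) >= 1)
    missing <- input_paths[!file.exists(input_paths)]
    if (length(missing)) stop("input files not found: ",
                              paste(missing, collapse = ", "))
    if (!is.null(roi_paths)) {
      stopifnot(length(roi_paths) == length(input_paths))
      bad <- roi_paths[!file.exists(roi_paths)]
      if (length(bad)) stop("ROI files not found: ", paste(bad, collapse = ", "))
    }
  }
  structure(list(preset = preset, input_paths = input_paths,
                 dialect = dialect, roi_paths = roi_paths,
                 simulate = simulate, n_images = as.integer(n_images),
                 n_az = as.integer(n_az), min_adc = min_adc,
                 az_params = az_params, alpha_values = alpha_values,
                 alpha_threshold = alpha_threshold,
                 area_window_um2 = area_window_um2, r_grid = r_grid,
                 sc_params = sc_params,
                 calibration_grids = calibration_grids, sc_alpha = sc_alpha,
                 pixel_size_nm = pixel_size_nm, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.write_csv_out <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full per-dye pipeline
#'
#' Stages: input (read or simulate) -> intensity/ROI filtering and image
#' summaries -> NeNA precision per image -> AZ-level HDBSCAN -> alpha-shape
#' morphometry (alpha selection, areas, area filter) -> nanocluster analysis
#' (per-AZ H functions, averaged maximum, SC calibration and second-level
#' clustering) -> report (per-AZ and per-image summary statistics). All stage
#' outputs are CSV files in `config$out_dir` plus a JSON manifest recording
#' parameters, seed, and output hashes; reruns with an identical config
#' produce byte-identical CSVs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the manifest and in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  preset <- dye_preset(config$preset)
  min_adc <- config$min_adc %||% preset$min_adc
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  outputs <- character(0)

  # -- stage 1: input ---------------------------------------------------------
  tables <- stage("input", {
    if (config$simulate) {
      lapply(seq_len(config$n_images), function(i) {
        cfg <- scene_config(n_az = config$n_az,
                            seed = config$seed * 1000L + i)
        simulate_scene(cfg, preset)$locs
      })
    } else {
      lapply(seq_along(config$input_paths), function(i) {
        tb <- read_localizations(config$input_paths[i], config$dialect)
        if (!is.null(config$roi_paths))
          tb <- crop_to_rois(tb, read_rois(config$roi_paths[i]))
        tb
      })
    }
  })

  # -- stage 2: filter + image summaries -------------------------------------
  tables <- stage("filter", lapply(tables, filter_min_intensity,
                                   min_adc = min_adc))
  res_filter <- do.call(rbind, lapply(tables, image_summary))
  outputs <- c(outputs, .write_csv_out(res_filter, config$out_dir,
                                       "image_summary.csv"))

  # -- stage 3: precision -----------------------------------------------------
  res_nena <- stage("precision", {
    do.call(rbind, lapply(tables, function(tb) {
      fit <- nena_precision(tb)
      data.frame(source_id = attr(tb, "source_id"), sigma_nm = fit$sigma,
                 n_distances = fit$n)
    }))
  })
  outputs <- c(outputs, .write_csv_out(res_nena, config$out_dir, "nena.csv"))

  # -- stage 4: segmentation --------------------------------------------------
  clusterings <- stage("segment", lapply(tables, cluster_localizations,
                                         params = config$az_params))
  assign_df <- do.call(rbind, lapply(seq_along(tables), function(i) {
    data.frame(image = i, x = tables[[i]]$x, y = tables[[i]]$y,
               frame = tables[[i]]$frame, intensity = tables[[i]]$intensity,
               az_label = clusterings[[i]]$labels)
  }))
  outputs <- c(outputs, .write_csv_out(assign_df, config$out_dir,
                                       "az_assignments.csv"))

  # -- stage 5: morphometry ---------------------------------------------------
  morpho <- stage("morphometry", {
    az_points <- unlist(lapply(seq_along(tables), function(i) {
      lapply(clusterings[[i]]$clusters, function(idx)
        cbind(tables[[i]]$x[idx], tables[[i]]$y[idx]))
    }), recursive = FALSE)
    if (length(az_points) == 0) stop("no AZ clusters found in any image")
    curve <- select_alpha(az_points, config$alpha_values,
                          config$alpha_threshold)
    recs <- do.call(rbind, lapply(seq_along(tables), function(i) {
      r <- az_summary(clusterings[[i]], tables[[i]], curve$selected_alpha,
                      config$area_window_um2)
      if (nrow(r)) cbind(image = i, r) else NULL
    }))
    list(curve = curve, records = recs, az_points = az_points)
  })
  curve_df <- data.frame(alpha_nm2 = morpho$curve$grid,
                         median_area_nm2 = morpho$curve$median_area,
                         q25_area_nm2 = morpho$curve$q25_area,
                         q75_area_nm2 = morpho$curve$q75_area,
                         pct_increase = morpho$curve$pct_increase)
  outputs <- c(outputs, .write_csv_out(curve_df, config$out_dir,
                                       "alpha_curve.csv"))
  outputs <- c(outputs, .write_csv_out(morpho$records, config$out_dir,
                                       "az_records.csv"))

  # -- stage 6: nanocluster ---------------------------------------------------
  nano <- stage("nanocluster", {
    kept <- morpho$records$kept
    kept_points <- list(); kept_areas <- numeric(0)
    az_i <- 0L
    for (i in seq_along(tables)) {
      for (k in seq_along(clusterings[[i]]$clusters)) {
        az_i <- az_i + 1L
        if (!morpho$records$kept[az_i]) next
        kept_points[[length(kept_points) + 1L]] <- morpho$az_points[[az_i]]
        kept_areas <- c(kept_areas, morpho$records$area_um2[az_i] * 1e6)
      }
    }
    if (length(kept_points) == 0) stop("no AZs pass the area filter")
    usable <- vapply(kept_points, nrow, 0L) >= 2
    n_dropped <- sum(!usable)
    curves <- lapply(which(usable), function(k)
      ripley_h(kept_points[[k]], config$r_grid, kept_areas[k]))
    avg <- average_h_and_max(curves)
    if (is.null(config$sc_params)) {
      cal <- calibrate_sc_params(kept_points, avg$h_max_radius,
                                 config$calibration_grids$mcs,
                                 config$calibration_grids$ms,
                                 config$sc_alpha)
      sc_params <- cal$params
    } else {
      cal <- NULL
      sc_params <- config$sc_params
    }
    sc <- subcluster_all(kept_points, sc_params, config$sc_alpha)
    list(mean_curve = avg, curves_used = sum(usable),
         curves_dropped = n_dropped, calibration = cal,
         sc_params = sc_params, sc = sc)
  })
  mean_h_df <- data.frame(r_nm = nano$mean_curve$mean_curve$r,
                          mean_H_nm = nano$mean_curve$mean_curve$H)
  outputs <- c(outputs, .write_csv_out(mean_h_df, config$out_dir,
                                       "mean_h.csv"))
  outputs <- c(outputs, .write_csv_out(nano$sc, config$out_dir,
                                       "sc_records.csv"))

  # -- stage 7: report --------------------------------------------------------
  report <- stage("report", {
    kept_rec <- morpho$records[morpho$records$kept, , drop = FALSE]
    sc_per_az <- if (nrow(nano$sc))
      as.numeric(table(factor(nano$sc$az_id,
                              levels = unique(nano$sc$az_id)))) else numeric(0)
    row_mq <- function(metric, v) {
      if (length(v) == 0)
        return(data.frame(metric = metric, n = 0L, median = NA_real_,
                          q25 = NA_real_, q75 = NA_real_))
      s <- summarize_mq(v)
      data.frame(metric = metric, n = length(v), median = s["median"],
                 q25 = s["q25"], q75 = s["q75"], row.names = NULL)
    }
    rbind(row_mq("nena_sigma_nm", res_nena$sigma_nm),
          row_mq("mean_brightness_adc", res_filter$mean_brightness),
          row_mq("locs_per_100_frames", res_filter$locs_per_100_frames),
          row_mq("locs_per_az", kept_rec$n_localizations),
          row_mq("az_area_um2", kept_rec$area_um2),
          row_mq("sc_per_az", sc_per_az),
          row_mq("sc_area_nm2", nano$sc$area_nm2),
          row_mq("sc_radius_nm", nano$sc$radius_nm))
  })
  outputs <- c(outputs, .write_csv_out(report, config$out_dir,
                                       "summary_stats.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("aznano")),
    seed = config$seed,
    preset = config$preset,
    min_adc = min_adc,
    inputs = if (config$simulate) list(simulated_images = config$n_images)
             else as.list(tools::md5sum(config$input_paths)),
    stages = c("input", "filter", "precision", "segment", "morphometry",
               "nanocluster", "report"),
    parameters = list(
      az_params = unclass(config$az_params),
      alpha_threshold = config$alpha_threshold,
      selected_alpha_nm2 = morpho$curve$selected_alpha,
      area_window_um2 = config$area_window_um2,
      sc_alpha_nm2 = config$sc_alpha,
      sc_params = unclass(nano$sc_params),
      h_max_radius_nm = nano$mean_curve$h_max_radius,
      h_curves_used = nano$curves_used,
      h_curves_dropped = nano$curves_dropped),
    outputs = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, image_summary = res_filter,
                 nena = res_nena, clusterings = clusterings,
                 morphometry = morpho, nanocluster = nano, report = report,
                 out_dir = config$out_dir))
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; nested `az_params` /
#' `sc_params` maps become [clustering_params()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (nm in c("az_params", "sc_params"))
    if (!is.null(y[[nm]]))
      y[[nm]] <- clustering_params(y[[nm]]$min_cluster_size,
                                   y[[nm]]$min_samples)
  do.call(pipeline_config, y)
}
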