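#' Per-dye generative presets
#'
#' Frozen parameter sets describing how each fluorophore images the Bruchpilot
#' scaffold: the per-axis localization precision, the median fitted brightness
#' and the A/D inclusion threshold, the target median localization count per
#' active zone (AZ), the subcluster (SC) radius and the mean number of SCs per
#' AZ.
#'
#' @param name One of `"AF647"`, `"CF568"`, `"CF583R"`.
#' @return A `dye_preset`: a named list with fields `name`, `sigma_loc` (nm),
#'   `median_adc`, `min_adc` (A/D counts), `locs_per_az`, `sc_radius` (nm),
#'   `sc_per_az`.
#' @examples
#' dye_preset("AF647")$sigma_loc  # 8 nm
#' @export
dye_preset <- function(name) {
  presets <- list(
    AF647  = list(name = "AF647",  sigma_loc = 8,  median_adc = 8228,
                  min_adc = 3000, locs_per_az = 1085, sc_radius = 25,
                  sc_per_az = 12),
    CF568  = list(name = "CF568",  sigma_loc = 11, median_adc = 4144,
                  min_adc = 1000, locs_per_az = 1481, sc_radius = 34,
                  sc_per_az = 6),
    CF583R = list(name = "CF583R", sigma_loc = 10, median_adc = 3879,
                  min_adc = 1000, locs_per_az = 547,  sc_radius = 26,
                  sc_per_az = 10)
  )
  if (!name %in% names(presets))
    stop("unknown dye preset '", name, "'; options: ",
         paste(names(presets), collapse = ", "))
  structure(presets[[name]], class = "dye_preset")
}

#' Scene configuration for the synthetic localization generator
#'
#' Defaults describe one dSTORM acquisition: a ~20 x 20 um illuminated field
#' recorded over 15,000 frames, with AZ-sized clusters composed of nanoscale
#' subclusters, molecule blinking across consecutive frames, and uniform
#' background localizations.
#'
#' @param n_az Number of active zones in the field.
#' @param field_size_nm Square field edge length (nm).
#' @param n_frames Number of camera frames.
#' @param az_footprint_radius_nm Radius of the disc on which SC centres and
#'   diffuse molecules of one AZ are placed. The default (170 nm) gives
#'   alpha-shape AZ areas near 0.1 um^2, inside the 0.03-0.3 um^2 analysis
#'   window.
#' @param diffuse_fraction Fraction of an AZ's molecules placed uniformly on
#'   the AZ footprint rather than inside SCs, emulating the continuous
#'   scaffold population between subclusters; without it the AZ-level cluster
#'   is not density-contiguous.
#' @param az_min_separation_nm Minimum centre-to-centre AZ distance; must
#'   exceed `2 * az_footprint_radius_nm`.
#' @param background_rate_um2 Background localizations per um^2 over the whole
#'   movie.
#' @param blinks_mean Mean number of blink events per molecule (geometric on
#'   1, 2, ...).
#' @param burst_len_mean Mean blink burst length in frames (geometric on
#'   1, 2, ...).
#' @param intensity_sdlog Log-normal shape parameter of the A/D intensity
#'   distribution (its median is taken from the dye preset).
#' @param sc_inner_radius_nm Inner radius of the annulus on which SC centres
#'   are placed (0 = full disc).
#' @param edge_margin_nm Keep AZ centres at least this far from the field
#'   edge.
#' @param seed RNG seed; the same seed reproduces the scene bit-identically.
#' @return A `scene_config` list.
#' @export
scene_config <- function(n_az = 30L, field_size_nm = 20000, n_frames = 15000L,
                         az_footprint_radius_nm = 170,
                         diffuse_fraction = 0.5,
                         az_min_separation_nm = 1000,
                         background_rate_um2 = 5,
                         blinks_mean = 3, burst_len_mean = 2,
                         intensity_sdlog = 0.45,
                         sc_inner_radius_nm = 0,
                         edge_margin_nm = 500,
                         seed = 1L) {
  stopifnot(n_frames > 0, n_az >= 0, burst_len_mean >= 1,
            az_min_separation_nm > 2 * az_footprint_radius_nm ||
              n_az <= 1)
  stopifnot(diffuse_fraction >= 0, diffuse_fraction < 1)
  structure(list(n_az = as.integer(n_az), field_size_nm = field_size_nm,
                 n_frames = as.integer(n_frames),
                 az_footprint_radius_nm = az_footprint_radius_nm,
                 diffuse_fraction = diffuse_fraction,
                 az_min_separation_nm = az_min_separation_nm,
                 background_rate_um2 = background_rate_um2,
                 blinks_mean = blinks_mean, burst_len_mean = burst_len_mean,
                 intensity_sdlog = intensity_sdlog,
                 sc_inner_radius_nm = sc_inner_radius_nm,
                 edge_margin_nm = edge_margin_nm,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Lay out molecules for a synthetic scene
#'
#' Places `n_az` AZ centres uniformly in the field with a minimum pairwise
#' separation, scatters per AZ a Poisson number of SC centres on an annulus of
#' the AZ footprint, fills each SC with molecules uniform in a disc of the
#' preset's SC radius, and adds a diffuse molecule population uniform on the
#' AZ footprint (`config$diffuse_fraction` of the AZ's molecules, `sc_id` NA
#' in the ground truth). Expected molecule counts are chosen so that the
#' expected localization count per AZ matches the preset's `locs_per_az`
#' under the blink model.
#'
#' @param config A [scene_config()].
#' @param preset A [dye_preset()].
#' @return A `scene` list: `molecules` (data.frame x, y, sc_id, az_id),
#'   `az` (id, x, y), `sc` (id, az_id, x, y, radius), plus the config/preset.
#' @export
make_scene <- function(config, preset) {
  stopifnot(inherits(config, "scene_config"), inherits(preset, "dye_preset"))
  set.seed(config$seed)
  fs <- config$field_size_nm
  m <- config$edge_margin_nm
  # AZ centres: rejection sampling with bounded retries
  az_xy <- matrix(numeric(0), 0, 2)
  tries <- 0L
  max_tries <- 1000L * max(1L, config$n_az)
  while (nrow(az_xy) < config$n_az) {
    cand <- stats::runif(2, m, fs - m)
    ok <- nrow(az_xy) == 0 ||
      min(sqrt((az_xy[, 1] - cand[1])^2 + (az_xy[, 2] - cand[2])^2)) >
        config$az_min_separation_nm
    if (ok) az_xy <- rbind(az_xy, cand)
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not place ", config$n_az, " non-overlapping AZs in the field")
  }

  locs_per_molecule <- config$blinks_mean * config$burst_len_mean
  mol_per_az <- preset$locs_per_az / locs_per_molecule
  mol_per_sc <- (1 - config$diffuse_fraction) * mol_per_az / preset$sc_per_az
  diffuse_per_az <- config$diffuse_fraction * mol_per_az

  az_df <- data.frame(az_id = seq_len(config$n_az),
                      x = az_xy[, 1], y = az_xy[, 2])
  sc_list <- list(); mol_list <- list()
  sc_id <- 0L; ml <- 0L
  for (a in seq_len(config$n_az)) {
    n_diff <- stats::rpois(1, diffuse_per_az)
    if (n_diff > 0) {
      dr <- config$az_footprint_radius_nm * sqrt(stats::runif(n_diff))
      dt <- stats::runif(n_diff, 0, 2 * pi)
      ml <- ml + 1L
      mol_list[[ml]] <- data.frame(x = az_df$x[a] + dr * cos(dt),
                                   y = az_df$y[a] + dr * sin(dt),
                                   sc_id = NA_integer_, az_id = a)
    }
    k <- stats::rpois(1, preset$sc_per_az)
    for (s in seq_len(k)) {
      sc_id <- sc_id + 1L
      # SC centre uniform on annulus [inner, outer] of the AZ footprint
      r0 <- config$sc_inner_radius_nm
      r1 <- config$az_footprint_radius_nm
      rr <- sqrt(stats::runif(1, r0^2, r1^2))
      th <- stats::runif(1, 0, 2 * pi)
      cx <- az_df$x[a] + rr * cos(th)
      cy <- az_df$y[a] + rr * sin(th)
      sc_list[[sc_id]] <- data.frame(sc_id = sc_id, az_id = a, x = cx, y = cy,
                                     radius = preset$sc_radius)
      nm_mol <- stats::rpois(1, mol_per_sc)
      if (nm_mol > 0) {
        mr <- preset$sc_radius * sqrt(stats::runif(nm_mol))
        mt <- stats::runif(nm_mol, 0, 2 * pi)
        ml <- ml + 1L
        mol_list[[ml]] <- data.frame(x = cx + mr * cos(mt),
                                     y = cy + mr * sin(mt),
                                     sc_id = sc_id, az_id = a)
      }
    }
  }
  molecules <- if (length(mol_list)) do.call(rbind, mol_list) else
    data.frame(x = numeric(0), y = numeric(0), sc_id = integer(0),
               az_id = integer(0))
  if (nrow(molecules)) molecules$molecule_id <- seq_len(nrow(molecules))
  else molecules$molecule_id <- integer(0)
  structure(list(molecules = molecules, az = az_df,
                 sc = if (sc_id > 0) do.call(rbind, sc_list) else
                   data.frame(sc_id = integer(0), az_id = integer(0),
                              x = numeric(0), y = numeric(0),
                              radius = numeric(0)),
                 config = config, preset = preset),
            class = "scene")
}

#' Simulate photoswitching and emission for a scene
#'
#' Each molecule emits a geometric number of blink events; each event is a run
#' of consecutive frames (geometric length, uniform start) and every frame of
#' a burst yields one localization at the molecule position plus isotropic
#' Gaussian noise with per-axis sd `sigma_loc`. Intensities are log-normal
#' with median `median_adc`. Background localizations are uniform over field
#' and frames. No intensity filtering is applied here; apply
#' [filter_min_intensity()] downstream as for real data.
#'
#' @param scene A scene from [make_scene()].
#' @param sigma_loc Optional override of the preset localization precision
#'   (nm).
#' @return A list with `locs` (a [loc_table()]) and `truth` (a data.frame
#'   aligned row-by-row: `az_id`, `sc_id`, `molecule_id`, `is_background`).
#' @export
simulate_blinking <- function(scene, sigma_loc = NULL) {
  stopifnot(inherits(scene, "scene"))
  config <- scene$config; preset <- scene$preset
  if (is.null(sigma_loc)) sigma_loc <- preset$sigma_loc
  # continue the seeded stream deterministically, independent of scene RNG use
  set.seed(config$seed + 1L)
  mol <- scene$molecules
  n_mol <- nrow(mol)

  frames <- integer(0); mol_idx <- integer(0)
  if (n_mol > 0) {
    n_blinks <- 1L + stats::rgeom(n_mol, 1 / config$blinks_mean)
    blk_mol <- rep(seq_len(n_mol), n_blinks)
    n_b <- length(blk_mol)
    blen <- 1L + stats::rgeom(n_b, 1 / config$burst_len_mean)
    bstart <- sample.int(config$n_frames, n_b, replace = TRUE) - 1L
    mol_idx <- rep(blk_mol, blen)
    frames <- unlist(lapply(seq_len(n_b), function(i)
      bstart[i] + 0:(blen[i] - 1L)), use.names = FALSE)
    keep <- frames < config$n_frames  # bursts truncated at movie end
    frames <- frames[keep]; mol_idx <- mol_idx[keep]
  }
  n_sig <- length(frames)
  sig_x <- mol$x[mol_idx] + stats::rnorm(n_sig, 0, sigma_loc)
  sig_y <- mol$y[mol_idx] + stats::rnorm(n_sig, 0, sigma_loc)

  area_um2 <- (config$field_size_nm / 1000)^2
  n_bg <- stats::rpois(1, config$background_rate_um2 * area_um2)
  bg_x <- stats::runif(n_bg, 0, config$field_size_nm)
  bg_y <- stats::runif(n_bg, 0, config$field_size_nm)
  bg_f <- sample.int(config$n_frames, n_bg, replace = TRUE) - 1L

  x <- c(sig_x, bg_x); y <- c(sig_y, bg_y); fr <- c(frames, bg_f)
  intensity <- stats::rlnorm(n_sig + n_bg, meanlog = log(preset$median_adc),
                             sdlog = config$intensity_sdlog)
  # clamp rare noise excursions outside the field
  x <- pmin(pmax(x, 0), config$field_size_nm)
  y <- pmin(pmax(y, 0), config$field_size_nm)

  truth <- data.frame(
    az_id = c(mol$az_id[mol_idx], rep(NA_integer_, n_bg)),
    sc_id = c(mol$sc_id[mol_idx], rep(NA_integer_, n_bg)),
    molecule_id = c(mol$molecule_id[mol_idx], rep(NA_integer_, n_bg)),
    is_background = c(rep(FALSE, n_sig), rep(TRUE, n_bg))
  )
  ord <- order(fr, seq_along(fr))  # frame-sorted, stable
  locs <- loc_table(x[ord], y[ord], fr[ord], intensity[ord],
                    n_frames = config$n_frames,
                    source_id = sprintf("sim-%s-seed%d", preset$name,
                                        config$seed))
  list(locs = locs, truth = truth[ord, , drop = FALSE], scene = scene)
}

#' Write simulator ground truth as CSV
#'
#' One row per emitted localization, aligned with the localization table:
#' `localization_id`, `az_id`, `sc_id`, `molecule_id`, `is_background`
#' (diffuse AZ molecules carry an NA `sc_id`).
#'
#' @param sim Result of [simulate_blinking()] or [simulate_scene()].
#' @param path Output CSV path.
#' @export
write_ground_truth <- function(sim, path) {
  df <- cbind(localization_id = seq_len(nrow(sim$truth)), sim$truth)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Generate a complete synthetic localization scene
#'
#' Convenience wrapper: [make_scene()] followed by [simulate_blinking()].
#'
#' @inheritParams make_scene
#' @inheritParams simulate_blinking
#' @return See [simulate_blinking()].
#' @export
simulate_scene <- function(config, preset, sigma_loc = NULL) {
  simulate_blinking(make_scene(config, preset), sigma_loc = sigma_loc)
}
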