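test_that("dye presets are frozen and unknown names fail", {
  af <- dye_preset("AF647")
  expect_equal(af$sigma_loc, 8)
  expect_equal(af$min_adc, 3000)
  expect_equal(af$locs_per_az, 1085)
  expect_equal(dye_preset("CF568")$sc_radius, 34)
  expect_equal(dye_preset("CF583R")$locs_per_az, 547)
  expect_error(dye_preset("AF488"), "AF647")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- scene_config(n_az = 4, seed = 7)
  a <- simulate_scene(cfg, dye_preset("CF583R"))
  b <- simulate_scene(cfg, dye_preset("CF583R"))
  expect_identical(as.data.frame(a$locs), as.data.frame(b$locs))
  expect_identical(a$truth, b$truth)
})

test_that("scene structure matches the requested configuration", {
  cfg <- scene_config(n_az = 30, seed = 2)
  sc <- make_scene(cfg, dye_preset("AF647"))
  expect_equal(nrow(sc$az), 30)
  expect_equal(sort(unique(sc$molecules$az_id)), 1:30)
  # pairwise separation above the configured minimum
  d <- as.matrix(dist(sc$az[, c("x", "y")]))
  expect_gt(min(d[upper.tri(d)]), cfg$az_min_separation_nm)
  # SC centres stay on the AZ footprint
  per_sc <- merge(sc$sc, sc$az, by = "az_id", suffixes = c("", ".az"))
  expect_true(all(sqrt((per_sc$x - per_sc$x.az)^2 +
                       (per_sc$y - per_sc$y.az)^2) <=
                  cfg$az_footprint_radius_nm))
})

test_that("n_az = 0 yields pure background and truth aligns with the table", {
  sim <- simulate_scene(scene_config(n_az = 0, seed = 3), dye_preset("AF647"))
  expect_true(all(sim$truth$is_background))
  expect_equal(nrow(sim$truth), nrow(sim$locs))
})

test_that("an overfull field raises a placement error", {
  expect_error(
    make_scene(scene_config(n_az = 500, field_size_nm = 3000,
                            az_min_separation_nm = 1000, seed = 1),
               dye_preset("AF647")),
    "could not place")
})

test_that("zero localization noise collapses each molecule to a point", {
  sc <- make_scene(scene_config(n_az = 2, seed = 5), dye_preset("AF647"))
  sim <- simulate_blinking(sc, sigma_loc = 0)
  sig <- !sim$truth$is_background
  spread <- tapply(seq_len(nrow(sim$locs))[sig],
                   sim$truth$molecule_id[sig], function(i)
                     max(sim$locs$x[i]) - min(sim$locs$x[i]) +
                     max(sim$locs$y[i]) - min(sim$locs$y[i]))
  expect_true(all(spread == 0))
})

test_that("localization scatter and intensity law match the preset", {
  sim <- cached_scene()
  sig <- which(!sim$truth$is_background)
  # per-axis sd of within-molecule scatter converges to sigma_loc
  mol <- sim$truth$molecule_id[sig]
  centered <- unlist(lapply(split(sig, mol), function(i) {
    if (length(i) < 2) return(NULL)
    c(sim$locs$x[i] - mean(sim$locs$x[i]), sim$locs$y[i] - mean(sim$locs$y[i]))
  }))
  # a residual in a molecule localized m times has variance sigma^2 (m-1)/m;
  # pool with molecule-size weights to undo the shrinkage exactly
  n_per <- table(mol)
  w <- n_per[n_per > 1]
  shrink <- sqrt(sum(w - 1) / sum(w))
  sigma_hat <- sqrt(mean(centered^2)) / shrink
  se <- sigma_hat / sqrt(2 * length(centered))
  expect_lt(abs(sigma_hat - 8), 3 * max(se, 0.05))

  # intensity median near the preset's median
  med <- median(sim$locs$intensity)
  expect_lt(abs(med - 8228) / 8228, 0.02)
})

test_that("consecutive-frame re-localizations follow the expected distance law", {
  # mean NN distance between two consecutive localizations of one molecule is
  # the Rayleigh mean sqrt(2)*sigma*sqrt(pi/2)
  sim <- cached_scene()
  d <- consecutive_frame_nn_distances(sim$locs)
  short <- d[d < 60]  # same-molecule part of the sample
  mode_est <- density(short)$x[which.max(density(short)$y)]
  expect_lt(abs(mode_est - sqrt(2) * 8), 2.5)
})

test_that("ground truth writes aligned CSV rows", {
  sim <- cached_scene()
  path <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(sim, path)
  gt <- read.csv(path)
  expect_equal(nrow(gt), nrow(sim$locs))
  expect_equal(gt$localization_id, seq_len(nrow(gt)))
  expect_equal(gt$is_background, sim$truth$is_background)
})

test_that("ground-truth labels partition signal localizations", {
  sim <- cached_scene()
  sig <- !sim$truth$is_background
  expect_true(all(!is.na(sim$truth$az_id[sig])))
  expect_true(all(!is.na(sim$truth$molecule_id[sig])))
  expect_true(all(is.na(sim$truth$az_id[!sig])))
  # SC membership: diffuse molecules carry NA sc_id, clustered ones an id
  expect_true(any(is.na(sim$truth$sc_id[sig])))
  expect_true(any(!is.na(sim$truth$sc_id[sig])))
})
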