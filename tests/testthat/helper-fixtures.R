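# Shared in-code fixtures; everything is generated deterministically.

# Three Gaussian blobs plus uniform clutter. The partition of this exact
# point set (seed 42) under several HDBSCAN parameter settings was verified
# against scikit-learn's HDBSCAN implementation; the frozen cluster sizes and
# noise counts in test-segmentation.R come from that run.
blobs_fixture <- function() {
  set.seed(42)
  rbind(cbind(rnorm(60, 0, 30), rnorm(60, 0, 30)),
        cbind(rnorm(80, 5000, 40), rnorm(80, 5000, 40)),
        cbind(rnorm(50, 0, 25), rnorm(50, 9000, 25)),
        cbind(runif(40, -2000, 10000), runif(40, -2000, 10000)))
}

# small localization table built by hand
tiny_table <- function() {
  loc_table(x = c(10, 20, 30, 40), y = c(15, 25, 35, 45),
            frame = c(0L, 0L, 1L, 2L), intensity = c(3500, 900, 1200, 5000),
            n_frames = 10L, source_id = "tiny")
}

# moderate simulated scene reused across tests (cached per session)
.sim_cache <- new.env(parent = emptyenv())
cached_scene <- function(key = "af647_s1", n_az = 8, seed = 101,
                         preset = dye_preset("AF647")) {
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_scene(scene_config(n_az = n_az, seed = seed),
                                        preset)
  .sim_cache[[key]]
}

# shoelace polygon area for convex-hull oracles
hull_area <- function(xy) {
  h <- grDevices::chull(xy)
  p <- xy[h, , drop = FALSE]
  n <- nrow(p)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}
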