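test_that("K matches the hand formula on two points", {
  pts <- rbind(c(0, 0), c(10, 0))
  h <- ripley_h(pts, r = c(0, 5, 20), area = 1e4)
  # K(20) = A * 2 / (2 * 1) = 1e4; K(5) = 0
  expect_equal(h$K, c(0, 0, 1e4))
  expect_equal(h$H[1], 0)  # H(0) = 0
  expect_equal(h$L, sqrt(h$K / pi))
})

test_that("vectorized K equals an O(n^2) double-loop oracle exactly", {
  set.seed(41)
  r <- 0:150
  for (rep in 1:20) {
    n <- sample(5:100, 1)
    xy <- cbind(runif(n, 0, 400), runif(n, 0, 400))
    h <- ripley_h(xy, r, area = 400^2)
    K_brute <- sapply(r, function(rr) {
      cnt <- 0
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i != j &&
            sqrt(sum((xy[i, ] - xy[j, ])^2)) <= rr) cnt <- cnt + 1
      }
      400^2 * cnt / (n * (n - 1))
    })
    expect_identical(h$K, K_brute)
  }
})

test_that("K is monotone and H starts at zero for every curve", {
  set.seed(42)
  for (rep in 1:10) {
    xy <- cbind(rnorm(80, 0, 50), rnorm(80, 0, 50))
    h <- ripley_h(xy, 0:150, area = 1e5)
    expect_true(all(diff(h$K) >= 0))
    expect_equal(h$H[1], 0)
  }
  expect_error(ripley_h(rbind(c(0, 0)), 0:10, 100), "fewer than 2")
})

test_that("averaging H curves locates maxima with small-r tie breaking", {
  mk <- function(H) structure(list(r = 0:10, K = pi * (H + 0:10)^2,
                                   L = H + 0:10, H = H, n = 5, area = 1,
                                   normalization = "ordered-pairs"),
                              class = "h_curve")
  c1 <- mk(c(0, 1, 4, 9, 4, 1, 0, -1, -2, -3, -4))
  one <- average_h_and_max(list(c1))
  expect_equal(one$h_max_radius, 3)
  # two curves mirrored about zero: flat mean, argmax at grid start with tie
  c2 <- mk(-c1$H)
  two <- average_h_and_max(list(c1, c2))
  expect_equal(two$h_max_radius, 0)
  expect_true(two$tie)
  c3 <- structure(list(r = 0:5, K = rep(0, 6), H = rep(0, 6)),
                  class = "h_curve")
  expect_error(average_h_and_max(list(c1, c3)), "radius grid")
})

test_that("subclustering finds constructed blobs and honours the radius identity", {
  set.seed(43)
  az <- rbind(cbind(rnorm(30, 0, 10), rnorm(30, 0, 10)),
              cbind(rnorm(30, 150, 10), rnorm(30, 150, 10)))
  sc <- subcluster(az, clustering_params(15, 3))
  expect_equal(nrow(sc), 2)
  expect_equal(pi * sc$radius_nm^2, sc$area_nm2, tolerance = 1e-12)

  # empty AZ and sub-threshold AZ yield zero SCs, not an error
  expect_equal(nrow(subcluster(az[0, ], clustering_params(15, 3))), 0)
  expect_equal(nrow(subcluster(az[1:5, ], clustering_params(15, 3))), 0)
})

test_that("printed SC area and radius obey the equivalent-circle relation", {
  # the published pairing: area 3632 nm^2 corresponds to radius 34 nm
  expect_equal(sqrt(3632 / pi), 34, tolerance = 0.001)
})

test_that("calibration minimizes radius deviation and matches brute force", {
  set.seed(44)
  azs <- lapply(1:4, function(i) {
    centers <- cbind(runif(6, 0, 300), runif(6, 0, 300))
    do.call(rbind, lapply(1:6, function(s) {
      rr <- 25 * sqrt(runif(40)); th <- runif(40, 0, 2 * pi)
      cbind(centers[s, 1] + rr * cos(th) + rnorm(40, 0, 4),
            centers[s, 2] + rr * sin(th) + rnorm(40, 0, 4))
    }))
  })
  mcs_grid <- c(10, 15, 20, 25, 30)
  ms_grid <- c(2, 3, 5, 8, 10)
  cal <- calibrate_sc_params(azs, 25, mcs_grid, ms_grid)
  # independent brute force over the same grid via the public subcluster API
  best <- NULL
  for (mcs in mcs_grid) for (ms in ms_grid) {
    if (ms > mcs) next
    sc <- subcluster_all(azs, clustering_params(mcs, ms))
    if (nrow(sc) == 0) next
    dev <- abs(median(sc$radius_nm) - 25)
    if (is.null(best) || dev < best$dev - 1e-12) {
      best <- list(mcs = mcs, ms = ms, dev = dev)
    }
  }
  expect_equal(cal$params$min_cluster_size, best$mcs)
  expect_equal(cal$params$min_samples, best$ms)
  expect_equal(abs(cal$achieved_radius - 25), best$dev)

  # degenerate single-SC AZs still return the minimizing pair
  one <- list(cbind(rnorm(40, 0, 12), rnorm(40, 0, 12)))
  cal1 <- calibrate_sc_params(one, 15, c(10, 20), c(3, 5))
  expect_s3_class(cal1$params, "clustering_params")
})
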