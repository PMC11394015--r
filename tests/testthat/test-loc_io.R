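test_that("generic CSV parsing maps columns and preserves extras", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x_nm,y_nm,frame,intensity,extra",
               "1.5,2.5,0,3000,a", "10,20,1,4000,b", "30,40,2,5000,c"), path)
  tb <- read_localizations(path, "generic-csv")
  expect_s3_class(tb, "loc_table")
  expect_equal(nrow(tb), 3)
  expect_equal(tb$x, c(1.5, 10, 30))
  expect_equal(tb$intensity, c(3000, 4000, 5000))
  expect_equal(tb$extra, c("a", "b", "c"))

  # header-only file is a valid empty table
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("x_nm,y_nm,frame,intensity", path2)
  expect_equal(nrow(read_localizations(path2, "generic-csv")), 0)
})

test_that("missing and malformed columns raise informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x_nm,y_nm,frame", "1,2,0"), path)
  expect_error(read_localizations(path, "generic-csv"), "intensity")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x_nm,y_nm,frame,intensity", "1,2,0,oops"), path2)
  expect_error(read_localizations(path2, "generic-csv"), "non-numeric")
})

test_that("write/read round-trips both dialects bit-identically", {
  set.seed(3)
  tb <- loc_table(x = runif(50, 0, 2e4), y = runif(50, 0, 2e4),
                  frame = sample(0:999, 50, TRUE),
                  intensity = rlnorm(50, log(8228), 0.45),
                  n_frames = 1000L)
  for (dialect in c("generic-csv", "rapidstorm-txt")) {
    path <- withr::local_tempfile()
    write_localizations(tb, path, dialect)
    tb2 <- read_localizations(path, dialect, n_frames = 1000L)
    expect_identical(tb2$x, tb$x)
    expect_identical(tb2$y, tb$y)
    expect_identical(tb2$frame, tb$frame)
    expect_identical(tb2$intensity, tb$intensity)
  }
})

test_that("intensity filter has an inclusive boundary and preserves order", {
  tb <- loc_table(x = 1:3, y = 1:3, frame = c(0L, 0L, 0L),
                  intensity = c(999, 1000, 1001), n_frames = 1L)
  expect_equal(nrow(filter_min_intensity(tb, 1000)), 2)
  expect_equal(filter_min_intensity(tb, 1000)$intensity, c(1000, 1001))
  expect_equal(filter_min_intensity(tb, 0), tb)  # identity at 0
})

test_that("filtered fraction on a simulated dye matches its intensity law", {
  sim <- cached_scene()
  tb <- sim$locs
  kept <- nrow(filter_min_intensity(tb, 3000)) / nrow(tb)
  expected <- mean(tb$intensity >= 3000)  # direct count on the sample
  expect_identical(kept, expected)
  # and the sample agrees with the lognormal tail probability
  expect_lt(abs(expected - (1 - plnorm(3000, log(8228), 0.45))), 0.02)
})

test_that("ROI cropping counts boundary as inside and matches ray casting", {
  square <- matrix(c(0, 0, 1000, 0, 1000, 1000, 0, 1000), ncol = 2,
                   byrow = TRUE)
  rois <- roi_set(list(square))
  tb <- loc_table(x = c(500, 2000, 0, 1000), y = c(500, 2000, 0, 500),
                  frame = rep(0L, 4), intensity = rep(1, 4), n_frames = 1L)
  out <- crop_to_rois(tb, rois)
  expect_equal(nrow(out), 3)  # interior + corner + edge midpoint

  # brute-force ray-casting oracle on random points vs a random polygon
  set.seed(9)
  poly <- cbind(500 + 400 * cos(seq(0, 2 * pi, length.out = 8)[-8]),
                500 + 300 * sin(seq(0, 2 * pi, length.out = 8)[-8]))
  pts <- cbind(runif(400, 0, 1000), runif(400, 0, 1000))
  ray_cast <- function(px, py) {
    n <- nrow(poly); inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- poly[i, 1]; yi <- poly[i, 2]
      xj <- poly[j, 1]; yj <- poly[j, 2]
      if ((yi > py) != (yj > py) &&
          px < (xj - xi) * (py - yi) / (yj - yi) + xi) inside <- !inside
      j <- i
    }
    inside
  }
  tb2 <- loc_table(pts[, 1], pts[, 2], frame = rep(0L, 400),
                   intensity = rep(1, 400), n_frames = 1L)
  got <- crop_to_rois(tb2, roi_set(list(poly)))
  want <- which(mapply(ray_cast, pts[, 1], pts[, 2]))
  expect_setequal(paste(got$x, got$y), paste(pts[want, 1], pts[want, 2]))

  # cropping is idempotent
  expect_equal(crop_to_rois(got, roi_set(list(poly))), got)

  expect_error(roi_set(rep(list(square), 7)), "at most 6")
})

test_that("binned image places counts in half-open bins and conserves totals", {
  tb <- loc_table(5, 5, 0L, 1000, n_frames = 1L)
  img <- render_binned_image(tb, 10)
  expect_equal(dim(img), c(1, 1))
  expect_equal(img[1, 1], 1L)

  set.seed(4)
  tb2 <- loc_table(runif(1000, 0, 500), runif(1000, 0, 800),
                   frame = rep(0L, 1000), intensity = rep(1, 1000),
                   n_frames = 1L)
  for (p in c(7, 10, 33)) {
    img <- render_binned_image(tb2, p)
    expect_equal(sum(img), 1000L)
  }
  # independent 2D histogram oracle
  p <- 10
  img <- render_binned_image(tb2, p)
  oracle <- matrix(0L, nrow(img), ncol(img))
  for (k in seq_len(nrow(tb2))) {
    i <- floor(tb2$y[k] / p) + 1
    j <- floor(tb2$x[k] / p) + 1
    oracle[i, j] <- oracle[i, j] + 1L
  }
  expect_identical(img, oracle)

  expect_equal(dim(render_binned_image(tb2[0, ], 10)), c(0, 0))
})

test_that("binned image survives a 16-bit TIFF round trip", {
  set.seed(5)
  tb <- loc_table(runif(200, 0, 300), runif(200, 0, 300),
                  frame = rep(0L, 200), intensity = rep(1, 200),
                  n_frames = 1L)
  img <- render_binned_image(tb, 10)
  path <- withr::local_tempfile(fileext = ".tif")
  write_binned_tiff(img, path)
  back <- round(tiff::readTIFF(path) * 65535)
  expect_equal(back, unclass(img), ignore_attr = TRUE)
})

test_that("image summary reports brightness and locs per 100 frames", {
  tb <- loc_table(runif(150), runif(150), frame = rep(0L, 150),
                  intensity = rep(4144, 150), n_frames = 15000L)
  s <- image_summary(tb)
  expect_equal(s$locs_per_100_frames, 1.0)
  expect_equal(s$mean_brightness, 4144)
  expect_equal(s$n_localizations, 150)

  s0 <- image_summary(tb[0, ])
  expect_true(is.na(s0$mean_brightness))
  expect_equal(s0$n_localizations, 0)
})

test_that("simulated brightness mean matches the preset distribution", {
  sim <- cached_scene()
  s <- image_summary(sim$locs)
  mu <- exp(log(8228) + 0.45^2 / 2)  # lognormal mean
  se <- sd(sim$locs$intensity) / sqrt(nrow(sim$locs))
  expect_lt(abs(s$mean_brightness - mu), 4 * se)
})
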