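test_that("two well-separated blobs give exactly two clusters", {
  set.seed(21)
  xy <- rbind(cbind(rnorm(200, 0, 30), rnorm(200, 0, 30)),
              cbind(rnorm(200, 5000, 30), rnorm(200, 5000, 30)))
  lab <- hdbscan_points(xy, clustering_params(100, 25))
  expect_equal(length(unique(lab[!is.na(lab)])), 2)
  # each blob maps to one label
  expect_equal(length(unique(lab[1:200][!is.na(lab[1:200])])), 1)
  expect_equal(length(unique(lab[201:400][!is.na(lab[201:400])])), 1)
})

test_that("sparse uniform background yields no clusters", {
  set.seed(22)
  xy <- cbind(runif(400, 0, 20000), runif(400, 0, 20000))
  lab <- hdbscan_points(xy, clustering_params(100, 25))
  expect_equal(sum(!is.na(lab)), 0)
})

test_that("partition frozen against the scikit-learn HDBSCAN oracle", {
  # cluster sizes and noise counts computed once with sklearn's HDBSCAN on
  # this exact fixture (identical partition, adjusted Rand index 1.0)
  xy <- blobs_fixture()
  cases <- list(list(p = c(10, 5), sizes = c(52, 72, 84), noise = 22),
                list(p = c(25, 25), sizes = c(53, 70, 86), noise = 21),
                list(p = c(40, 10), sizes = c(53, 66, 86), noise = 25))
  for (cs in cases) {
    lab <- hdbscan_points(xy, clustering_params(cs$p[1], cs$p[2]))
    expect_equal(sort(as.integer(table(lab))), cs$sizes,
                 info = paste(cs$p, collapse = ","))
    expect_equal(sum(is.na(lab)), cs$noise, info = paste(cs$p, collapse = ","))
  }
})

test_that("cluster membership partitions the table", {
  xy <- blobs_fixture()
  tb <- loc_table(xy[, 1] + 3000, xy[, 2] + 3000, rep(0L, nrow(xy)),
                  rep(1, nrow(xy)), n_frames = 1L)
  cl <- cluster_localizations(tb, clustering_params(10, 5))
  members <- unlist(cl$clusters)
  expect_equal(length(members), length(unique(members)))  # disjoint
  expect_setequal(c(members, which(is.na(cl$labels))), seq_len(nrow(tb)))
})

test_that("clustering is invariant under permutation of record order", {
  # tie-free instance: dense distinct blobs without uniform clutter (border
  # points whose mutual-reachability distances tie can legitimately swap
  # assignment under reordering, in any HDBSCAN implementation)
  xy <- blobs_fixture()[1:190, ]
  lab <- hdbscan_points(xy, clustering_params(10, 5))
  set.seed(23)
  perm <- sample(nrow(xy))
  lab_p <- hdbscan_points(xy[perm, ], clustering_params(10, 5))
  # map permuted labels back to original record order, compare partitions as
  # sets of member-index sets (labels themselves may be renumbered)
  back <- integer(length(lab)); back[perm] <- lab_p
  part <- function(l) unname(lapply(split(seq_along(l), l), function(i)
    paste(sort(i), collapse = ",")))
  expect_setequal(part(ifelse(is.na(lab), -1L, lab)),
                  part(ifelse(is.na(back), -1L, back)))
})

test_that("too-small tables warn and return noise only", {
  tb <- tiny_table()
  expect_warning(cl <- cluster_localizations(tb, clustering_params(100, 25)),
                 "min_cluster_size")
  expect_equal(length(cl$clusters), 0)
  expect_true(all(is.na(cl$labels)))
})

test_that("the published sweep grids enumerate 14 x 14 combinations", {
  g <- sweep_grids()
  expect_equal(g$min_cluster_size, c(seq(10, 90, 10), seq(100, 500, 100)))
  expect_equal(g$min_samples, c(2, seq(5, 25, 5), seq(30, 100, 10)))
  expect_equal(length(g$min_cluster_size), 14)
  expect_equal(length(g$min_samples), 14)
})

test_that("sweep medians over a single image equal its counts", {
  xy <- blobs_fixture()
  tb <- loc_table(xy[, 1] + 3000, xy[, 2] + 3000, rep(0L, nrow(xy)),
                  rep(1, nrow(xy)), n_frames = 1L)
  grids <- list(min_cluster_size = c(10L, 25L), min_samples = c(5L, 10L))
  sw <- parameter_sweep(list(tb), grids)
  expect_equal(dim(sw$median_az_count), c(2, 2))
  for (ci in 1:2) for (mi in 1:2) {
    lab <- suppressWarnings(
      hdbscan_points(xy, clustering_params(grids$min_cluster_size[ci],
                                           grids$min_samples[mi])))
    expect_equal(sw$median_az_count[ci, mi],
                 length(unique(lab[!is.na(lab)])))
  }
  # median over three copies of the same image is the single-image count
  sw3 <- parameter_sweep(list(tb, tb, tb), grids)
  expect_equal(sw3$median_az_count, sw$median_az_count)
})

test_that("simulated AZ count is recovered on a moderate scene", {
  sim <- cached_scene()
  tb <- filter_min_intensity(sim$locs, 3000)
  cl <- cluster_localizations(tb, clustering_params(100, 25))
  azp <- lapply(cl$clusters, function(i) cbind(tb$x[i], tb$y[i]))
  curve <- select_alpha(azp)
  rec <- az_summary(cl, tb, curve$selected_alpha)
  expect_lte(abs(sum(rec$kept) - 8), 1)
})
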