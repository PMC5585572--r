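test_that("pairs-dialect text files are transcribed exactly", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 3", "0 5", "1 4"), f)
  r <- read_raster_text(f)
  expect_equal(r$n_neurons, 2L)
  expect_equal(r$spikes[[1]], c(4L, 6L))   # 0-based on disk, 1-based in memory
  expect_equal(r$spikes[[2]], 5L)
  expect_equal(r$n_bins, 6L)
})

test_that("empty and malformed spike files raise informative errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), f)
  expect_error(read_raster_text(f), "no spikes")
  writeLines(c("0 3", "1 oops"), f)
  expect_error(read_raster_text(f, dialect = "pairs"), "malformed")
  writeLines(c("0 -3"), f)
  expect_error(read_raster_text(f, dialect = "pairs"), "negative")
})

test_that("text round trip is the identity for random rasters, both dialects", {
  set.seed(11)
  for (k in 1:20) {
    r <- random_raster(sample(2:6, 1), sample(20:60, 1))
    for (dialect in c("pairs", "per_neuron_rows")) {
      f <- withr::local_tempfile(fileext = ".txt")
      write_raster_text(r, f, dialect = dialect)
      r2 <- read_raster_text(f, dialect = dialect,
                             n_bins = r$n_bins, n_neurons = r$n_neurons)
      expect_equal(r2$spikes, r$spikes)
      expect_equal(r2$n_bins, r$n_bins)
    }
  }
})

test_that("JSON archival round trip is lossless, including MEA and silent neurons", {
  mea <- mea_config(4, 4, pitch = 60,
                    positions = cbind(c(1, 2, 3), c(1, 1, 4)))
  r <- spike_raster(list(c(4, 6), 5, integer(0)), n_bins = 10, bin_ms = 2,
                    labels = c("a", "b", "c"), mea = mea)
  f <- withr::local_tempfile(fileext = ".json")
  write_raster_json(r, f)
  r2 <- read_raster_json(f)
  expect_equal(r2$spikes, r$spikes)
  expect_equal(r2$n_bins, r$n_bins)
  expect_equal(r2$bin_ms, r$bin_ms)
  expect_equal(r2$labels, r$labels)
  expect_equal(r2$mea$positions, unname(mea$positions))
  expect_equal(lengths(r2$spikes)[[3]], 0L)  # silent neuron preserved
})

test_that("JSON round trip preserves a large random raster exactly", {
  set.seed(21)
  r <- random_raster(50, 400, rate = 0.1)
  f <- withr::local_tempfile(fileext = ".json")
  write_raster_json(r, f)
  expect_equal(read_raster_json(f)$spikes, r$spikes)
})

test_that("corrupted archival files name the missing group", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(format = "spikegibbs-raster-1", n_neurons = 2),
                       f, auto_unbox = TRUE)
  expect_error(read_raster_json(f), "n_bins")
  jsonlite::write_json(list(a = 1), f, auto_unbox = TRUE)
  expect_error(read_raster_json(f), "format")
})

test_that("time stamps load, reject non-monotone rows, and keep spacing", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0", "33.3", "66.6"), f)
  expect_equal(as.numeric(read_timestamps(f)), c(0, 33.3, 66.6))
  writeLines(c("0", "0"), f)
  expect_error(read_timestamps(f), "row 2")
  writeLines(format(seq(0, by = 25, length.out = 1000)), f)
  ts <- read_timestamps(f)
  expect_equal(mean(diff(as.numeric(ts))), 25)
})

test_that("stimulus directories load ordered, normalized, and round trip", {
  dir <- withr::local_tempdir()
  set.seed(3)
  checker <- (outer(1:8, 1:8, "+") %% 2)
  frames <- list(checker, matrix(0, 8, 8), matrix(stats::runif(64), 8, 8))
  stim <- stimulus_sequence(frames)
  write_stimulus_dir(stim, dir)
  loaded <- load_stimulus_dir(dir)
  expect_length(loaded$frames, 3)
  # PNG quantizes to 8 bits
  for (k in 1:3)
    expect_lt(max(abs(loaded$frames[[k]] - frames[[k]])), 1 / 255)
  expect_true(all(loaded$frames[[2]] == 0))
})

test_that("mixed-size stimulus directories are rejected", {
  dir <- withr::local_tempdir()
  png::writePNG(matrix(0.5, 4, 4), file.path(dir, "a.png"))
  png::writePNG(matrix(0.5, 5, 5), file.path(dir, "b.png"))
  expect_error(load_stimulus_dir(dir), "mixed sizes")
})

test_that("neuron selection preserves the time axis and rates", {
  r <- spike_raster(list(c(2, 3, 4), 6), n_bins = 10)
  top <- select_neurons(r, top_k = 1)
  expect_equal(top$n_neurons, 1L)
  expect_equal(top$spikes[[1]], c(2L, 3L, 4L))
  expect_equal(top$n_bins, r$n_bins)
  all_kept <- select_neurons(r, indices = 1:2)
  expect_equal(all_kept$spikes, r$spikes)
  expect_error(select_neurons(r, indices = integer(0)), "empty|range")
})

test_that("top-k selection dominates excluded neurons in rate and is idempotent", {
  set.seed(7)
  for (k in 1:25) {
    r <- random_raster(6, 50)
    kk <- sample(1:5, 1)
    sel <- select_neurons(r, top_k = kk)
    kept_min <- min(firing_rates(sel))
    counts <- lengths(r$spikes)
    kept_idx <- which(counts %in% (kept_min * r$n_bins) |
                        counts / r$n_bins >= kept_min)
    excluded_max <- if (kk < 6)
      max(sort(counts, decreasing = TRUE)[(kk + 1):6] / r$n_bins) else 0
    expect_gte(kept_min, excluded_max)
  }
  r <- random_raster(4, 30)
  once <- select_neurons(r, indices = c(1, 3))
  twice <- select_neurons(once, indices = 1:2)
  expect_equal(twice$spikes, once$spikes)
})
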