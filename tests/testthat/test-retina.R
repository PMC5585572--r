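test_that("lif parameters derive gamma from the leak time and validate ranges", {
  p <- lif_params(tau_l = 10)
  expect_equal(p$gamma, 0.9)
  expect_equal(p$dt, 1)
  expect_equal(lif_params(gamma = 0.8)$tau_l, 5)
  expect_error(lif_params(gamma = 1.5), "gamma")
  expect_error(lif_params(sigma_b = -1), "sigma_b")
})

test_that("subthreshold constant drive converges to the affine fixed point, no spikes", {
  p <- lif_params(gamma = 0.9, sigma_b = 0)
  I <- 0.05                       # fixed point 0.5 < theta = 1
  V <- 0; Z <- 0L
  spiked <- FALSE
  for (t in 1:300) {
    st <- lif_step(V, Z, I, NULL, p)
    V <- st$V; Z <- st$Z
    if (Z == 1L) spiked <- TRUE
  }
  expect_false(spiked)
  expect_equal(V, I / (p$capacitance * (1 - p$gamma)), tolerance = 1e-10)
})

test_that("the reset acts through the (1 - Z) factor only", {
  p <- lif_params(gamma = 0.9, sigma_b = 0)
  st <- lif_step(V = 5, Z = 1L, I_t = 0.3, params = p)
  expect_equal(st$V, 0.3)          # leak term zeroed after a spike
  st2 <- lif_step(V = 5, Z = 0L, I_t = 0.3, params = p)
  expect_equal(st2$V, 0.9 * 5 + 0.3)
})

test_that("suprathreshold drive fires with the geometric-sum period", {
  p <- lif_params(gamma = 0.9, sigma_b = 0)
  for (I in c(0.15, 0.2, 0.3, 0.6)) {
    nstar <- which((I / p$capacitance) *
                     (1 - p$gamma^(1:200)) / (1 - p$gamma) >=
                     p$threshold)[1]
    r <- simulate_lif(matrix(I, 1, 12 * nstar), p)
    expect_equal(unique(diff(r$spikes[[1]])), nstar)
    expect_equal(r$spikes[[1]][1], nstar)
  }
})

test_that("gamma = 0 makes the membrane memoryless", {
  p <- lif_params(gamma = 0, sigma_b = 0)
  drive <- matrix(c(0.4, 1.2, 0.4, 1.2), 1, 4)
  r <- simulate_lif(drive, p)
  expect_equal(r$spikes[[1]], c(2L, 4L))  # V(t+1) = I(t) only
})

test_that("spike labels are consistent with threshold crossings at every bin", {
  set.seed(167)
  p <- lif_params(gamma = 0.85, sigma_b = 0.4)
  drive <- matrix(stats::runif(3 * 400, 0, 0.25), 3, 400)
  seed <- 11
  r <- simulate_lif(drive, p, seed = seed)
  # replay the dynamics and compare V >= theta with recorded labels
  set.seed(seed)
  noise <- matrix(stats::rnorm(3 * 400), 3, 400)
  V <- numeric(3); Z <- integer(3)
  for (t in 1:400) {
    st <- lif_step(V, Z, drive[, t], NULL, p, noise[, t])
    V <- st$V; Z <- st$Z
    expect_identical(Z, as.integer(V >= p$threshold))
    expect_identical(as.integer(as.matrix(r)[, t]), Z)
  }
})

test_that("firing rate is non-decreasing in the drive for deterministic neurons", {
  p <- lif_params(gamma = 0.9, sigma_b = 0)
  rates <- vapply(seq(0.05, 0.8, by = 0.05), function(I) {
    n_spikes(simulate_lif(matrix(I, 1, 400), p)) / 400
  }, numeric(1))
  expect_true(all(diff(rates) >= -1e-12))
})

test_that("connectivity schemes honor their contracts", {
  W0 <- build_connectivity("none", 10)
  expect_true(all(W0 == 0))
  Ws <- build_connectivity("sparse", 100, n_connections = 1000, seed = 2)
  expect_equal(sum(Ws != 0), 1000L)
  expect_identical(Ws, build_connectivity("sparse", 100,
                                          n_connections = 1000, seed = 2))
  Ws2 <- build_connectivity("sparse", 100, n_connections = 1000, seed = 3)
  expect_false(identical(Ws != 0, Ws2 != 0))
  Wd <- build_connectivity("dense", 8, seed = 4)
  expect_true(all(Wd != 0))
  expect_error(build_connectivity("sparse", 3, n_connections = 10),
               "n_connections")
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.table(matrix(1:4 / 10, 2, 2), f, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  Wf <- build_connectivity("file", 2, path = f)
  expect_equal(dim(Wf), c(2L, 2L))
  expect_error(build_connectivity("file", 3, path = f), "expected 3x3")
})

test_that("uncoupled simulation equals the none-scheme simulation at matched seed", {
  stim <- make_white_noise_stimulus(10, 10, 5, seed = 5,
                                    display_ms = 20)$stimulus
  lay <- retina_layout(2, 2, sigma_center = 1.5, gain = 3)
  p <- lif_params(sigma_b = 0.2)
  r1 <- simulate_retina(stim, lay, p, connectivity = NULL, seed = 21)
  r2 <- simulate_retina(stim, lay, p,
                        connectivity = build_connectivity("none", 4),
                        seed = 21)
  expect_identical(r1$spikes, r2$spikes)
})

test_that("the DoG front-end is spatially uniform on gray, local, and linear", {
  gray <- stimulus_sequence(list(matrix(0.5, 16, 16)), display_ms = 30)
  lay <- retina_layout(3, 3, sigma_center = 1.5)
  d <- compute_drive(gray, lay)
  # all neurons receive the same drive at every bin (time ramp is shared)
  expect_lt(max(apply(d, 2, max) - apply(d, 2, min)), 1e-9)
  # single bright pixel at one center dominates that neuron's drive
  centers <- attr(d, "centers")
  img <- matrix(0, 16, 16)
  img[round(centers[5, "y"]), round(centers[5, "x"])] <- 1
  spot <- stimulus_sequence(list(img), display_ms = 30)
  ds <- compute_drive(spot, lay)
  final <- ds[, ncol(ds)]
  expect_equal(which.max(final), 5L)
  # linearity in the gain
  lay2 <- retina_layout(3, 3, sigma_center = 1.5, gain = 2)
  expect_equal(compute_drive(spot, lay2), 2 * ds, ignore_attr = TRUE)
  expect_error(compute_drive(spot, retina_layout(40, 40)), "grid larger")
})

test_that("a black stimulus with zero-DC drive yields an empty raster", {
  black <- stimulus_sequence(list(matrix(0, 8, 8), matrix(0, 8, 8)),
                             display_ms = 25)
  lay <- retina_layout(2, 2, sigma_center = 1)
  p <- lif_params(sigma_b = 0)
  r <- simulate_retina(black, lay, p)
  expect_equal(n_spikes(r), 0L)
  expect_equal(r$n_bins, 50L)           # 2 frames x 25 ms at 1 ms bins
})

test_that("excitatory dense coupling raises the population rate", {
  stim <- make_white_noise_stimulus(12, 12, 10, seed = 7,
                                    display_ms = 20)$stimulus
  lay <- retina_layout(3, 3, sigma_center = 1.5, gain = 4)
  p <- lif_params(sigma_b = 0.3)
  W <- build_connectivity("dense", 9, seed = 8,
                          weight_law = function(n) rep(0.4, n))
  gain <- vapply(1:10, function(s) {
    r0 <- simulate_retina(stim, lay, p, NULL, seed = 500 + s)
    r1 <- simulate_retina(stim, lay, p, W, seed = 500 + s)
    n_spikes(r1) - n_spikes(r0)
  }, numeric(1))
  expect_gt(mean(gain), 0)
})

test_that("retina configuration files round trip through JSON", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    lif = list(gamma = 0.85, sigma_b = 0.2, threshold = 0.8),
    layout = list(n_x = 2, n_y = 3, sigma_center = 1.2, gain = 2),
    connectivity = list(scheme = "sparse", n_connections = 6, seed = 1)),
    f, auto_unbox = TRUE)
  cfg <- read_retina_config(f)
  expect_equal(cfg$params$gamma, 0.85)
  expect_equal(cfg$layout$n_y, 3L)
  expect_equal(cfg$connectivity_spec$scheme, "sparse")
})
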