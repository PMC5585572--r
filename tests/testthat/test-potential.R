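test_that("monomial evaluation is the product of the named spike variables", {
  # neuron 1 fires at t+1, neuron 3 at t, neuron 4 at t+2 (0-based: 0,2,3)
  m <- spikegibbs:::monomial(c(1, 3, 4), c(1, 0, 2))
  r <- spike_raster(list(6, integer(0), 5, 7), n_bins = 8)
  expect_equal(eval_monomial(m, r, 5), 1L)
  r2 <- spike_raster(list(6, integer(0), 5, integer(0)), n_bins = 8)
  expect_equal(eval_monomial(m, r2, 5), 0L)
  expect_error(eval_monomial(m, r, 7), "beyond raster end")
})

test_that("monomial evaluation matches a dense brute-force product", {
  set.seed(37)
  for (k in 1:30) {
    r <- random_raster(4, 25, rate = 0.4)
    M <- as.matrix(r)
    deg <- sample(1:3, 1)
    ev <- unique(cbind(sample(4, deg, replace = TRUE),
                       sample(0:2, deg, replace = TRUE)))
    m <- spikegibbs:::monomial(ev[, 1], ev[, 2])
    t0 <- sample(seq_len(25 - 2), 1)
    brute <- prod(M[cbind(m[, 1], t0 + m[, 2])])
    expect_equal(eval_monomial(m, r, t0), as.integer(brute))
  }
})

test_that("canned models reproduce the published monomial enumerations", {
  b <- build_potential("bernoulli", 3)
  expect_equal(names(b$h), c("w0(0)", "w1(0)", "w2(0)"))
  i3 <- build_potential("ising", 3)
  expect_equal(names(i3$h),
               c("w0(0)", "w1(0)", "w2(0)",
                 "w0(0)w1(0)", "w0(0)w2(0)", "w1(0)w2(0)"))
  pw <- build_potential("pairwise", 2, 2)
  expect_setequal(names(pw$h),
                  c("w0(0)", "w1(0)", "w0(0)w1(0)",
                    "w0(0)w0(1)", "w1(0)w1(1)", "w0(0)w1(1)", "w1(0)w0(1)"))
  expect_equal(names(pw$h)[1:2], c("w0(0)", "w1(0)"))  # singles first
  expect_error(build_potential("ising", 3, range = 2), "range 1")
})

test_that("canned model sizes match explicit enumeration for N <= 4, R <= 3", {
  for (N in 1:4) {
    expect_length(build_potential("bernoulli", N)$h, N)
    expect_length(build_potential("ising", N)$h, N + choose(N, 2))
    expect_length(build_potential("pairwise_triplets", N)$h,
                  N + choose(N, 2) + choose(N, 3))
    for (R in 1:3)
      expect_length(build_potential("pairwise", N, R)$h,
                    N + choose(N, 2) + (R - 1) * N^2)
  }
})

test_that("potential_value sums coefficients of active monomials", {
  pot <- build_potential("bernoulli", 2)
  expect_equal(potential_value(pot, matrix(c(1, 1), 2, 1)), 0)
  pot$h[] <- c(1, 2)
  expect_equal(potential_value(pot, matrix(c(0, 1), 2, 1)), 2)
  expect_error(potential_value(pot, matrix(0, 3, 1)), "must be")
  set.seed(41)
  for (k in 1:20) {
    p <- random_potential(3, 2, 5)
    blk <- matrix(sample(0:1, 6, replace = TRUE), 3, 2)
    brute <- sum(vapply(seq_along(p$h), function(l) {
      m <- p$monomials[[l]]
      p$h[l] * prod(blk[cbind(m[, 1], m[, 2] + 1)])
    }, numeric(1)))
    expect_equal(potential_value(p, blk), brute)
  }
})

test_that("energy equals the window sum and the Bernoulli closed form", {
  r <- random_raster(3, 40)
  zero <- build_potential("bernoulli", 3)
  expect_equal(energy(zero, r), 0)
  bern <- build_potential("bernoulli", 3)
  bern$h[] <- c(0.5, -1, 2)
  expect_equal(energy(bern, r), sum(bern$h * lengths(r$spikes)))
  set.seed(43)
  for (k in 1:10) {
    p <- random_potential(3, 2, 6)
    rr <- random_raster(3, 30, rate = 0.3)
    expect_equal(energy(p, rr), brute_energy(p, rr), tolerance = 1e-12)
  }
})

test_that("empirical averages match a brute-force window scan", {
  ones <- spike_raster(lapply(1:3, function(i) 1:20), n_bins = 20)
  pot <- build_potential("pairwise", 3, 2)
  st <- empirical_averages(ones, pot)
  expect_true(all(st$averages == 1))
  expect_equal(st$n_windows, 19L)
  set.seed(47)
  for (k in 1:10) {
    r <- random_raster(3, 35, rate = 0.35)
    p <- random_potential(3, 2, 6)
    st <- empirical_averages(r, p)
    nw <- r$n_bins - p$range + 1
    brute <- vapply(p$monomials, function(m) {
      mean(vapply(seq_len(nw), function(t)
        eval_monomial(m, r, t), integer(1)))
    }, numeric(1))
    expect_equal(unname(st$averages), brute)
    expect_equal(st$counts, as.integer(round(st$averages * nw)))
  }
})

test_that("monomial averages never decrease when spikes are added", {
  set.seed(53)
  r <- random_raster(3, 40, rate = 0.2)
  p <- random_potential(3, 2, 8)
  base <- empirical_averages(r, p)$averages
  M <- as.matrix(r)
  M[cbind(sample(3, 5, TRUE), sample(40, 5))] <- 1L
  more <- empirical_averages(raster_from_matrix(M), p)$averages
  expect_true(all(more >= base - 1e-12))
})

test_that("block probabilities normalize and count patterns combinatorially", {
  const <- spike_raster(list(seq(1, 19, by = 2)), n_bins = 20)
  # alternating 1010...: length-2 blocks are '10' and '01' only
  bp <- block_probabilities(const, 2)
  l2 <- bp[bp$length == 2, ]
  expect_equal(nrow(l2), 2)
  expect_equal(sort(l2$prob), c(9, 10) / 19)
  for (len in 1:2)
    expect_equal(sum(bp$prob[bp$length == len]), 1)
  set.seed(59)
  for (k in 1:20) {
    r <- random_raster(3, 30)
    bp <- block_probabilities(r, 3)
    for (len in 1:3)
      expect_equal(sum(bp$prob[bp$length == len]), 1)
  }
  full <- spike_raster(list(1:10), n_bins = 10)
  bp1 <- block_probabilities(full, 1)
  expect_equal(nrow(bp1), 1)
  expect_equal(bp1$prob, 1)
  expect_error(block_probabilities(full, 0), "max_len")
})

test_that("empirical averages agree with the raster's own block distribution", {
  set.seed(61)
  r <- random_raster(3, 60, rate = 0.3)
  p <- build_potential("pairwise", 3, 2)
  st <- empirical_averages(r, p)
  bp <- block_probabilities(r, 2)
  l2 <- bp[bp$length == 2, ]
  for (l in seq_along(p$h)) {
    m <- p$monomials[[l]]
    if (max(m[, 2]) < 1) next
    hit <- vapply(l2$code, function(cd) {
      blk <- spikegibbs:::decode_block(cd, 3, 2)
      all(blk[cbind(m[, 1], m[, 2] + 1)] == 1)
    }, logical(1))
    expect_equal(unname(st$averages[l]), sum(l2$prob[hit]))
  }
})

test_that("potential files parse the grammar and round trip losslessly", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("h=-0.5 : w0(0) w1(1)", f)
  p <- parse_potential_file(f)
  expect_equal(unname(p$h), -0.5)
  expect_equal(names(p$h), "w0(0)w1(1)")
  pw <- build_potential("pairwise", 2, 2)
  pw$h[] <- stats::rnorm(7)
  write_potential_file(pw, f)
  p2 <- parse_potential_file(f)
  expect_equal(p2$h, pw$h)
  expect_equal(p2$monomials, pw$monomials)
  writeLines(c("h=1 : w0(0)", "h=2 : w0(0)"), f)
  expect_error(parse_potential_file(f), "duplicate")
  writeLines("h=1 : w0(0) bogus", f)
  expect_error(parse_potential_file(f), "unknown token")
  writeLines("h=1 : w0(3)", f)
  expect_error(parse_potential_file(f, range = 2), "range")
})
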