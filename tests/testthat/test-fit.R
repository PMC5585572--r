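test_that("the coordinate update has the stated arithmetic and fixed point", {
  h <- c(0.2, -0.1)
  expect_equal(update_sequential(h, 1, 0.4, 0.4), h)        # fixed point
  h2 <- update_sequential(h, 2, 0.75, 0.5)
  expect_equal(h2[2], -0.1 + log(3))
  expect_equal(h2[1], h[1])
  expect_error(update_sequential(h, 1, 0, 0.5), "inside")
})

test_that("the parallel update reduces to the sequential step and respects damping", {
  h <- c(0.3)
  expect_equal(update_parallel(h, 0.75, 0.5, damping = 1),
               update_sequential(h, 1, 0.75, 0.5))
  h3 <- c(0, 0, 0)
  pi_v <- c(0.6, 0.6, 0.6); mu_v <- c(0.5, 0.5, 0.5)
  expect_equal(update_parallel(h3, pi_v, mu_v, damping = 0.5),
               0.5 * log(0.6 * 0.5 / (0.5 * 0.4)) + h3)
  expect_equal(update_parallel(h3, mu_v, mu_v, damping = 0.3), h3)
})

test_that("hellinger error is a symmetric distance, zero at equality, one at opposition", {
  expect_equal(hellinger_error(c(0.2, 0.7), c(0.2, 0.7)), 0)
  expect_equal(hellinger_error(c(1, 1), c(0, 0)), 1)
  set.seed(103)
  for (k in 1:30) {
    a <- stats::runif(5); b <- stats::runif(5)
    expect_equal(hellinger_error(a, b), hellinger_error(b, a))
    expect_gte(hellinger_error(a, b), 0)
    expect_lte(hellinger_error(a, b), 1)
  }
  expect_error(hellinger_error(c(0.5), c(0.5, 0.5)), "length")
})

test_that("linear response is exact at zero step and diagonal for independent monomials", {
  mu <- c(0.3, 0.6)
  C <- diag(c(0.21, 0.24))
  expect_equal(linear_response(mu, C, c(0, 0)), mu)
  moved <- linear_response(mu, C, c(0.5, 0))
  expect_equal(moved[2], 0.6)
  expect_gt(moved[1], 0.3)
  expect_error(linear_response(mu, C, c(1, 2, 3)), "dimension")
})

test_that("linear response predicts exact-engine averages to first order", {
  pot <- build_potential("bernoulli", 2)
  pot$h[] <- c(0.3, -0.4)
  ch <- build_chain(pot)
  mu0 <- exact_averages(ch, pot$monomials)
  # exact covariance of independent Bernoulli features
  C <- diag(mu0 * (1 - mu0))
  errs <- vapply(c(0.2, 0.1, 0.05), function(step) {
    dh <- c(step, -step)
    pred <- linear_response(mu0, C, dh)
    pot2 <- pot; pot2$h <- pot$h + dh
    truth <- exact_averages(build_chain(pot2), pot2$monomials)
    max(abs(pred - truth))
  }, numeric(1))
  # quadratic remainder: quartering with each halving of the step
  expect_lt(errs[2], errs[1] / 3)
  expect_lt(errs[3], errs[2] / 3)
})

test_that("fitting a symmetric target returns coefficients near zero", {
  r <- make_periodic_raster(3, 4000, period = 2, phase = c(1, 2, 1))
  # rates are exactly 1/2 for each neuron
  f <- fit_maxent(r, "bernoulli",
                  fit_config(engine = "exact", convergence_bound = 1e-8))
  expect_lt(max(abs(coef(f))), 1e-3)
})

test_that("Bernoulli fits recover generating parameters on exact samples", {
  truth <- build_potential("bernoulli", 3)
  truth$h[] <- c(-1, 0, 1)
  r <- sample_chain(build_chain(truth), 50000, seed = 107)
  f <- fit_maxent(r, "bernoulli",
                  fit_config(engine = "exact", convergence_bound = 1e-7))
  expect_lt(max(abs(coef(f) - truth$h)), 0.1)
  expect_equal(unname(residuals(f)), unname(f$pi - f$mu))
  expect_lt(max(abs(residuals(f))), 1e-4)
})

test_that("Ising fits recover the coupling from a long sample", {
  truth <- build_potential("ising", 2)
  truth$h[] <- c(-0.4, 0.2, 0.6)
  r <- sample_chain(build_chain(truth), 100000, seed = 109)
  f <- fit_maxent(r, "ising",
                  fit_config(engine = "exact", convergence_bound = 1e-7,
                             n_parallel_iterations = 60,
                             n_sequential_iterations = 150))
  expect_lt(abs(coef(f)[3] - 0.6), 0.15)
})

test_that("the tolerance filter drops rare monomials monotonically", {
  r <- spike_raster(list(c(1, 2, 3, 10), c(2, 11)), n_bins = 50)
  pot <- build_potential("ising", 2)
  f0 <- fit_maxent(r, pot, fit_config(tolerance_coefficient = 0,
                                      n_parallel_iterations = 2,
                                      n_sequential_iterations = 0))
  # pair w0(0)w1(0) occurs once (bin 2): kept at tol 0, dropped at tol 1
  expect_length(f0$dropped, 0)
  f1 <- fit_maxent(r, pot, fit_config(tolerance_coefficient = 1,
                                      n_parallel_iterations = 2,
                                      n_sequential_iterations = 0))
  expect_true("w0(0)w1(0)" %in% f1$dropped)
  f3 <- fit_maxent(r, pot, fit_config(tolerance_coefficient = 3,
                                      n_parallel_iterations = 2,
                                      n_sequential_iterations = 0))
  expect_true(all(f1$dropped %in% f3$dropped))
  empty <- spike_raster(list(1, integer(0)), n_bins = 30)
  expect_error(fit_maxent(empty, pot,
                          fit_config(tolerance_coefficient = 100)),
               "filtered")
})

test_that("the Monte-Carlo engine converges on a small Bernoulli problem", {
  truth <- build_potential("bernoulli", 2)
  truth$h[] <- c(-0.8, 0.5)
  r <- sample_chain(build_chain(truth), 30000, seed = 113)
  f <- fit_maxent(r, "bernoulli",
                  fit_config(engine = "monte_carlo", seed = 1,
                             mc_raster_length = 20000,
                             convergence_bound = 5e-3,
                             n_parallel_iterations = 25,
                             n_sequential_iterations = 25))
  expect_lt(max(abs(coef(f) - truth$h)), 0.25)
  expect_gt(length(f$trace), 1)
})

test_that("identical configurations reproduce identical Monte-Carlo traces", {
  r <- make_poisson_raster(2, 5000, rates = c(0.2, 0.4), seed = 127)
  cfg <- fit_config(engine = "monte_carlo", seed = 42,
                    mc_raster_length = 4000,
                    n_parallel_iterations = 6, n_sequential_iterations = 4)
  f1 <- fit_maxent(r, "bernoulli", cfg)
  f2 <- fit_maxent(r, "bernoulli", cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(coef(f1), coef(f2))
})

test_that("maxent_fit methods expose the model surface", {
  r <- make_poisson_raster(2, 4000, rates = c(0.3, 0.5), seed = 131)
  f <- fit_maxent(r, "ising", fit_config(engine = "exact"))
  expect_named(coef(f))
  expect_s3_class(f, "maxent_fit")
  expect_output(print(f), "maxent_fit")
  sim <- simulate(f, n_bins = 2000, seed = 3)
  expect_s3_class(sim, "spike_raster")
  expect_equal(sim$n_neurons, 2L)
  sims <- simulate(f, nsim = 2, n_bins = 500, seed = 4)
  expect_length(sims, 2)
  expect_equal(unname(fitted(f)), unname(f$mu))
})
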