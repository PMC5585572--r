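#' Fitting hyper-parameters for maximum-entropy estimation
#'
#' Bundles the knobs of the iterative entropy-maximization procedure.
#'
#' @param convergence_bound stop when the Hellinger error between empirical
#'   and model monomial averages falls below this bound.
#' @param tolerance_coefficient drop monomials observed at most this many
#'   times in the raster before fitting (0 drops only never-observed
#'   monomials).
#' @param mc_raster_length length of the Monte-Carlo raster used to
#'   estimate model averages (Monte-Carlo engine only).
#' @param spike_flips average Metropolis proposals per (neuron, bin) per
#'   sweep.
#' @param mc_burn_in Metropolis sweeps per re-sampling.
#' @param delta when the proposed coefficient step has sup-norm below
#'   `delta`, model averages are updated by linear response instead of
#'   re-sampling (Monte-Carlo engine).
#' @param n_parallel_iterations damped parallel (all-coordinates) updates.
#' @param n_sequential_iterations single-coordinate updates applied after
#'   the parallel phase, cycling through the monomials; better for
#'   fine-tuning.
#' @param damping scale of the parallel step; default `NULL` uses
#'   `1 / R_active`, where `R_active` is the largest number of monomials
#'   simultaneously active on any window of the data.
#' @param max_coefficient clamp on `|h_l|`; hitting it flags divergence.
#' @param seed master seed for the engine's stochastic steps.
#' @param engine `"auto"` (exact when the state space permits, else
#'   Monte Carlo), `"exact"`, or `"monte_carlo"`.
#' @param max_bits state-space cap passed to [build_chain()].
#' @return a `fit_config` list.
#' @export
fit_config <- function(convergence_bound = 1e-3,
                       tolerance_coefficient = 0,
                       mc_raster_length = 10000,
                       spike_flips = 1,
                       mc_burn_in = 30,
                       delta = 0.05,
                       n_parallel_iterations = 40,
                       n_sequential_iterations = 60,
                       damping = NULL,
                       max_coefficient = 20,
                       seed = NULL,
                       engine = c("auto", "exact", "monte_carlo"),
                       max_bits = 14) {
  engine <- match.arg(engine)
  stopifnot(convergence_bound > 0, tolerance_coefficient >= 0,
            mc_raster_length >= 1, spike_flips >= 1, delta > 0,
            n_parallel_iterations >= 0, n_sequential_iterations >= 0,
            max_coefficient > 0)
  structure(list(convergence_bound = convergence_bound,
                 tolerance_coefficient = as.integer(tolerance_coefficient),
                 mc_raster_length = as.integer(mc_raster_length),
                 spike_flips = spike_flips,
                 mc_burn_in = as.integer(mc_burn_in),
                 delta = delta,
                 n_parallel_iterations = as.integer(n_parallel_iterations),
                 n_sequential_iterations = as.integer(n_sequential_iterations),
                 damping = damping, max_coefficient = max_coefficient,
                 seed = seed, engine = engine, max_bits = max_bits),
            class = "fit_config")
}

clamp01 <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

#' Hellinger error between empirical and model monomial averages
#'
#' Mean over monomials of the Bernoulli Hellinger distance
#' \deqn{H_l = \frac{1}{\sqrt 2}\sqrt{(\sqrt{\pi_l}-\sqrt{\mu_l})^2 +
#'   (\sqrt{1-\pi_l}-\sqrt{1-\mu_l})^2}.}
#' Zero iff the vectors agree; 1 when every pair is maximally distinct.
#' This is the canonical convergence metric of [fit_maxent()].
#'
#' @param p,q vectors of probabilities in `[0, 1]`, equal length.
#' @return scalar in `[0, 1]`.
#' @export
hellinger_error <- function(p, q) {
  if (length(p) != length(q)) stop("length mismatch")
  if (any(p < 0 | p > 1 | q < 0 | q > 1)) stop("entries must be in [0, 1]")
  mean(sqrt((sqrt(p) - sqrt(q))^2 + (sqrt(1 - p) - sqrt(1 - q))^2) / sqrt(2))
}

#' Single-coordinate maximum-entropy update
#'
#' The standard coordinate step matching one empirical average:
#' \deqn{h_l' = h_l + \log\frac{\pi_l (1-\mu_l)}{\mu_l (1-\pi_l)}.}
#' `pi_l = mu_l` is its fixed point.
#'
#' @param h coefficient vector.
#' @param l coordinate to update.
#' @param pi_l empirical average (clamped to (0, 1)).
#' @param mu_l current model average (clamped to (0, 1)).
#' @return updated coefficient vector.
#' @export
update_sequential <- function(h, l, pi_l, mu_l) {
  if (pi_l <= 0 || pi_l >= 1 || mu_l <= 0 || mu_l >= 1)
    stop("pi_l and mu_l must be strictly inside (0, 1); clamp first")
  h[l] <- h[l] + log(pi_l * (1 - mu_l) / (mu_l * (1 - pi_l)))
  h
}

#' Damped parallel maximum-entropy update
#'
#' Applies the [update_sequential()] increment to every coordinate
#' simultaneously, scaled by `damping`. With features that can be
#' simultaneously active, an undamped joint step overshoots; damping by the
#' reciprocal of the maximal number of co-active monomials restores
#' stability.
#'
#' @param h coefficient vector.
#' @param pi_vec,mu_vec empirical and model average vectors, strictly
#'   inside (0, 1).
#' @param damping step scale in (0, 1].
#' @return updated coefficient vector.
#' @export
update_parallel <- function(h, pi_vec, mu_vec, damping = 1) {
  if (length(pi_vec) != length(mu_vec) || length(h) != length(pi_vec))
    stop("length mismatch")
  if (any(pi_vec <= 0 | pi_vec >= 1 | mu_vec <= 0 | mu_vec >= 1))
    stop("averages must be strictly inside (0, 1); clamp first")
  h + damping * log(pi_vec * (1 - mu_vec) / (mu_vec * (1 - pi_vec)))
}

#' Linear-response update of model averages
#'
#' First-order prediction of the model monomial averages after a small
#' coefficient change `dh`, using the monomial covariance matrix
#' `C[l, k] = mu[m_l m_k] - mu[m_l] mu[m_k]`:
#' `mu' = clamp(mu + C dh)`. Used by the Monte-Carlo engine to avoid
#' re-sampling when steps are small.
#'
#' @param mu current model averages.
#' @param corr_matrix monomial covariance matrix.
#' @param dh coefficient increment.
#' @param eps clamping margin.
#' @return updated average vector.
#' @export
linear_response <- function(mu, corr_matrix, dh, eps = 1e-8) {
  if (length(dh) != length(mu) || !all(dim(corr_matrix) == length(mu)))
    stop("dimension mismatch between mu, corr_matrix and dh")
  clamp01(mu + as.vector(corr_matrix %*% dh), eps)
}

# Covariance of monomial indicators over windows of a raster.
monomial_covariance <- function(raster, potential) {
  ind <- monomial_indicators(raster, potential)
  nw <- ncol(ind)
  mu <- rowMeans(ind)
  (ind %*% t(ind)) / nw - tcrossprod(mu)
}

subset_potential <- function(potential, keep) {
  gibbs_potential(unname(potential$h[keep]), potential$monomials[keep],
                  n_neurons = potential$n_neurons, range = potential$range)
}

#' Fit a maximum-entropy Gibbs model to a spike raster
#'
#' Estimates the coefficients \eqn{h_l} of a Gibbs potential
#' \eqn{\phi = \sum_l h_l m_l} by maximizing statistical entropy under the
#' constraints that model monomial averages \eqn{\mu[m_l]} match the
#' empirical averages \eqn{\pi[m_l]} of the raster (equivalently, by
#' minimizing the Kullback-Leibler divergence from the empirical measure).
#' Coefficients start at 0 — an independent fair-coin model — unless the
#' supplied potential carries non-zero values (warm start). Each iteration
#' evaluates the current model averages (exactly via the transfer matrix
#' when the state space is small, else on a Metropolis-sampled raster of
#' `mc_raster_length` bins), records the Hellinger error, and applies
#' damped parallel then single-coordinate updates. In the Monte-Carlo
#' engine, steps smaller than `delta` update the averages by
#' [linear_response()] instead of re-sampling.
#'
#' @param raster a [spike_raster()] with `n_bins >= range`.
#' @param model a [gibbs_potential()] (possibly from [build_potential()] or
#'   a potential file), or a model type string accepted by
#'   [build_potential()].
#' @param config a [fit_config()].
#' @param range model range when `model` is given as a type string.
#' @return an object of class `maxent_fit`; see [coef.maxent_fit()],
#'   [residuals.maxent_fit()], [simulate.maxent_fit()],
#'   [plot.maxent_fit()].
#' @examples
#' set.seed(1)
#' r <- make_poisson_raster(3, 5000, rates = c(0.2, 0.4, 0.6))
#' f <- fit_maxent(r, "bernoulli")
#' coef(f)           # close to logit of the rates
#' @export
fit_maxent <- function(raster, model, config = fit_config(), range = 1) {
  stopifnot(inherits(raster, "spike_raster"))
  if (is.character(model))
    model <- build_potential(model, raster$n_neurons, range)
  stopifnot(inherits(model, "gibbs_potential"))
  if (model$n_neurons != raster$n_neurons)
    stop("model and raster disagree on the number of neurons")
  if (raster$n_bins < model$range) stop("raster shorter than model range")
  if (!is.null(config$seed)) set.seed(config$seed)

  emp <- empirical_averages(raster, model)
  keep <- emp$counts > config$tolerance_coefficient
  dropped <- names(model$h)[!keep]
  if (!any(keep))
    stop("all monomials filtered out by tolerance_coefficient = ",
         config$tolerance_coefficient)
  pot <- subset_potential(model, keep)
  pi_raw <- emp$averages[keep]
  eps <- 1 / (2 * emp$n_windows)
  pi_cl <- clamp01(pi_raw, eps)

  engine <- config$engine
  small <- pot$n_neurons * max(pot$range - 1L, 1L) <= config$max_bits
  if (engine == "auto") engine <- if (small) "exact" else "monte_carlo"
  if (engine == "exact" && !small)
    stop("exact engine requested but the state space exceeds the cap")

  damping <- config$damping
  if (is.null(damping)) {
    ind <- monomial_indicators(raster, pot)
    r_active <- max(1L, max(colSums(ind)))
    damping <- 1 / r_active
  }

  h <- unname(pot$h)
  L <- length(h)
  mc_raster <- NULL
  mu <- NULL
  need_sample <- TRUE

  model_averages <- function() {
    if (engine == "exact") {
      cur <- subset_potential(pot, seq_len(L))
      cur$h[] <- h
      ch <- build_chain(cur, max_bits = config$max_bits)
      clamp01(exact_averages(ch, cur$monomials), eps)
    } else {
      cur <- subset_potential(pot, seq_len(L))
      cur$h[] <- h
      mc_raster <<- sample_metropolis(cur, config$mc_raster_length,
                                      burn_in = config$mc_burn_in,
                                      flips_per_neuron = config$spike_flips)
      clamp01(empirical_averages(mc_raster, cur)$averages, eps)
    }
  }

  trace <- numeric(0)
  diverged <- FALSE
  total <- config$n_parallel_iterations + config$n_sequential_iterations
  seq_cursor <- 0L
  for (it in seq_len(total + 1L)) {
    if (need_sample || engine == "exact") {
      mu <- unname(model_averages())
      need_sample <- FALSE
    }
    err <- hellinger_error(pi_cl, mu)
    trace <- c(trace, err)
    if (err < config$convergence_bound || it > total) break
    if (it <= config$n_parallel_iterations) {
      h_new <- update_parallel(h, pi_cl, mu, damping)
    } else {
      seq_cursor <- seq_cursor %% L + 1L
      h_new <- update_sequential(h, seq_cursor, pi_cl[seq_cursor],
                                 mu[seq_cursor])
    }
    dh <- h_new - h
    h <- pmin(pmax(h_new, -config$max_coefficient), config$max_coefficient)
    if (any(abs(h_new) > config$max_coefficient)) diverged <- TRUE
    if (engine == "monte_carlo") {
      if (max(abs(dh)) < config$delta && !is.null(mc_raster)) {
        cur <- subset_potential(pot, seq_len(L))
        cur$h[] <- h
        C <- monomial_covariance(mc_raster, cur)
        mu <- unname(linear_response(mu, C, dh, eps))
      } else {
        need_sample <- TRUE
      }
    }
  }

  pot$h[] <- h
  structure(list(potential = pot, pi = pi_cl, mu = stats::setNames(
                   mu, names(pot$h)),
                 trace = trace, dropped = dropped, config = config,
                 engine = engine, damping = damping,
                 n_windows = emp$n_windows, diverged = diverged,
                 n_neurons = raster$n_neurons, raster_bins = raster$n_bins),
            class = "maxent_fit")
}

#' @export
print.maxent_fit <- function(x, ...) {
  cat(sprintf(
    "maxent_fit: %d monomials (N = %d, R = %d), engine = %s\n",
    length(x$potential$h), x$potential$n_neurons, x$potential$range,
    x$engine))
  cat(sprintf("Hellinger error: %.4g after %d iterations%s\n",
              utils::tail(x$trace, 1), length(x$trace),
              if (x$diverged) " [coefficient clamp hit]" else ""))
  if (length(x$dropped))
    cat("dropped (tolerance filter):", length(x$dropped), "monomials\n")
  invisible(x)
}

#' @export
summary.maxent_fit <- function(object, ...) {
  print(object)
  tab <- data.frame(h = coef(object), empirical = object$pi,
                    model = object$mu,
                    row.names = names(object$potential$h))
  cat("\nLeading coefficients:\n")
  print(utils::head(tab[order(-abs(tab$h)), ], 10), digits = 4)
  invisible(tab)
}

#' Fitted potential coefficients
#' @param object a [fit_maxent()] result.
#' @param ... unused.
#' @return named numeric vector \eqn{h_l}.
#' @export
coef.maxent_fit <- function(object, ...) object$potential$h

#' Constraint residuals of a maximum-entropy fit
#'
#' Differences \eqn{\pi[m_l] - \mu[m_l]} between the empirical constraint
#' targets and the fitted model averages.
#'
#' @param object a [fit_maxent()] result.
#' @param ... unused.
#' @return named numeric vector.
#' @export
residuals.maxent_fit <- function(object, ...) object$pi - object$mu

#' @export
fitted.maxent_fit <- function(object, ...) object$mu

#' Simulate rasters from a fitted maximum-entropy model
#'
#' Samples spike rasters from the fitted Gibbs distribution: exactly via
#' the transfer-matrix chain when the state space permits, otherwise by
#' Metropolis spike flips.
#'
#' @param object a [fit_maxent()] result.
#' @param nsim number of rasters.
#' @param seed optional integer seed.
#' @param n_bins raster length (default: length of the fitted raster).
#' @param ... unused.
#' @return a list of [spike_raster()]s (a single raster when `nsim = 1`).
#' @export
simulate.maxent_fit <- function(object, nsim = 1, seed = NULL,
                                n_bins = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_bins)) n_bins <- object$raster_bins
  small <- object$potential$n_neurons *
    max(object$potential$range - 1L, 1L) <= object$config$max_bits
  out <- vector("list", nsim)
  if (small) {
    ch <- build_chain(object$potential, max_bits = object$config$max_bits)
    for (k in seq_len(nsim)) out[[k]] <- sample_chain(ch, n_bins)
  } else {
    for (k in seq_len(nsim))
      out[[k]] <- sample_metropolis(object$potential, n_bins,
                                    burn_in = object$config$mc_burn_in,
                                    flips_per_neuron = object$config$spike_flips)
  }
  if (nsim == 1) out[[1]] else out
}

#' Diagnostic plots for a maximum-entropy fit
#'
#' `which = "trace"` draws the Hellinger error against iterations;
#' `which = "averages"` draws fitted model averages against their
#' empirical targets.
#'
#' @param x a [fit_maxent()] result.
#' @param which `"trace"` or `"averages"`.
#' @param ... passed to the underlying plot call.
#' @export
plot.maxent_fit <- function(x, which = c("trace", "averages"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    graphics::plot(seq_along(x$trace), x$trace, type = "b", log = "y",
                   xlab = "iteration", ylab = "Hellinger error", ...)
  } else {
    graphics::plot(x$pi, x$mu, xlab = "empirical average pi[m_l]",
                   ylab = "model average mu[m_l]", ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
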