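#' Block entropies of a raster
#'
#' Plug-in Shannon entropies (nats) of the empirical distribution of
#' spatio-temporal spike blocks of lengths `1..n_max`, optionally with the
#' Miller-Madow small-sample correction `(K - 1) / (2 n)` added (`K`
#' observed patterns, `n` windows), which removes the leading downward
#' bias of the plug-in estimator.
#'
#' @param raster a [spike_raster()].
#' @param n_max maximal block length.
#' @param miller_madow apply the bias correction (default `TRUE`).
#' @return numeric vector `H[n]`, `n = 1..n_max`.
#' @export
block_entropies <- function(raster, n_max, miller_madow = TRUE) {
  bp <- block_probabilities(raster, n_max)
  vapply(seq_len(n_max), function(len) {
    p <- bp$prob[bp$length == len]
    H <- -sum(p * log(p))
    if (miller_madow) H <- H + (length(p) - 1) / (2 * bp$n_windows[
      bp$length == len][1])
    H
  }, numeric(1))
}

#' Empirical entropy rate by block-entropy extrapolation
#'
#' Estimates the entropy rate of a stationary raster from the growth of
#' block entropies: `H_n` is computed for `n = 1..n_max` and a least-squares
#' line through the last `fit_points` (n, H_n) pairs is fitted; its slope
#' is the entropy-rate estimate (the asymptotic per-step increment of block
#' entropy).
#'
#' @inheritParams block_entropies
#' @param fit_points number of trailing points used for the linear fit
#'   (default 3).
#' @return scalar entropy rate in nats per time bin.
#' @export
entropy_rate <- function(raster, n_max = 6, fit_points = 3,
                         miller_madow = TRUE) {
  n_max <- as.integer(n_max)
  if (n_max < 2) stop("n_max must be >= 2")
  if (n_max > raster$n_bins) stop("raster too short for n_max")
  H <- block_entropies(raster, n_max, miller_madow)
  k <- min(fit_points, n_max)
  n <- seq_len(n_max)
  idx <- (n_max - k + 1):n_max
  unname(stats::coef(stats::lm(H[idx] ~ n[idx]))[2])
}

#' Kullback-Leibler divergence estimate between data and model
#'
#' Estimates `KL(pi || mu)` between the empirical measure of a raster and a
#' Gibbs model through the thermodynamic identity
#' \deqn{KL = P(\phi) - \pi(\phi) - S(\pi),}
#' where `P(phi)` is the model pressure (log Perron eigenvalue),
#' `pi(phi) = sum_l h_l pi[m_l]` the empirical per-window average of the
#' potential, and `S(pi)` the empirical entropy rate from block-entropy
#' extrapolation ([entropy_rate()]). The raw value is reported unfloored so
#' estimation bias stays visible; a floored-at-zero convenience value is
#' included.
#'
#' @param raster a [spike_raster()].
#' @param potential a [gibbs_potential()] small enough for the exact
#'   engine.
#' @param n_max maximal block length for the entropy extrapolation.
#' @param miller_madow bias-correct the block entropies.
#' @param max_bits state-space cap for [build_chain()].
#' @return list with `kl`, `kl_floored`, `pressure`, `pi_phi`,
#'   `entropy_rate`.
#' @export
kl_estimate <- function(raster, potential, n_max = 6, miller_madow = TRUE,
                        max_bits = 14) {
  stopifnot(inherits(raster, "spike_raster"),
            inherits(potential, "gibbs_potential"))
  if (n_max > raster$n_bins)
    stop("raster too short for block length n_max = ", n_max)
  ch <- build_chain(potential, max_bits = max_bits)
  emp <- empirical_averages(raster, potential)
  pi_phi <- sum(potential$h * emp$averages)
  S <- entropy_rate(raster, n_max = n_max, miller_madow = miller_madow)
  kl <- ch$pressure - pi_phi - S
  list(kl = kl, kl_floored = max(0, kl), pressure = ch$pressure,
       pi_phi = pi_phi, entropy_rate = S)
}

#' Confidence plot of empirical vs model block probabilities
#'
#' For every spike block observed in the raster (lengths `1..max_len`),
#' pairs the empirical probability `p_hat` with the model probability `p`
#' and the central-limit-theorem standard error
#' `sigma_l = sqrt(p_hat (1 - p_hat) / n_windows)`. Points whose empirical
#' probability lies within `3 sigma_l` of the model value fall inside the
#' confidence region; under a perfect model approximately 99.7% of points
#' do. The `c_plus`/`c_minus` columns are the `p +/- 3 sigma` bound
#' curves, clipped to (0, 1].
#'
#' @param raster a [spike_raster()].
#' @param model a [build_chain()] result (exact model probabilities) or a
#'   long model-sampled [spike_raster()] (empirical model probabilities).
#' @param max_len maximal pattern length.
#' @param sigma `"empirical"` (from `p_hat`, default) or `"model"` (from
#'   `p`).
#' @return a data frame of class `confidence_plot` with columns `length`,
#'   `pattern`, `empirical`, `model`, `sigma`, `c_plus`, `c_minus`,
#'   `inside`; attribute `coverage` gives the percentage inside.
#' @export
confidence_plot <- function(raster, model, max_len = 2,
                            sigma = c("empirical", "model")) {
  sigma <- match.arg(sigma)
  stopifnot(inherits(raster, "spike_raster"))
  bp <- block_probabilities(raster, max_len)
  if (inherits(model, "gibbs_chain")) {
    if (model$n_neurons != raster$n_neurons)
      stop("model and raster disagree on the number of neurons")
    p_model <- numeric(nrow(bp))
    for (len in unique(bp$length)) {
      sel <- bp$length == len
      if (len <= model$range) {
        dist <- exact_block_distribution(model, len)
        p_model[sel] <- dist[bp$code[sel] + 1]
      } else {
        p_model[sel] <- vapply(bp$code[sel], function(cd)
          exact_block_probability(model, cd, len = len), numeric(1))
      }
    }
  } else if (inherits(model, "spike_raster")) {
    mbp <- block_probabilities(model, max_len)
    key <- paste(bp$length, bp$code)
    mkey <- paste(mbp$length, mbp$code)
    p_model <- mbp$prob[match(key, mkey)]
    p_model[is.na(p_model)] <- 0
  } else stop("'model' must be a gibbs_chain or a spike_raster")
  zero <- p_model <= 0
  if (any(zero)) {
    warning(sum(zero), " observed blocks have zero model probability; ",
            "excluded")
    bp <- bp[!zero, ]; p_model <- p_model[!zero]
  }
  se <- if (sigma == "empirical") {
    sqrt(bp$prob * (1 - bp$prob) / bp$n_windows)
  } else {
    sqrt(p_model * (1 - p_model) / bp$n_windows)
  }
  out <- data.frame(length = bp$length, pattern = bp$pattern,
                    empirical = bp$prob, model = p_model, sigma = se,
                    c_plus = pmin(p_model + 3 * se, 1),
                    c_minus = pmax(p_model - 3 * se, .Machine$double.xmin),
                    inside = abs(bp$prob - p_model) <= 3 * se,
                    stringsAsFactors = FALSE)
  class(out) <- c("confidence_plot", "data.frame")
  attr(out, "coverage") <- 100 * mean(out$inside)
  out
}

#' @export
print.confidence_plot <- function(x, ...) {
  cat(sprintf("confidence_plot: %d observed blocks, %.2f%% inside the 3-sigma region\n",
              nrow(x), attr(x, "coverage")))
  NextMethod()
}

#' Draw a confidence plot
#'
#' Log-log scatter of empirical vs model block probabilities with the
#' diagonal and the 3-sigma bound band.
#'
#' @param x a [confidence_plot()] result.
#' @param ... passed to `plot`.
#' @export
plot.confidence_plot <- function(x, ...) {
  graphics::plot(x$empirical, x$model, log = "xy",
                 col = ifelse(x$inside, "black", "red"),
                 xlab = "empirical block probability",
                 ylab = "model block probability", ...)
  graphics::abline(0, 1, untf = TRUE, lty = 2)
  ord <- order(x$model)
  graphics::lines(x$c_plus[ord], x$model[ord], col = "grey50")
  graphics::lines(pmax(x$c_minus[ord], .Machine$double.xmin), x$model[ord],
                  col = "grey50")
  invisible(x)
}
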