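#' Sample a raster exactly from a Gibbs chain
#'
#' Draws the initial memory block from the invariant distribution `mu` and
#' every subsequent spike column from the chain's transition probabilities,
#' so the output raster is an exact sample of the stationary Gibbs
#' distribution. Reproducible per seed.
#'
#' @param chain a [build_chain()] result.
#' @param n_bins raster length `T` (>= chain memory `D`).
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param bin_ms bin width of the output raster.
#' @return a [spike_raster()] with `N` neurons and `T` bins.
#' @export
sample_chain <- function(chain, n_bins, seed = NULL, bin_ms = 1) {
  stopifnot(inherits(chain, "gibbs_chain"))
  if (!is.null(seed)) set.seed(seed)
  N <- chain$n_neurons
  TT <- as.integer(n_bins)
  D <- chain$memory
  if (TT < max(D, 1L)) stop("n_bins must be at least the chain memory")
  if (D == 0L) {
    cols <- sample.int(length(chain$col_prob), TT, replace = TRUE,
                       prob = chain$col_prob) - 1L
  } else {
    w0 <- sample.int(chain$n_states, 1L, prob = chain$mu) - 1L
    cumP <- t(apply(chain$transition, 1, cumsum))
    if (chain$n_states == 1L) cumP <- matrix(cumP, nrow = 1L)
    sampled <- cpp_chain_sample(cumP, chain$next_state, w0, TT - D)
    init_cols <- integer(D)
    cc <- w0
    for (s in seq_len(D)) {
      init_cols[s] <- cc %% 2L^N
      cc <- cc %/% 2L^N
    }
    cols <- c(init_cols, sampled)
  }
  mat <- matrix(0L, N, TT)
  for (i in seq_len(N))
    mat[i, ] <- as.integer(bitwAnd(cols, bitwShiftL(1L, i - 1L)) > 0L)
  raster_from_matrix(mat, bin_ms = bin_ms)
}

#' Sample a raster from a Gibbs potential by spike-flip Metropolis
#'
#' Targets the finite-window Gibbs measure proportional to
#' `exp(sum_windows phi)`. Starting from an independent fair-coin raster,
#' each sweep proposes `flips_per_neuron * N * T` single-bit flips at
#' uniformly random (neuron, bin) positions, accepting with probability
#' `min(1, exp(deltaE))` where the energy change is computed from only the
#' windows overlapping the flipped bin. The raster after `burn_in` sweeps
#' is returned whole.
#'
#' @param potential a [gibbs_potential()].
#' @param n_bins raster length `T` (>= range `R`).
#' @param burn_in number of sweeps before returning (default 100).
#' @param flips_per_neuron average proposals per (neuron, bin) per sweep.
#' @param seed optional integer seed.
#' @param bin_ms bin width of the output raster.
#' @return a [spike_raster()].
#' @export
sample_metropolis <- function(potential, n_bins, burn_in = 100,
                              flips_per_neuron = 1, seed = NULL,
                              bin_ms = 1) {
  stopifnot(inherits(potential, "gibbs_potential"))
  TT <- as.integer(n_bins)
  if (TT < potential$range) stop("n_bins must be >= potential range")
  if (!is.null(seed)) set.seed(seed)
  N <- potential$n_neurons
  init <- matrix(as.integer(stats::runif(N * TT) < 0.5), N, TT)
  events0 <- lapply(potential$monomials, function(m)
    cbind(m[, "neuron"] - 1L, m[, "tau"]))
  out <- cpp_metropolis_raster(init, unname(potential$h), events0,
                               potential$range, as.integer(burn_in),
                               flips_per_neuron)
  raster_from_matrix(out, bin_ms = bin_ms)
}

#' Energy change of a single spike flip
#'
#' Exact difference `energy(after flip) - energy(before flip)` for
#' toggling neuron `neuron` at bin `t`, computed from only the potential
#' terms whose windows cover the flipped bin. This is the efficiency core
#' of the Metropolis sampler and agrees with a global energy
#' recomputation.
#'
#' @param potential a [gibbs_potential()].
#' @param raster a [spike_raster()].
#' @param neuron neuron index (1-based).
#' @param t time bin (1-based).
#' @return scalar energy difference.
#' @export
local_energy_delta <- function(potential, raster, neuron, t) {
  stopifnot(inherits(potential, "gibbs_potential"),
            inherits(raster, "spike_raster"))
  if (neuron < 1 || neuron > raster$n_neurons) stop("neuron out of range")
  if (t < 1 || t > raster$n_bins) stop("time bin out of range")
  events0 <- lapply(potential$monomials, function(m)
    cbind(m[, "neuron"] - 1L, m[, "tau"]))
  cpp_local_energy_delta(as.matrix(raster), unname(potential$h), events0,
                         potential$range, neuron - 1L, t - 1L)
}
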