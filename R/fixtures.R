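#' Deterministic toy-data generators
#'
#' Self-contained generators of rasters, white-noise stimuli and
#' linear-nonlinear (LN) model spikes, so every analysis can be exercised
#' without recorded data. All are reproducible per seed.
#'
#' @name fixtures
NULL

#' Independent Bernoulli (Poisson-like) raster
#'
#' Each neuron spikes independently in every bin with its own probability,
#' i.e. a discrete-time homogeneous Poisson approximation.
#'
#' @param n_neurons number of neurons.
#' @param n_bins raster length.
#' @param rates per-bin spike probability, recycled over neurons; all in
#'   `[0, 1]`.
#' @param seed optional integer seed.
#' @param bin_ms bin width in ms.
#' @return a [spike_raster()].
#' @export
make_poisson_raster <- function(n_neurons, n_bins, rates = 0.1,
                                seed = NULL, bin_ms = 1) {
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  rates <- rep_len(rates, n_neurons)
  spikes <- lapply(seq_len(n_neurons), function(i)
    which(stats::runif(n_bins) < rates[i]))
  spike_raster(spikes, n_bins = n_bins, bin_ms = bin_ms)
}

#' Strictly periodic raster
#'
#' @param n_neurons number of neurons.
#' @param n_bins raster length.
#' @param period spike period in bins, recycled over neurons.
#' @param phase first spike bin, recycled.
#' @param bin_ms bin width.
#' @return a [spike_raster()].
#' @export
make_periodic_raster <- function(n_neurons, n_bins, period, phase = 1,
                                 bin_ms = 1) {
  period <- rep_len(as.integer(period), n_neurons)
  phase <- rep_len(as.integer(phase), n_neurons)
  spikes <- lapply(seq_len(n_neurons), function(i)
    seq.int(phase[i], n_bins, by = period[i]))
  spike_raster(spikes, n_bins = n_bins, bin_ms = bin_ms)
}

#' White-noise stimulus with uniform time stamps
#'
#' Frames of i.i.d. pixels — binary checkerboard-style (each pixel 0 or 1
#' with probability 1/2) or Gaussian mapped into `[0, 1]` — plus the
#' matching uniformly spaced time-stamp series.
#'
#' @param width,height frame size in pixels.
#' @param n_frames number of frames.
#' @param mode `"binary"` (default) or `"gaussian"`.
#' @param display_ms frame duration / stamp spacing in ms.
#' @param seed optional integer seed.
#' @return list with `stimulus` (a [stimulus_sequence()]) and `timestamps`
#'   (a [timestamp_series()], onsets starting at 0).
#' @export
make_white_noise_stimulus <- function(width, height, n_frames,
                                      mode = c("binary", "gaussian"),
                                      display_ms = 100, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(width >= 1, height >= 1, n_frames >= 1)
  if (!is.null(seed)) set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(k) {
    if (mode == "binary") {
      matrix(as.numeric(stats::runif(height * width) < 0.5), height, width)
    } else {
      x <- matrix(stats::rnorm(height * width), height, width)
      stats::pnorm(x)               # probability-integral map into [0, 1]
    }
  })
  list(stimulus = stimulus_sequence(frames, display_ms = display_ms),
       timestamps = timestamp_series((seq_len(n_frames) - 1) * display_ms))
}

#' Spikes of a thresholded linear (LN) model neuron
#'
#' A single model neuron projects each stimulus frame onto a planted
#' spatial kernel and spikes — one raster bin per frame, at the frame's
#' temporal resolution — whenever the projection of the frame `lag_frames`
#' earlier exceeds a threshold (optionally thinned by a Bernoulli keep
#' probability). The planted kernel is recorded for recovery tests.
#'
#' @param stimulus a [stimulus_sequence()].
#' @param kernel numeric matrix of the stimulus frame size (the planted
#'   spatial filter).
#' @param threshold spiking threshold on the projection.
#' @param lag_frames temporal lag of the filter in frames (default 1).
#' @param keep_prob Bernoulli thinning probability (default 1).
#' @param seed optional integer seed.
#' @return a [spike_raster()] with one neuron, `n_bins` = number of
#'   frames, `bin_ms` = the frame duration; attribute `kernel` holds the
#'   planted filter.
#' @export
make_ln_spikes <- function(stimulus, kernel, threshold, lag_frames = 1,
                           keep_prob = 1, seed = NULL) {
  stopifnot(inherits(stimulus, "stimulus_sequence"))
  kernel <- as.matrix(kernel)
  if (!all(dim(kernel) == c(stimulus$height, stimulus$width)))
    stop("kernel dimensions must match the stimulus frames")
  if (!is.null(seed)) set.seed(seed)
  n_frames <- length(stimulus$frames)
  proj <- vapply(stimulus$frames, function(f) sum(f * kernel), numeric(1))
  spiking <- rep(FALSE, n_frames)
  idx <- seq_len(n_frames)
  src <- idx - lag_frames
  ok <- src >= 1
  spiking[ok] <- proj[src[ok]] >= threshold
  if (keep_prob < 1)
    spiking <- spiking & stats::runif(n_frames) < keep_prob
  if (!any(spiking)) {
    r <- spike_raster(list(integer(0)), n_bins = n_frames,
                      bin_ms = stimulus$display_ms)
  } else {
    r <- spike_raster(list(which(spiking)), n_bins = n_frames,
                      bin_ms = stimulus$display_ms)
  }
  attr(r, "kernel") <- kernel
  r
}
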