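#' Spike-train histograms
#'
#' Light container shared by [psth()], [isi()] and the correlograms:
#' `edges` (bin edges, ms or lag bins), `counts`, and a `normalization`
#' tag (`"counts"` or `"rate"`). `as.data.frame` and [write_histogram_csv()]
#' give tabular access.
#'
#' @param edges numeric bin edges, length `length(counts) + 1`.
#' @param counts numeric bin contents.
#' @param normalization `"counts"` or `"rate"`.
#' @param lag logical: edges are signed lags (correlograms).
#' @return an object of class `spike_histogram`.
#' @export
spike_histogram <- function(edges, counts, normalization = "counts",
                            lag = FALSE) {
  if (length(edges) != length(counts) + 1)
    stop("need length(edges) == length(counts) + 1")
  if (normalization == "counts" && any(counts < 0))
    stop("negative counts")
  structure(list(edges = edges, counts = counts,
                 normalization = normalization, lag = lag),
            class = "spike_histogram")
}

#' @export
print.spike_histogram <- function(x, ...) {
  cat(sprintf("spike_histogram: %d bins [%g, %g], total %g (%s)\n",
              length(x$counts), min(x$edges), max(x$edges),
              sum(x$counts), x$normalization))
  invisible(x)
}

#' @export
as.data.frame.spike_histogram <- function(x, ...) {
  data.frame(left = x$edges[-length(x$edges)], right = x$edges[-1],
             count = x$counts)
}

#' Export a histogram as CSV
#' @param hist a [spike_histogram()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(hist, path) {
  utils::write.csv(as.data.frame(hist), path, row.names = FALSE)
  invisible(path)
}

#' Peri-stimulus time histogram
#'
#' Pools the spikes of the selected neurons and counts them in time bins of
#' `bin_ms` milliseconds across the recording. Counts conserve the total
#' number of selected spikes.
#'
#' @param raster a [spike_raster()].
#' @param bin_ms histogram bin width in ms; must be at least the raster
#'   resolution.
#' @param neurons neuron indices to pool (default: all).
#' @return a [spike_histogram()] with edges in ms.
#' @export
psth <- function(raster, bin_ms = raster$bin_ms, neurons = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  if (bin_ms < raster$bin_ms)
    stop("bin_ms (", bin_ms, ") smaller than raster resolution (",
         raster$bin_ms, ")")
  if (is.null(neurons)) neurons <- seq_len(raster$n_neurons)
  if (length(neurons) == 0) stop("empty neuron selection")
  if (any(neurons < 1 | neurons > raster$n_neurons))
    stop("neuron index out of range")
  times <- (unlist(raster$spikes[neurons], use.names = FALSE) - 1) *
    raster$bin_ms
  total_ms <- raster$n_bins * raster$bin_ms
  edges <- seq(0, total_ms + bin_ms - 1e-9, by = bin_ms)
  if (edges[length(edges)] < total_ms) edges <- c(edges, edges[length(edges)] + bin_ms)
  counts <- if (length(times)) {
    tabulate(findInterval(times, edges, rightmost.closed = FALSE),
             nbins = length(edges) - 1)
  } else rep(0L, length(edges) - 1)
  spike_histogram(edges, counts)
}

#' Inter-spike-interval histogram
#'
#' Histogram of the successive spike-time differences of one neuron. The
#' neuron must have at least two spikes; before truncation at `max_isi`
#' there are `n_spikes - 1` intervals.
#'
#' @param raster a [spike_raster()].
#' @param neuron neuron index.
#' @param bin_ms histogram bin width in ms.
#' @param max_isi truncate intervals above this value (default: largest
#'   interval).
#' @return a [spike_histogram()] with edges in ms.
#' @export
isi <- function(raster, neuron, bin_ms = raster$bin_ms, max_isi = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  s <- raster$spikes[[neuron]]
  if (length(s) < 2) stop("neuron ", neuron, " has fewer than 2 spikes")
  d <- diff(s) * raster$bin_ms
  if (is.null(max_isi)) max_isi <- max(d)
  d <- d[d <= max_isi]
  edges <- seq(0, max_isi + bin_ms, by = bin_ms)
  counts <- tabulate(findInterval(d - 1e-9, edges), nbins = length(edges) - 1)
  spike_histogram(edges, counts)
}

#' Cross-correlogram of two spike trains
#'
#' Counts spike pairs `(t_i, t_j)` at each signed lag `t_j - t_i` in
#' `[-max_lag, max_lag]` bins. Lags are counted only when both bins lie in
#' the recording (no wrap-around). The auto-correlogram (`i == j`) is
#' allowed; its zero-lag self-pairs are excluded. The `"centered"` variant
#' subtracts the product-of-rates expectation per lag.
#'
#' @param raster a [spike_raster()].
#' @param i,j neuron indices (presynaptic `i`, postsynaptic `j`).
#' @param max_lag maximal lag in raster bins (> 0).
#' @param lag_bin lag bin width in raster bins (default 1).
#' @param centered subtract the independence expectation.
#' @return a [spike_histogram()] over lags, edges in raster bins.
#' @export
cross_correlogram <- function(raster, i, j, max_lag, lag_bin = 1,
                              centered = FALSE) {
  stopifnot(inherits(raster, "spike_raster"))
  if (max_lag <= 0) stop("max_lag must be positive")
  max_lag <- as.integer(max_lag); lag_bin <- as.integer(lag_bin)
  TT <- raster$n_bins
  xi <- integer(TT); xi[raster$spikes[[i]]] <- 1L
  xj <- integer(TT); xj[raster$spikes[[j]]] <- 1L
  lags <- (-max_lag):max_lag
  raw <- vapply(lags, function(tau) {
    if (tau >= 0) {
      n <- TT - tau
      sum(xi[seq_len(n)] * xj[seq_len(n) + tau])
    } else {
      n <- TT + tau
      sum(xi[seq_len(n) - tau] * xj[seq_len(n)])
    }
  }, numeric(1))
  if (i == j) raw[lags == 0] <- 0
  if (centered) {
    ri <- length(raster$spikes[[i]]) / TT
    rj <- length(raster$spikes[[j]]) / TT
    n_valid <- TT - abs(lags)
    expect <- ri * rj * n_valid
    if (i == j) expect[lags == 0] <- 0
    raw <- raw - expect
  }
  # aggregate into lag_bin-wide bins
  if (lag_bin > 1) {
    grp <- floor((lags + max_lag) / lag_bin)
    raw <- as.vector(rowsum(raw, grp))
    edges <- seq(-max_lag, by = lag_bin,
                 length.out = length(raw) + 1) - 0.5
  } else {
    edges <- c(lags - 0.5, max_lag + 0.5)
  }
  spike_histogram(edges, raw,
                  normalization = if (centered) "rate" else "counts",
                  lag = TRUE)
}

#' Average cross-correlation of a population
#'
#' Mean over all ordered neuron pairs `i != j` of the centered
#' cross-correlograms: a population summary of pairwise temporal
#' correlations that vanishes (up to noise) for independent neurons.
#'
#' @param raster a [spike_raster()] with at least 2 neurons.
#' @param max_lag maximal lag in raster bins.
#' @param lag_bin lag bin width in raster bins.
#' @param centered subtract the independence expectation per pair
#'   (default `TRUE`).
#' @return a [spike_histogram()] over lags.
#' @export
average_cross_correlation <- function(raster, max_lag, lag_bin = 1,
                                      centered = TRUE) {
  stopifnot(inherits(raster, "spike_raster"))
  N <- raster$n_neurons
  if (N < 2) stop("need at least 2 neurons")
  acc <- NULL
  n_pairs <- 0L
  for (i in seq_len(N)) for (j in seq_len(N)) {
    if (i == j) next
    cc <- cross_correlogram(raster, i, j, max_lag, lag_bin,
                            centered = centered)
    acc <- if (is.null(acc)) cc$counts else acc + cc$counts
    n_pairs <- n_pairs + 1L
    edges <- cc$edges
  }
  spike_histogram(edges, acc / n_pairs, normalization = "rate", lag = TRUE)
}
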