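#' Spike raster objects
#'
#' A `spike_raster` is a sparse representation of a binary spike matrix
#' \eqn{\omega} with `n_neurons` rows and `n_bins` time-bin columns:
#' \eqn{\omega_i(t) = 1} when neuron `i` emitted a spike in bin `t`. Only
#' spike times are stored, as one sorted integer vector of bin indices per
#' neuron (1-based in memory).
#'
#' @param spikes list of integer vectors, one per neuron, each a strictly
#'   increasing set of 1-based bin indices.
#' @param n_bins total number of time bins `T`; defaults to the largest
#'   occupied bin.
#' @param bin_ms bin width in milliseconds (default 1).
#' @param labels optional character vector of neuron identifiers.
#' @param mea optional [mea_config()] describing electrode geometry.
#' @return an object of class `spike_raster`.
#' @examples
#' r <- spike_raster(list(c(1, 3, 5), c(2, 4)), n_bins = 6)
#' r
#' firing_rates(r)
#' @export
spike_raster <- function(spikes, n_bins = NULL, bin_ms = 1, labels = NULL,
                         mea = NULL) {
  if (!is.list(spikes) || length(spikes) < 1L)
    stop("'spikes' must be a non-empty list of per-neuron bin vectors")
  spikes <- lapply(spikes, function(s) {
    s <- as.integer(s)
    if (anyNA(s)) stop("spike bins must be integers")
    if (any(s < 1L)) stop("spike bins must be >= 1 (negative or zero time)")
    if (is.unsorted(s, strictly = TRUE)) {
      s <- sort(unique(s))
    }
    s
  })
  max_bin <- max(c(0L, unlist(spikes, use.names = FALSE)))
  if (is.null(n_bins)) n_bins <- max(max_bin, 1L)
  n_bins <- as.integer(n_bins)
  if (n_bins < max_bin)
    stop("n_bins (", n_bins, ") smaller than largest spike bin (", max_bin, ")")
  if (!is.numeric(bin_ms) || bin_ms <= 0) stop("bin_ms must be positive")
  if (!is.null(labels) && length(labels) != length(spikes))
    stop("labels length must match number of neurons")
  structure(
    list(n_neurons = length(spikes), n_bins = n_bins, bin_ms = bin_ms,
         spikes = spikes, labels = labels, mea = mea),
    class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("spike_raster: %d neurons x %d bins (%.3g ms/bin), %d spikes\n",
              x$n_neurons, x$n_bins, x$bin_ms, n_spikes(x)))
  invisible(x)
}

#' @export
summary.spike_raster <- function(object, ...) {
  r <- firing_rates(object)
  cat(sprintf("spike_raster: N = %d, T = %d bins, bin = %.3g ms\n",
              object$n_neurons, object$n_bins, object$bin_ms))
  cat(sprintf("total spikes: %d\n", n_spikes(object)))
  cat("per-neuron rate (spikes/bin):\n")
  print(summary(r))
  invisible(object)
}

#' Total spike count of a raster
#' @param raster a [spike_raster()].
#' @return integer spike count.
#' @export
n_spikes <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  sum(lengths(raster$spikes))
}

#' Per-neuron firing rates
#'
#' @param raster a [spike_raster()].
#' @param per one of `"bin"` (spikes per time bin) or `"second"` (Hz).
#' @return numeric vector of length `n_neurons`.
#' @export
firing_rates <- function(raster, per = c("bin", "second")) {
  stopifnot(inherits(raster, "spike_raster"))
  per <- match.arg(per)
  r <- lengths(raster$spikes) / raster$n_bins
  if (per == "second") r <- r * 1000 / raster$bin_ms
  r
}

#' Dense binary matrix view of a raster
#'
#' @param x a [spike_raster()].
#' @param ... unused.
#' @return an `n_neurons` x `n_bins` integer 0/1 matrix.
#' @export
as.matrix.spike_raster <- function(x, ...) {
  m <- matrix(0L, x$n_neurons, x$n_bins)
  for (i in seq_len(x$n_neurons)) m[i, x$spikes[[i]]] <- 1L
  m
}

#' Build a raster from a dense 0/1 matrix
#' @param mat neurons x bins matrix with entries in \{0, 1\}.
#' @param bin_ms bin width in ms.
#' @return a [spike_raster()].
#' @export
raster_from_matrix <- function(mat, bin_ms = 1) {
  stopifnot(is.matrix(mat))
  spikes <- lapply(seq_len(nrow(mat)), function(i) which(mat[i, ] != 0))
  spike_raster(spikes, n_bins = ncol(mat), bin_ms = bin_ms)
}

#' Multi-electrode array geometry
#'
#' Describes the rectangular electrode grid a raster was recorded on and,
#' optionally, the (row, col) position of each neuron. Rasters loaded from
#' bare text files have no positions; neurons are then arranged in row-major
#' grid order.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param pitch electrode pitch in micrometers.
#' @param positions optional 2-column matrix (row, col), one row per neuron,
#'   1-based, within the grid bounds.
#' @return an object of class `mea_config`.
#' @export
mea_config <- function(n_rows, n_cols, pitch = 100, positions = NULL) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1, n_cols >= 1, pitch > 0)
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (ncol(positions) != 2) stop("positions must have 2 columns (row, col)")
    if (any(positions[, 1] < 1 | positions[, 1] > n_rows |
            positions[, 2] < 1 | positions[, 2] > n_cols))
      stop("neuron positions outside the MEA grid")
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, pitch = pitch,
                 positions = positions),
            class = "mea_config")
}

#' Default row-major neuron positions on an MEA grid
#' @param mea an [mea_config()].
#' @param n_neurons number of neurons to place.
#' @return 2-column matrix of (row, col) positions.
#' @export
default_positions <- function(mea, n_neurons) {
  stopifnot(inherits(mea, "mea_config"))
  if (n_neurons > mea$n_rows * mea$n_cols)
    stop("more neurons than MEA grid slots")
  idx <- seq_len(n_neurons) - 1L
  cbind(row = idx %/% mea$n_cols + 1L, col = idx %% mea$n_cols + 1L)
}

#' Select a subset of neurons from a raster
#'
#' Keeps a sub-population while leaving the time axis (`n_bins`, `bin_ms`)
#' untouched, so selected neurons keep their firing rates. The criterion is
#' either an explicit index set, the top-k neurons by average spike rate, or
#' a rectangular MEA region (which requires positions).
#'
#' @param raster a [spike_raster()].
#' @param indices explicit neuron indices to keep.
#' @param top_k keep the `top_k` neurons with the highest spike rate (ties
#'   broken by neuron index).
#' @param region numeric vector `c(row_min, row_max, col_min, col_max)`
#'   selecting neurons whose MEA position falls in the rectangle.
#' @return a [spike_raster()] over the kept neurons.
#' @export
select_neurons <- function(raster, indices = NULL, top_k = NULL,
                           region = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  given <- c(!is.null(indices), !is.null(top_k), !is.null(region))
  if (sum(given) != 1L)
    stop("give exactly one of 'indices', 'top_k', 'region'")
  if (!is.null(top_k)) {
    top_k <- as.integer(top_k)
    if (top_k < 1L || top_k > raster$n_neurons)
      stop("top_k out of range")
    ord <- order(-lengths(raster$spikes), seq_len(raster$n_neurons))
    indices <- sort(ord[seq_len(top_k)])
  } else if (!is.null(region)) {
    if (is.null(raster$mea) || is.null(raster$mea$positions))
      stop("region selection requires MEA neuron positions")
    stopifnot(length(region) == 4)
    p <- raster$mea$positions
    indices <- which(p[, 1] >= region[1] & p[, 1] <= region[2] &
                     p[, 2] >= region[3] & p[, 2] <= region[4])
  } else {
    indices <- as.integer(indices)
    if (any(indices < 1L | indices > raster$n_neurons))
      stop("neuron indices out of range")
    indices <- sort(unique(indices))
  }
  if (length(indices) == 0L) stop("empty neuron selection")
  mea <- raster$mea
  if (!is.null(mea) && !is.null(mea$positions))
    mea$positions <- mea$positions[indices, , drop = FALSE]
  spike_raster(raster$spikes[indices], n_bins = raster$n_bins,
               bin_ms = raster$bin_ms,
               labels = if (!is.null(raster$labels)) raster$labels[indices],
               mea = mea)
}
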