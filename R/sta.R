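#' Temporal resolution from stimulus time stamps
#'
#' The STA lag spacing `t_d`: the average difference between two
#' successive time stamps.
#'
#' @param timestamps a [timestamp_series()] (>= 2 stamps).
#' @return scalar `t_d` in ms.
#' @export
temporal_resolution <- function(timestamps) {
  if (length(timestamps) < 2) stop("need at least 2 time stamps")
  mean(diff(as.numeric(timestamps)))
}

#' Spike-triggered-average receptive field
#'
#' Estimates the spatio-temporal receptive field of each selected neuron
#' as the average stimulus preceding its spikes, stored as a 3D volume
#' `RF(x, y, z)` with `n_f` temporal slices at resolution `t_d` (the mean
#' time-stamp spacing): slice `z` (0-based) averages the frame that was on
#' screen at time `-(n_f - 1 - z) * t_d` before the spike, so the first
#' slice is the earliest lag and the last slice the spike time. A lag time
#' maps to the frame whose onset interval contains it; spikes whose
#' earliest lag precedes the first frame (insufficient history) or falls
#' after the last frame's interval are skipped and excluded from
#' `n_spikes_used`. Spike time is the start of the spike's bin.
#'
#' @param raster a [spike_raster()].
#' @param stimulus a [stimulus_sequence()] whose frames align with the
#'   stamps.
#' @param timestamps a [timestamp_series()], one onset per frame.
#' @param n_f number of temporal slices (>= 1).
#' @param neurons neuron indices (default: all).
#' @param downsample integer spatial downsampling factor `s_d` (block
#'   averaging; default 1, RF grid = stimulus grid).
#' @return a list of `rf_volume` objects (one per neuron; a single volume
#'   when one neuron is selected). Each has `values` (array
#'   `height x width x n_f`), `s_d`, `t_d`, `n_f`, `n_spikes_used`,
#'   `neuron`.
#' @export
compute_sta <- function(raster, stimulus, timestamps, n_f, neurons = NULL,
                        downsample = 1) {
  stopifnot(inherits(raster, "spike_raster"),
            inherits(stimulus, "stimulus_sequence"))
  n_f <- as.integer(n_f)
  if (n_f < 1) stop("n_f must be >= 1")
  onsets <- as.numeric(timestamps)
  n_frames <- length(stimulus$frames)
  if (length(onsets) != n_frames)
    stop("time-stamp count (", length(onsets),
         ") does not match frame count (", n_frames, ")")
  t_d <- if (n_frames >= 2) temporal_resolution(timestamps) else
    stimulus$display_ms
  if (is.null(neurons)) neurons <- seq_len(raster$n_neurons)
  h <- stimulus$height; w <- stimulus$width
  Fm <- vapply(stimulus$frames, as.vector, numeric(h * w))
  bounds <- c(onsets, onsets[n_frames] + t_d)
  out <- vector("list", length(neurons))
  for (q in seq_along(neurons)) {
    nn <- neurons[q]
    s <- raster$spikes[[nn]]
    if (length(s) == 0) stop("neuron ", nn, " has no spikes")
    t_spk <- (s - 1) * raster$bin_ms
    lag_mat <- outer(t_spk, -(n_f - 1 - (seq_len(n_f) - 1)) * t_d, "+")
    fidx <- matrix(findInterval(lag_mat, bounds), nrow = length(t_spk))
    usable <- rowSums(fidx >= 1 & fidx <= n_frames) == n_f
    if (!any(usable))
      stop("neuron ", nn, ": no spikes with enough stimulus history")
    fidx <- fidx[usable, , drop = FALSE]
    n_used <- nrow(fidx)
    vol <- array(0, dim = c(h, w, n_f))
    for (z in seq_len(n_f)) {
      cnt <- tabulate(fidx[, z], nbins = n_frames)
      vol[, , z] <- matrix(Fm %*% cnt, h, w) / n_used
    }
    if (downsample > 1) {
      vol <- downsample_volume(vol, as.integer(downsample))
    }
    out[[q]] <- structure(
      list(values = vol, s_d = as.integer(downsample), t_d = t_d,
           n_f = n_f, n_spikes_used = n_used, neuron = nn),
      class = "rf_volume")
  }
  if (length(out) == 1) out[[1]] else out
}

downsample_volume <- function(vol, f) {
  d <- dim(vol)
  h2 <- d[1] %/% f; w2 <- d[2] %/% f
  if (h2 < 1 || w2 < 1) stop("downsampling factor larger than the image")
  out <- array(0, dim = c(h2, w2, d[3]))
  for (z in seq_len(d[3])) {
    m <- vol[seq_len(h2 * f), seq_len(w2 * f), z]
    out[, , z] <- t(rowsum(t(rowsum(m, rep(seq_len(h2), each = f))),
                           rep(seq_len(w2), each = f))) / f^2
  }
  out
}

#' @export
print.rf_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "rf_volume (neuron %d): %dx%d px x %d slices, t_d = %.3g ms, %d spikes\n",
    x$neuron, d[1], d[2], d[3], x$t_d, x$n_spikes_used))
  invisible(x)
}

#' Temporal profile through the receptive-field peak
#'
#' Locates the global maximum `(x_M, y_M, z_M) = argmax RF(x, y, z)` (ties
#' broken by the smallest `(z, y, x)`) and returns the temporal profile
#' `RF(x_M, y_M, .)` through it.
#'
#' @param rf an `rf_volume` from [compute_sta()].
#' @return numeric vector of length `n_f` with attribute `peak`
#'   (named vector `x`, `y`, `z`, 1-based array indices).
#' @export
peak_profile <- function(rf) {
  stopifnot(inherits(rf, "rf_volume"))
  v <- rf$values
  idx <- which(v == max(v), arr.ind = TRUE)   # rows: (y, x, z)
  ord <- order(idx[, 3], idx[, 1], idx[, 2])
  p <- idx[ord[1], ]
  prof <- v[p[1], p[2], ]
  attr(prof, "peak") <- c(x = unname(p[2]), y = unname(p[1]),
                          z = unname(p[3]))
  prof
}

#' Export a receptive-field volume
#'
#' Writes the `n_f` temporal slices as PNG images (min-max normalized per
#' volume; the normalization constants are recorded) plus a lossless JSON
#' volume file carrying the raw values and the `s_d`, `t_d`, `n_f`
#' attributes. [read_rf_json()] restores the volume exactly.
#'
#' @param rf an `rf_volume`.
#' @param dir output directory (created if missing).
#' @return invisibly, the list of written files.
#' @export
export_rf <- function(rf, dir) {
  stopifnot(inherits(rf, "rf_volume"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  v <- rf$values
  lo <- min(v); hi <- max(v)
  png_paths <- file.path(dir, sprintf("rf_neuron%03d_slice%03d.png",
                                      rf$neuron, seq_len(rf$n_f) - 1L))
  for (z in seq_len(rf$n_f)) {
    img <- if (hi > lo) (v[, , z] - lo) / (hi - lo) else
      matrix(0, dim(v)[1], dim(v)[2])
    png::writePNG(img, png_paths[z])
  }
  json_path <- file.path(dir, sprintf("rf_neuron%03d.json", rf$neuron))
  jsonlite::write_json(
    list(format = "spikegibbs-rf-1", neuron = rf$neuron, s_d = rf$s_d,
         t_d = rf$t_d, n_f = rf$n_f, n_spikes_used = rf$n_spikes_used,
         dim = dim(v), values = as.vector(v),
         normalization = list(min = lo, max = hi)),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(png = png_paths, json = json_path))
}

#' @rdname export_rf
#' @param path a JSON volume file written by [export_rf()].
#' @export
read_rf_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "spikegibbs-rf-1"))
    stop("not a spikegibbs RF volume file: ", path)
  structure(list(values = array(obj$values, dim = obj$dim),
                 s_d = obj$s_d, t_d = obj$t_d, n_f = obj$n_f,
                 n_spikes_used = obj$n_spikes_used, neuron = obj$neuron),
            class = "rf_volume")
}
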