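#' Read a spike raster from a plain-text file
#'
#' Two common MEA export layouts are supported. In the `"pairs"` dialect
#' every line holds one spike as `"neuron_index spike_bin"`. In the
#' `"per_neuron_rows"` dialect row `i` lists all spike bins of neuron `i`
#' (a row may be empty for a silent neuron). On disk both neuron indices and
#' time bins are 0-based, matching the usual export convention; in memory
#' they become 1-based. Lines starting with `#` are ignored.
#'
#' With `dialect = "auto"` the first non-comment line decides: exactly two
#' fields on every line reads as `"pairs"`, anything else as
#' `"per_neuron_rows"`. Pass the dialect explicitly when the heuristic is
#' ambiguous (e.g. a two-spike-per-row file).
#'
#' @param path text file path.
#' @param dialect `"auto"`, `"pairs"` or `"per_neuron_rows"`.
#' @param n_bins override the number of time bins `T` (default: largest
#'   spike bin + 1).
#' @param n_neurons override the number of neurons (default: largest neuron
#'   index + 1 for pairs, number of rows otherwise).
#' @param bin_ms bin width in milliseconds.
#' @return a [spike_raster()].
#' @export
read_raster_text <- function(path, dialect = c("auto", "pairs",
                                               "per_neuron_rows"),
                             n_bins = NULL, n_neurons = NULL, bin_ms = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines)
  lines <- lines[keep]
  content <- which(nzchar(trimws(lines)))
  if (length(content) == 0L) stop("no spikes found in ", path)
  fields <- strsplit(trimws(lines), "\\s+")
  if (dialect == "auto") {
    nf <- lengths(fields[content])
    dialect <- if (all(nf == 2L)) "pairs" else "per_neuron_rows"
  }
  if (dialect == "pairs") {
    nf <- lengths(fields[content])
    if (any(nf != 2L))
      stop("malformed pairs line ", content[which(nf != 2L)[1]],
           " in ", path)
    vals <- suppressWarnings(
      vapply(fields[content], as.numeric, numeric(2)))
    if (anyNA(vals))
      stop("malformed pairs line ",
           content[which(colSums(is.na(vals)) > 0)[1]], " in ", path)
    neuron <- vals[1, ]; bin <- vals[2, ]
    if (any(neuron < 0) || any(bin < 0))
      stop("negative neuron index or spike time in ", path)
    if (is.null(n_neurons)) n_neurons <- max(neuron) + 1
    spikes <- split(as.integer(bin) + 1L,
                    factor(as.integer(neuron),
                           levels = 0:(n_neurons - 1)))
    spikes <- unname(lapply(spikes, function(s) sort(unique(s))))
  } else {
    spikes <- lapply(lines, function(ln) {
      ln <- trimws(ln)
      if (!nzchar(ln)) return(integer(0))
      v <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (anyNA(v)) stop("malformed row in ", path)
      if (any(v < 0)) stop("negative spike time in ", path)
      sort(unique(as.integer(v) + 1L))
    })
    if (!is.null(n_neurons)) {
      if (n_neurons < length(spikes)) stop("n_neurons smaller than row count")
      spikes <- c(spikes, rep(list(integer(0)), n_neurons - length(spikes)))
    }
  }
  if (sum(lengths(spikes)) == 0L) stop("no spikes found in ", path)
  spike_raster(spikes, n_bins = n_bins, bin_ms = bin_ms)
}

#' Write a spike raster to a plain-text file
#'
#' Inverse of [read_raster_text()]; on-disk indices are 0-based.
#'
#' @param raster a [spike_raster()].
#' @param path output file path.
#' @param dialect `"pairs"` or `"per_neuron_rows"`.
#' @return `path`, invisibly.
#' @export
write_raster_text <- function(raster, path,
                              dialect = c("pairs", "per_neuron_rows")) {
  stopifnot(inherits(raster, "spike_raster"))
  dialect <- match.arg(dialect)
  if (dialect == "pairs") {
    lines <- unlist(lapply(seq_len(raster$n_neurons), function(i) {
      s <- raster$spikes[[i]]
      if (length(s) == 0L) return(character(0))
      paste(i - 1L, s - 1L)
    }))
  } else {
    lines <- vapply(raster$spikes, function(s)
      paste(s - 1L, collapse = " "), character(1))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Archival raster I/O (JSON container)
#'
#' Lossless round trip of every raster field — spike lists, `n_bins`,
#' `bin_ms`, neuron labels and the optional MEA geometry — through a
#' single self-describing JSON file. This is the package's native archival
#' format; the schema is the object layout of [spike_raster()] plus a
#' `format` tag.
#'
#' @param raster a [spike_raster()].
#' @param path file path (conventionally `.json`).
#' @return `read_raster_json` returns a [spike_raster()];
#'   `write_raster_json` returns `path` invisibly.
#' @export
write_raster_json <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  obj <- list(format = "spikegibbs-raster-1",
              n_neurons = raster$n_neurons,
              n_bins = raster$n_bins,
              bin_ms = raster$bin_ms,
              spikes = lapply(raster$spikes, function(s) s - 1L))
  if (!is.null(raster$labels)) obj$labels <- raster$labels
  if (!is.null(raster$mea)) {
    m <- raster$mea
    obj$mea <- list(n_rows = m$n_rows, n_cols = m$n_cols, pitch = m$pitch)
    if (!is.null(m$positions))
      obj$mea$positions <- unclass(m$positions)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_raster_json
#' @export
read_raster_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || !identical(obj$format, "spikegibbs-raster-1"))
    stop("not a spikegibbs raster file (missing 'format' tag): ", path)
  for (g in c("n_neurons", "n_bins", "bin_ms", "spikes"))
    if (is.null(obj[[g]])) stop("raster file missing group '", g, "': ", path)
  spikes <- obj$spikes
  if (is.matrix(spikes)) spikes <- split(spikes, row(spikes))
  if (!is.list(spikes)) spikes <- as.list(spikes)
  spikes <- lapply(spikes, function(s) as.integer(s) + 1L)
  if (length(spikes) != obj$n_neurons)
    stop("raster file spike list length disagrees with n_neurons")
  mea <- NULL
  if (!is.null(obj$mea)) {
    pos <- obj$mea$positions
    if (!is.null(pos)) pos <- matrix(as.integer(as.matrix(pos)), ncol = 2)
    mea <- mea_config(obj$mea$n_rows, obj$mea$n_cols, obj$mea$pitch, pos)
  }
  labels <- if (!is.null(obj$labels)) as.character(obj$labels)
  spike_raster(spikes, n_bins = obj$n_bins, bin_ms = obj$bin_ms,
               labels = labels, mea = mea)
}

#' Read stimulus frame onset times
#'
#' Row `n` of the file contains the onset time (ms) of image `n`. Onsets
#' must be strictly increasing.
#'
#' @param path text file, one number per row.
#' @return numeric vector of class `timestamp_series`.
#' @export
read_timestamps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
  if (length(v) == 0L) stop("no time stamps in ", path)
  timestamp_series(v)
}

#' @rdname read_timestamps
#' @param onsets strictly increasing onset times in ms.
#' @export
timestamp_series <- function(onsets) {
  onsets <- as.numeric(onsets)
  bad <- which(diff(onsets) <= 0)
  if (length(bad) > 0)
    stop("time stamps not strictly increasing at row ", bad[1] + 1)
  structure(onsets, class = "timestamp_series")
}

#' Load a stimulus image sequence from a directory
#'
#' Reads all PNG/TIFF images in a directory, ordered by file name
#' (lexicographically), converts them to luminance by equal-weight channel
#' averaging and normalizes intensities to `[0, 1]`. All frames must share
#' the same dimensions.
#'
#' @param path directory of images.
#' @param display_ms per-frame display duration in ms (default 100).
#' @return a `stimulus_sequence`: list with `frames` (list of matrices,
#'   rows = image rows), `display_ms`, `width`, `height`.
#' @export
load_stimulus_dir <- function(path, display_ms = 100) {
  if (!dir.exists(path)) stop("not a directory: ", path)
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no PNG/TIFF images in ", path)
  frames <- lapply(files, function(f) {
    img <- tryCatch({
      if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
      else tiff::readTIFF(f)
    }, error = function(e) stop("unreadable image: ", f, " (",
                                conditionMessage(e), ")"))
    if (length(dim(img)) == 3L) {
      nc <- min(dim(img)[3], 3L)   # drop alpha, average color channels
      img <- apply(img[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
    }
    img
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("stimulus images have mixed sizes")
  frames <- lapply(frames, function(f) pmin(pmax(f, 0), 1))
  stimulus_sequence(frames, display_ms = display_ms)
}

#' Construct a stimulus sequence from in-memory frames
#' @param frames list of equal-size numeric matrices with values in `[0, 1]`.
#' @param display_ms per-frame display duration in ms.
#' @return a `stimulus_sequence` object.
#' @export
stimulus_sequence <- function(frames, display_ms = 100) {
  stopifnot(is.list(frames), length(frames) >= 1, display_ms > 0)
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!identical(dim(f), d)) stop("stimulus frames have mixed sizes")
    if (any(f < 0 | f > 1)) stop("frame intensities outside [0, 1]")
  }
  structure(list(frames = frames, display_ms = display_ms,
                 height = d[1], width = d[2]),
            class = "stimulus_sequence")
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  cat(sprintf("stimulus_sequence: %d frames of %dx%d px, %g ms/frame\n",
              length(x$frames), x$height, x$width, x$display_ms))
  invisible(x)
}

#' Write a stimulus sequence as numbered PNG files
#' @param stimulus a `stimulus_sequence`.
#' @param dir output directory (created if missing).
#' @return character vector of written paths, invisibly.
#' @export
write_stimulus_dir <- function(stimulus, dir) {
  stopifnot(inherits(stimulus, "stimulus_sequence"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("frame_%05d.png",
                                  seq_along(stimulus$frames)))
  for (k in seq_along(paths)) png::writePNG(stimulus$frames[[k]], paths[k])
  invisible(paths)
}
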