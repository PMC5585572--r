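#' Monomials and Gibbs potentials
#'
#' A monomial is a product of spike variables
#' \eqn{\omega_{i_1}(\tau_1)\cdots\omega_{i_n}(\tau_n)} over a small set of
#' (neuron, time-offset) events; it evaluates to 1 on a raster window iff
#' every named spike is present. A potential \eqn{\phi} is a weighted sum
#' \eqn{\phi = \sum_l h_l m_l} of distinct monomials; its range `R` is one
#' plus the largest time offset used (`R = D + 1`, `D` the Markov memory).
#'
#' Internally a monomial is a 2-column integer matrix `cbind(neuron, tau)`
#' with 1-based neurons and 0-based offsets, rows sorted by (tau, neuron).
#'
#' @name potential
NULL

monomial <- function(neurons, taus) {
  m <- cbind(neuron = as.integer(neurons), tau = as.integer(taus))
  if (nrow(m) < 1) stop("monomial must have at least one event")
  if (any(m[, "tau"] < 0)) stop("negative time offset in monomial")
  if (any(m[, "neuron"] < 1)) stop("non-positive neuron index in monomial")
  m <- m[order(m[, "tau"], m[, "neuron"]), , drop = FALSE]
  if (anyDuplicated(paste(m[, 1], m[, 2]))) stop("duplicate event in monomial")
  m
}

monomial_key <- function(m) {
  paste(m[, "tau"], m[, "neuron"], sep = ":", collapse = ",")
}

monomial_label <- function(m, zero_based = TRUE) {
  off <- if (zero_based) 1L else 0L
  paste0("w", m[, "neuron"] - off, "(", m[, "tau"], ")", collapse = "")
}

#' Construct a Gibbs potential from explicit terms
#'
#' @param h numeric coefficients, one per monomial.
#' @param monomials list of 2-column matrices `cbind(neuron, tau)` (1-based
#'   neurons, 0-based offsets).
#' @param n_neurons number of neurons `N` the potential acts on.
#' @param range potential range `R`; defaults to `1 + max(tau)`.
#' @return an object of class `gibbs_potential` with fields `h` (named
#'   numeric), `monomials`, `n_neurons`, `range`.
#' @export
gibbs_potential <- function(h, monomials, n_neurons, range = NULL) {
  stopifnot(length(h) == length(monomials), length(monomials) >= 1)
  monomials <- lapply(monomials, function(m) monomial(m[, 1], m[, 2]))
  keys <- vapply(monomials, monomial_key, character(1))
  if (anyDuplicated(keys)) stop("duplicate monomial in potential")
  max_tau <- max(vapply(monomials, function(m) max(m[, "tau"]), integer(1)))
  if (is.null(range)) range <- max_tau + 1L
  range <- as.integer(range)
  if (range < max_tau + 1L)
    stop("declared range ", range, " smaller than 1 + max offset ", max_tau)
  max_neuron <- max(vapply(monomials, function(m) max(m[, "neuron"]),
                           integer(1)))
  n_neurons <- as.integer(n_neurons)
  if (n_neurons < max_neuron)
    stop("monomial references neuron beyond n_neurons")
  h <- as.numeric(h)
  names(h) <- vapply(monomials, monomial_label, character(1))
  structure(list(h = h, monomials = monomials, n_neurons = n_neurons,
                 range = range),
            class = "gibbs_potential")
}

#' @export
print.gibbs_potential <- function(x, max_terms = 8, ...) {
  cat(sprintf("gibbs_potential: N = %d, range R = %d, %d monomials\n",
              x$n_neurons, x$range, length(x$h)))
  k <- min(max_terms, length(x$h))
  for (l in seq_len(k))
    cat(sprintf("  %+.6g %s\n", x$h[l], names(x$h)[l]))
  if (length(x$h) > k) cat("  ... (", length(x$h) - k, " more)\n", sep = "")
  invisible(x)
}

#' @export
length.gibbs_potential <- function(x) length(x$h)

#' Build a canned maximum-entropy model potential
#'
#' Constructs the monomial set of one of the standard spike-train
#' maximum-entropy models, with all coefficients initialized to zero:
#' \describe{
#'   \item{bernoulli}{independent neurons; singles \eqn{\omega_i(0)};
#'     range 1.}
#'   \item{ising}{singles plus all same-time pairs
#'     \eqn{\omega_i(0)\omega_j(0)}, i < j; range 1.}
#'   \item{pairwise_triplets}{Ising plus all same-time triplets; range 1.}
#'   \item{pairwise}{spatio-temporal pairwise model: singles, same-time
#'     pairs (i < j), and all cross-time pairs
#'     \eqn{\omega_i(0)\omega_j(k)} for every ordered (i, j) and
#'     1 <= k <= D = R - 1.}
#' }
#' Monomials are canonically ordered: the N singles first, then by
#' (degree, offset list, neuron list).
#'
#' @param model_type one of `"bernoulli"`, `"ising"`, `"pairwise_triplets"`,
#'   `"pairwise"`.
#' @param n_neurons number of neurons.
#' @param range model range `R`; must be 1 except for `"pairwise"`.
#' @return a `gibbs_potential` with zero coefficients.
#' @examples
#' build_potential("pairwise", n_neurons = 2, range = 2)  # 7 monomials
#' @export
build_potential <- function(model_type = c("bernoulli", "ising",
                                           "pairwise_triplets", "pairwise"),
                            n_neurons, range = 1) {
  model_type <- match.arg(model_type)
  N <- as.integer(n_neurons); R <- as.integer(range)
  stopifnot(N >= 1, R >= 1)
  if (model_type != "pairwise" && R != 1L)
    stop("model '", model_type, "' has range 1; got range = ", R)
  mono <- lapply(seq_len(N), function(i) monomial(i, 0L))
  if (model_type %in% c("ising", "pairwise_triplets", "pairwise")) {
    if (N >= 2)
      for (i in seq_len(N - 1)) for (j in (i + 1):N)
        mono[[length(mono) + 1L]] <- monomial(c(i, j), c(0L, 0L))
  }
  if (model_type == "pairwise_triplets" && N >= 3) {
    cmb <- utils::combn(N, 3)
    for (k in seq_len(ncol(cmb)))
      mono[[length(mono) + 1L]] <- monomial(cmb[, k], c(0L, 0L, 0L))
  }
  if (model_type == "pairwise" && R >= 2) {
    for (k in seq_len(R - 1L))
      for (i in seq_len(N)) for (j in seq_len(N))
        mono[[length(mono) + 1L]] <- monomial(c(i, j), c(0L, k))
  }
  gibbs_potential(numeric(length(mono)), mono, n_neurons = N, range = R)
}

#' Evaluate a monomial on a raster window
#'
#' Returns \eqn{\prod \omega_i(t + \tau)} over the monomial's events: 1 iff
#' every named spike occurs in the window starting at bin `t`.
#'
#' @param m a monomial (2-column matrix, see [gibbs_potential()]).
#' @param raster a [spike_raster()].
#' @param t 1-based window start bin; `t + max(tau)` must be within the
#'   raster.
#' @return 0 or 1.
#' @export
eval_monomial <- function(m, raster, t) {
  stopifnot(inherits(raster, "spike_raster"))
  depth <- max(m[, "tau"])
  if (t < 1 || t + depth > raster$n_bins)
    stop("window [", t, ", ", t + depth, "] beyond raster end")
  for (e in seq_len(nrow(m))) {
    s <- raster$spikes[[m[e, "neuron"]]]
    bin <- t + m[e, "tau"]
    idx <- findInterval(bin, s)
    if (idx == 0L || s[idx] != bin) return(0L)
  }
  1L
}

#' Potential value of one spatio-temporal block
#'
#' @param potential a `gibbs_potential`.
#' @param block `n_neurons` x `range` binary matrix (columns = successive
#'   time steps).
#' @return \eqn{\phi(\mathrm{block}) = \sum_l h_l m_l(\mathrm{block})}.
#' @export
potential_value <- function(potential, block) {
  stopifnot(inherits(potential, "gibbs_potential"))
  block <- as.matrix(block)
  if (nrow(block) != potential$n_neurons || ncol(block) != potential$range)
    stop("block must be ", potential$n_neurons, " x ", potential$range)
  val <- 0
  for (l in seq_along(potential$h)) {
    m <- potential$monomials[[l]]
    on <- all(block[cbind(m[, "neuron"], m[, "tau"] + 1L)] != 0)
    if (on) val <- val + unname(potential$h[l])
  }
  val
}

#' Gibbs energy of a raster
#'
#' Sums the potential over every length-`R` window of the raster:
#' \eqn{E(\omega) = \sum_{t} \phi(\omega(t..t+R-1))} for
#' `t = 1, ..., T - R + 1`.
#'
#' @param potential a `gibbs_potential`.
#' @param raster a [spike_raster()] with `n_bins >= range`.
#' @return scalar energy.
#' @export
energy <- function(potential, raster) {
  stats <- empirical_averages(raster, potential)
  sum(potential$h * stats$counts)
}

# Per-monomial indicator time series over all windows: logical matrix
# L x n_windows. Dense (N x T) representation; N is small in practice.
monomial_indicators <- function(raster, potential) {
  M <- as.matrix(raster) != 0
  R <- potential$range
  TT <- raster$n_bins
  if (TT < R) stop("raster shorter than potential range (T < R)")
  nw <- TT - R + 1L
  ind <- matrix(TRUE, length(potential$h), nw)
  for (l in seq_along(potential$monomials)) {
    m <- potential$monomials[[l]]
    v <- rep(TRUE, nw)
    for (e in seq_len(nrow(m)))
      v <- v & M[m[e, "neuron"], seq.int(1L + m[e, "tau"],
                                         length.out = nw)]
    ind[l, ] <- v
  }
  ind
}

#' Empirical monomial averages of a raster
#'
#' Computes \eqn{\pi[m_l]}, the fraction of the `T - R + 1` sliding windows
#' of the raster on which each monomial of the potential evaluates to 1.
#' These are the constraint targets of maximum-entropy fitting.
#'
#' @param raster a [spike_raster()].
#' @param potential a `gibbs_potential`.
#' @return an object of class `empirical_stats`: list with `averages`
#'   (named numeric \eqn{\pi[m_l]}), `counts` (integer window counts),
#'   `n_windows`.
#' @export
empirical_averages <- function(raster, potential) {
  ind <- monomial_indicators(raster, potential)
  counts <- as.integer(rowSums(ind))
  structure(list(averages = stats::setNames(counts / ncol(ind),
                                            names(potential$h)),
                 counts = counts, n_windows = ncol(ind)),
            class = "empirical_stats")
}

#' @export
print.empirical_stats <- function(x, ...) {
  cat(sprintf("empirical_stats over %d windows:\n", x$n_windows))
  print(utils::head(x$averages, 10))
  if (length(x$averages) > 10) cat("...\n")
  invisible(x)
}

# Encode N x len binary blocks over a window as integer codes,
# column-major in time: bit (neuron-1) + N*(step-1).
encode_windows <- function(M, len) {
  N <- nrow(M); TT <- ncol(M)
  nw <- TT - len + 1L
  if (nw < 1L) stop("raster shorter than block length")
  code <- numeric(nw)
  p <- 1
  for (step in seq_len(len)) {
    for (i in seq_len(N)) {
      code <- code + p * M[i, seq.int(step, length.out = nw)]
      p <- p * 2
    }
  }
  code
}

decode_block <- function(code, N, len) {
  bits <- matrix(0L, N, len)
  for (step in seq_len(len)) for (i in seq_len(N)) {
    bits[i, step] <- code %% 2
    code <- code %/% 2
  }
  bits
}

block_string <- function(block) {
  paste(apply(block, 2, paste, collapse = ""), collapse = "|")
}

#' Empirical probabilities of observed spike blocks
#'
#' Scans all sliding windows of each length `1..max_len` and tabulates the
#' observed spatio-temporal spike patterns ("blocks"). Only observed blocks
#' are stored; probabilities sum to 1 within each length.
#'
#' @param raster a [spike_raster()].
#' @param max_len maximal pattern length in time steps.
#' @return data frame with columns `length`, `code` (integer block code),
#'   `pattern` (readable label, columns separated by `|`), `count`, `prob`,
#'   `n_windows`.
#' @export
block_probabilities <- function(raster, max_len) {
  stopifnot(inherits(raster, "spike_raster"))
  max_len <- as.integer(max_len)
  if (max_len < 1L) stop("max_len must be >= 1")
  if (max_len > raster$n_bins) stop("max_len exceeds raster length")
  M <- as.matrix(raster)
  out <- vector("list", max_len)
  for (len in seq_len(max_len)) {
    code <- encode_windows(M, len)
    tb <- table(code)
    codes <- as.numeric(names(tb))
    nw <- length(code)
    out[[len]] <- data.frame(
      length = len, code = codes,
      pattern = vapply(codes, function(cd)
        block_string(decode_block(cd, raster$n_neurons, len)), character(1)),
      count = as.integer(tb), prob = as.integer(tb) / nw,
      n_windows = nw, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read / write a potential definition file
#'
#' Line-oriented grammar: each non-comment line is
#' `h=<float> : w<i>(<tau>) w<j>(<tau>) ...` with 0-based neuron indices
#' (the notation used in printed literal potentials) and offsets in
#' `[0, R)`. `#` starts a comment. Duplicate monomials are an error.
#'
#' @param path file path.
#' @param n_neurons optional total neuron count (default: largest index
#'   + 1).
#' @param range optional declared range (default: `1 + max(tau)`).
#' @return `parse_potential_file` returns a `gibbs_potential`;
#'   `write_potential_file` returns `path` invisibly.
#' @export
parse_potential_file <- function(path, n_neurons = NULL, range = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty potential file: ", path)
  h <- numeric(0); mono <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed potential line: '", ln, "'")
    hs <- trimws(parts[1])
    if (!grepl("^h\\s*=", hs)) stop("expected 'h=<float>' in: '", ln, "'")
    coef <- suppressWarnings(as.numeric(sub("^h\\s*=\\s*", "", hs)))
    if (is.na(coef)) stop("bad coefficient in: '", ln, "'")
    evs <- regmatches(parts[2],
                      gregexpr("w([0-9]+)\\(([0-9]+)\\)", parts[2]))[[1]]
    residue <- gsub("w([0-9]+)\\(([0-9]+)\\)", "", parts[2])
    if (grepl("\\S", residue))
      stop("unknown token in monomial: '", trimws(residue), "'")
    if (length(evs) == 0) stop("no events on line: '", ln, "'")
    neu <- as.integer(sub("^w([0-9]+)\\(.*$", "\\1", evs)) + 1L
    tau <- as.integer(sub("^w[0-9]+\\(([0-9]+)\\)$", "\\1", evs))
    m <- monomial(neu, tau)
    key <- monomial_key(m)
    if (key %in% vapply(mono, monomial_key, character(1)))
      stop("duplicate monomial in potential file: '", ln, "'")
    h <- c(h, coef); mono[[length(mono) + 1L]] <- m
  }
  max_tau <- max(vapply(mono, function(m) max(m[, "tau"]), integer(1)))
  if (!is.null(range) && range < max_tau + 1L)
    stop("offset ", max_tau, " >= declared range ", range)
  if (is.null(n_neurons))
    n_neurons <- max(vapply(mono, function(m) max(m[, "neuron"]),
                            integer(1)))
  gibbs_potential(h, mono, n_neurons = n_neurons, range = range)
}

#' @rdname parse_potential_file
#' @param potential a `gibbs_potential`.
#' @export
write_potential_file <- function(potential, path) {
  stopifnot(inherits(potential, "gibbs_potential"))
  lines <- vapply(seq_along(potential$h), function(l) {
    m <- potential$monomials[[l]]
    evs <- paste0("w", m[, "neuron"] - 1L, "(", m[, "tau"], ")",
                  collapse = " ")
    sprintf("h=%.17g : %s", potential$h[l], evs)
  }, character(1))
  writeLines(c("# spikegibbs potential file", lines), path)
  invisible(path)
}
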