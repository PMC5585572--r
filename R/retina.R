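#' Discrete leaky integrate-and-fire parameters
#'
#' Parameters of the coupled discrete-time LIF network used by the retina
#' simulator. The membrane update over one time step `dt = 1` ms is
#' \deqn{V_i(t+1) = \gamma V_i(t)(1 - Z_i(t)) + I_i(t)/C +
#'   \frac{1}{C}\sum_j W_{ij} Z_j(t) + \frac{\sigma_B}{C} B_i(t),}
#' with spike label `Z_i = 1` iff `V_i >= theta`, `B_i(t)` i.i.d. standard
#' Gaussian noise, and reset acting only through the `(1 - Z_i)` factor.
#' Potentials are measured relative to the leak reversal, so the reset
#' value is 0. The leak factor is `gamma = 1 - dt / tau_L` with
#' `tau_L = C / g_L` the leak characteristic time; `dt` must be well below
#' `tau_L` for the discretization to describe the biophysics.
#'
#' @param gamma leak factor in `[0, 1]` (default 0.9, i.e. `tau_L` = 10 ms).
#' @param sigma_b membrane noise amplitude, >= 0 (default 0.1).
#' @param capacitance membrane capacity `C` > 0 (default 1).
#' @param threshold firing threshold `theta` (default 1).
#' @param tau_l alternatively give the leak time constant in ms;
#'   `gamma` is then derived as `1 - dt / tau_l`.
#' @return a `lif_params` list (includes `dt = 1` ms).
#' @export
lif_params <- function(gamma = 0.9, sigma_b = 0.1, capacitance = 1,
                       threshold = 1, tau_l = NULL) {
  dt <- 1
  if (!is.null(tau_l)) {
    if (tau_l <= dt) stop("tau_l must exceed the 1 ms time step")
    gamma <- 1 - dt / tau_l
  }
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  if (sigma_b < 0) stop("sigma_b must be >= 0")
  if (capacitance <= 0) stop("capacitance must be positive")
  structure(list(gamma = gamma, sigma_b = sigma_b,
                 capacitance = capacitance, threshold = threshold,
                 dt = dt,
                 tau_l = if (gamma < 1) dt / (1 - gamma) else Inf),
            class = "lif_params")
}

#' One step of the coupled discrete LIF network
#'
#' Advances membrane potentials and spike labels by one 1-ms bin, following
#' the update in [lif_params()].
#'
#' @param V numeric membrane potentials.
#' @param Z integer 0/1 spike labels at the current bin.
#' @param I_t drive currents at the current bin.
#' @param W N x N connectivity (`W[i, j]`: presynaptic `j` onto
#'   postsynaptic `i`), or `NULL` for uncoupled neurons.
#' @param params a [lif_params()].
#' @param noise standard-Gaussian draws for this bin (default none, i.e. a
#'   deterministic step); scaled internally by `sigma_b / C`.
#' @return list with updated `V` and `Z`.
#' @export
lif_step <- function(V, Z, I_t, W = NULL, params = lif_params(),
                     noise = NULL) {
  if (any(!is.finite(V)) || any(!is.finite(I_t)))
    stop("non-finite membrane potential or drive")
  C <- params$capacitance
  V_new <- params$gamma * V * (1 - Z) + I_t / C
  if (!is.null(W)) V_new <- V_new + as.vector(W %*% Z) / C
  if (!is.null(noise)) V_new <- V_new + params$sigma_b / C * noise
  Z_new <- as.integer(V_new >= params$threshold)
  list(V = V_new, Z = Z_new)
}

#' Build a ganglion-cell connectivity matrix
#'
#' Synaptic weight matrix `W[i, j]` for the LIF network. Schemes:
#' `"none"` (zeros — independent neurons), `"sparse"` (exactly
#' `n_connections` entries drawn without replacement among the `N^2`
#' slots), `"dense"` (all entries drawn), `"file"` (CSV matrix validated to
#' N x N). Default weights are zero-mean Gaussian scaled by the reciprocal
#' square root of the expected in-degree.
#'
#' @param scheme `"none"`, `"sparse"`, `"dense"` or `"file"`.
#' @param n_neurons number of neurons `N`.
#' @param n_connections number of non-zeros for `"sparse"`.
#' @param weight_law function `n -> numeric(n)` drawing weights; default
#'   `rnorm(n, 0, 1/sqrt(k))` with `k` the expected in-degree.
#' @param seed optional integer seed.
#' @param path CSV file for `scheme = "file"`.
#' @return an N x N matrix with attribute `scheme`.
#' @export
build_connectivity <- function(scheme = c("none", "sparse", "dense", "file"),
                               n_neurons, n_connections = NULL,
                               weight_law = NULL, seed = NULL,
                               path = NULL) {
  scheme <- match.arg(scheme)
  N <- as.integer(n_neurons)
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, N, N)
  if (scheme == "sparse") {
    if (is.null(n_connections) || n_connections < 1 ||
        n_connections > N * N)
      stop("sparse scheme needs 0 < n_connections <= N^2")
    k <- n_connections / N
    if (is.null(weight_law))
      weight_law <- function(n) stats::rnorm(n, 0, 1 / sqrt(max(k, 1)))
    slots <- sample.int(N * N, n_connections)
    W[slots] <- weight_law(n_connections)
  } else if (scheme == "dense") {
    if (is.null(weight_law))
      weight_law <- function(n) stats::rnorm(n, 0, 1 / sqrt(N))
    W[] <- weight_law(N * N)
  } else if (scheme == "file") {
    if (is.null(path)) stop("scheme 'file' needs a path")
    W <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(W) <- NULL
    if (!all(dim(W) == N))
      stop("connectivity file is ", nrow(W), "x", ncol(W),
           ", expected ", N, "x", N)
  }
  attr(W, "scheme") <- scheme
  W
}

#' Model-cell layout and linear front-end parameters
#'
#' The simulator's front-end converts each stimulus frame into per-neuron
#' drive currents with a difference-of-Gaussians (DoG) spatial receptive
#' field per model cell and first-order exponential temporal low-pass
#' filters (a fast center minus a slower, weighted surround). Cell centers
#' tile the image on an `n_x` by `n_y` grid.
#'
#' @param n_x,n_y grid of model-cell centers.
#' @param sigma_center center Gaussian s.d. in pixels.
#' @param surround_ratio surround s.d. as a multiple of the center s.d.
#'   (default 3).
#' @param surround_weight relative surround strength in the DoG
#'   (default 0.8).
#' @param tau_center,tau_surround temporal filter time constants in ms.
#' @param gain scalar gain applied to the drive current.
#' @return a `retina_layout` list.
#' @export
retina_layout <- function(n_x, n_y, sigma_center = 2, surround_ratio = 3,
                          surround_weight = 0.8, tau_center = 10,
                          tau_surround = 30, gain = 1) {
  stopifnot(n_x >= 1, n_y >= 1, sigma_center > 0, surround_ratio > 1,
            surround_weight >= 0, tau_center > 0, tau_surround > 0)
  structure(list(n_x = as.integer(n_x), n_y = as.integer(n_y),
                 sigma_center = sigma_center,
                 surround_ratio = surround_ratio,
                 surround_weight = surround_weight,
                 tau_center = tau_center, tau_surround = tau_surround,
                 gain = gain),
            class = "retina_layout")
}

gaussian_kernel_row <- function(cx, cy, sigma, h, w) {
  gx <- exp(-((seq_len(w) - cx)^2) / (2 * sigma^2))
  gy <- exp(-((seq_len(h) - cy)^2) / (2 * sigma^2))
  k <- outer(gy, gx)
  as.vector(k / sum(k))
}

#' Per-neuron drive currents from a stimulus sequence
#'
#' Linear front-end of the retina simulator: each model cell applies its
#' DoG spatial kernel to the frame on screen, and the center and surround
#' responses pass through first-order exponential low-pass filters (time
#' constants `tau_center` < `tau_surround`); the drive is
#' `gain * (center_lp - surround_weight * surround_lp)`. Deterministic.
#'
#' @param stimulus a [stimulus_sequence()].
#' @param layout a [retina_layout()]; the center grid must fit inside the
#'   image.
#' @param duration_ms simulation length (default: frames x display time).
#' @return N x T matrix of drive currents (1-ms bins), with attribute
#'   `centers` (N x 2 matrix of pixel coordinates, columns x, y).
#' @export
compute_drive <- function(stimulus, layout, duration_ms = NULL) {
  stopifnot(inherits(stimulus, "stimulus_sequence"),
            inherits(layout, "retina_layout"))
  h <- stimulus$height; w <- stimulus$width
  if (layout$n_x > w || layout$n_y > h)
    stop("center grid larger than the stimulus image")
  cx <- (seq_len(layout$n_x) - 0.5) * w / layout$n_x + 0.5
  cy <- (seq_len(layout$n_y) - 0.5) * h / layout$n_y + 0.5
  centers <- cbind(x = rep(cx, each = layout$n_y),
                   y = rep(cy, times = layout$n_x))
  N <- nrow(centers)
  Kc <- matrix(0, N, h * w); Ks <- matrix(0, N, h * w)
  for (n in seq_len(N)) {
    Kc[n, ] <- gaussian_kernel_row(centers[n, 1], centers[n, 2],
                                   layout$sigma_center, h, w)
    Ks[n, ] <- gaussian_kernel_row(centers[n, 1], centers[n, 2],
                                   layout$sigma_center * layout$surround_ratio,
                                   h, w)
  }
  Fm <- vapply(stimulus$frames, as.vector, numeric(h * w))
  resp_c <- Kc %*% Fm                       # N x n_frames
  resp_s <- Ks %*% Fm
  n_frames <- ncol(Fm)
  if (is.null(duration_ms))
    duration_ms <- n_frames * stimulus$display_ms
  TT <- as.integer(duration_ms)             # dt = 1 ms
  frame_at <- pmin(floor((seq_len(TT) - 1) / stimulus$display_ms) + 1,
                   n_frames)
  xc <- resp_c[, frame_at, drop = FALSE]
  xs <- resp_s[, frame_at, drop = FALSE]
  ac <- exp(-1 / layout$tau_center)
  as_ <- exp(-1 / layout$tau_surround)
  yc <- matrix(0, N, TT); ys <- matrix(0, N, TT)
  yc[, 1] <- (1 - ac) * xc[, 1]
  ys[, 1] <- (1 - as_) * xs[, 1]
  for (t in seq_len(TT - 1)) {
    yc[, t + 1] <- ac * yc[, t] + (1 - ac) * xc[, t + 1]
    ys[, t + 1] <- as_ * ys[, t] + (1 - as_) * xs[, t + 1]
  }
  drive <- layout$gain * (yc - layout$surround_weight * ys)
  attr(drive, "centers") <- centers
  drive
}

#' Simulate spiking retinal output from drive currents
#'
#' Iterates the coupled discrete LIF network ([lif_step()]) over the
#' columns of a drive matrix and records the spike labels as a raster.
#' Noise draws are pre-generated per neuron and bin from the seed, so the
#' result does not depend on iteration order.
#'
#' @param drive N x T drive current matrix (e.g. from [compute_drive()]).
#' @param params a [lif_params()].
#' @param connectivity N x N weight matrix or `NULL`.
#' @param seed optional integer seed for the membrane noise.
#' @return a [spike_raster()] at 1-ms bins.
#' @export
simulate_lif <- function(drive, params = lif_params(), connectivity = NULL,
                         seed = NULL) {
  stopifnot(is.matrix(drive))
  N <- nrow(drive); TT <- ncol(drive)
  if (!is.null(connectivity) && !all(dim(connectivity) == N))
    stop("connectivity must be ", N, "x", N)
  if (!is.null(seed)) set.seed(seed)
  noise <- if (params$sigma_b > 0) matrix(stats::rnorm(N * TT), N, TT)
  V <- numeric(N); Z <- integer(N)
  out <- matrix(0L, N, TT)
  for (t in seq_len(TT)) {
    st <- lif_step(V, Z, drive[, t], connectivity, params,
                   noise = if (!is.null(noise)) noise[, t])
    V <- st$V; Z <- st$Z
    out[, t] <- Z
  }
  raster_from_matrix(out, bin_ms = params$dt)
}

#' Simulate the retinal spike response to an image sequence
#'
#' Full stimulus-to-spikes pipeline: the linear DoG front-end
#' ([compute_drive()]) turns the image sequence into per-neuron currents,
#' which drive the coupled discrete LIF network ([simulate_lif()]).
#'
#' @param stimulus a [stimulus_sequence()].
#' @param layout a [retina_layout()].
#' @param params a [lif_params()].
#' @param connectivity N x N weight matrix (N = `n_x * n_y`) or `NULL`.
#' @param duration_ms simulation length (default: frames x display time).
#' @param seed optional integer seed.
#' @return a [spike_raster()] at 1-ms bins with the cell-center MEA
#'   geometry attached.
#' @export
simulate_retina <- function(stimulus, layout, params = lif_params(),
                            connectivity = NULL, duration_ms = NULL,
                            seed = NULL) {
  if (length(stimulus$frames) == 0) stop("empty stimulus")
  drive <- compute_drive(stimulus, layout, duration_ms)
  r <- simulate_lif(drive, params, connectivity, seed)
  centers <- attr(drive, "centers")
  pos <- cbind(rep(seq_len(layout$n_y), times = layout$n_x),
               rep(seq_len(layout$n_x), each = layout$n_y))
  r$mea <- mea_config(layout$n_y, layout$n_x, positions = pos)
  r
}

#' Read a retina configuration file (JSON)
#'
#' Loads [lif_params()], [retina_layout()] and a connectivity
#' specification from a single JSON document with groups `lif`, `layout`,
#' `connectivity` (fields mirror the constructor arguments; connectivity
#' has `scheme` and, as needed, `n_connections`, `seed`, `path`).
#'
#' @param path JSON file.
#' @return list with `params`, `layout`, `connectivity_spec`.
#' @export
read_retina_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(lif_params, as.list(cfg$lif %||% list()))
  if (is.null(cfg$layout)) stop("retina config missing 'layout'")
  layout <- do.call(retina_layout, as.list(cfg$layout))
  list(params = params, layout = layout,
       connectivity_spec = as.list(cfg$connectivity %||%
                                     list(scheme = "none")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
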