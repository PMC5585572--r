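#' Exact Markov-chain (transfer-matrix) representation of a Gibbs model
#'
#' A range-`R` Gibbs potential defines a probability on rasters that is the
#' invariant measure of a Markov chain with memory `D = R - 1` over the
#' 2^(N*D) spatio-temporal states (N-neuron binary blocks of D time steps;
#' D = 0 degenerates to an independent product measure over columns). The
#' transfer matrix `M(w, c) = exp(phi(w . c))` — `phi` evaluated on the
#' R-window formed by the state `w` followed by the new spike column `c` —
#' yields, through its Perron eigenvalue `lambda` and eigenvectors, the
#' transition probabilities, the invariant distribution `mu`, and the
#' pressure `log(lambda)` (free energy per time step). For small models this
#' is the exact ground-truth engine against which Monte-Carlo methods are
#' checked.
#'
#' States and spike columns are encoded as integers: bit `(i - 1) + N*(s - 1)`
#' is neuron `i` at step `s` of the block.
#'
#' @param potential a [gibbs_potential()].
#' @param max_bits size cap: `N * max(D, 1)` may not exceed `max_bits`
#'   (default 14, i.e. at most 16384 states).
#' @param tol convergence tolerance on the stationarity residual.
#' @return an object of class `gibbs_chain` with fields `n_neurons`,
#'   `memory` (D), `range`, `n_states`, `lambda`, `pressure`,
#'   `transition` (states x 2^N matrix `P(c | w)`), `next_state`
#'   (states x 2^N integer matrix of successor states, 0-based),
#'   `mu` (invariant distribution over states), `window_dist`
#'   (probability of every N x R window, indexed by window code + 1),
#'   and `col_prob` (for D = 0: spike-column distribution).
#' @examples
#' pot <- build_potential("bernoulli", 2)     # h = 0: fair independent spikes
#' ch <- build_chain(pot)
#' exact_averages(ch, pot$monomials)          # both rates are 1/2
#' @export
build_chain <- function(potential, max_bits = 14, tol = 1e-12) {
  stopifnot(inherits(potential, "gibbs_potential"))
  N <- potential$n_neurons
  D <- potential$range - 1L
  if (N * max(D, 1L) > max_bits)
    stop("state space too large: N*max(D,1) = ", N * max(D, 1L),
         " exceeds cap ", max_bits)
  h <- potential$h
  if (any(!is.finite(h))) stop("non-finite potential coefficients")
  R <- potential$range
  n_cols <- 2L^N
  # phi over all N x R window codes
  n_win <- 2L^(N * R)
  codes <- 0:(n_win - 1L)
  phi <- numeric(n_win)
  for (l in seq_along(h)) {
    m <- potential$monomials[[l]]
    on <- rep(TRUE, n_win)
    for (e in seq_len(nrow(m))) {
      bit <- bitwShiftL(1L, (m[e, "neuron"] - 1L) + N * m[e, "tau"])
      on <- on & bitwAnd(codes, bit) > 0L
    }
    phi[on] <- phi[on] + h[l]
  }
  if (D == 0L) {
    w <- exp(phi - max(phi))
    Z <- sum(w)
    col_prob <- w / Z
    lambda <- Z * exp(max(phi))
    obj <- list(n_neurons = N, memory = 0L, range = 1L, n_states = 1L,
                lambda = lambda, pressure = log(lambda),
                transition = matrix(col_prob, 1L), next_state = NULL,
                mu = 1, window_dist = col_prob, col_prob = col_prob,
                potential = potential)
    class(obj) <- "gibbs_chain"
    return(obj)
  }
  S <- 2L^(N * D)
  states <- 0:(S - 1L)
  shift_hi <- 2L^(N * (D - 1L))
  # weight M[w, c] = exp(phi(window w + c*2^(ND))); successor state
  M <- matrix(0, S, n_cols)
  nxt <- matrix(0L, S, n_cols)
  for (c in 0:(n_cols - 1L)) {
    M[, c + 1L] <- exp(phi[states + c * S + 1L])
    nxt[, c + 1L] <- (states %/% n_cols) + c * shift_hi
  }
  # Perron right and left eigenvectors by power iteration
  v <- rep(1 / S, S)
  lambda <- NA_real_
  for (it in 1:20000) {
    v2 <- numeric(S)
    for (c in seq_len(n_cols))
      v2 <- v2 + M[, c] * v[nxt[, c] + 1L]
    lambda <- sum(v2)
    v2 <- v2 / lambda
    if (max(abs(v2 - v)) < tol) { v <- v2; break }
    v <- v2
  }
  # left vector: u'(w') = sum over predecessors
  mid <- states %% shift_hi
  top <- states %/% shift_hi           # newest column of state w'
  u <- rep(1 / S, S)
  for (it in 1:20000) {
    u2 <- numeric(S)
    for (a in 0:(n_cols - 1L)) {
      pred <- a + mid * n_cols
      u2 <- u2 + u[pred + 1L] * M[cbind(pred + 1L, top + 1L)]
    }
    u2 <- u2 / sum(u2)
    if (max(abs(u2 - u)) < tol) { u <- u2; break }
    u <- u2
  }
  # Rayleigh estimate of lambda from the converged right vector
  v2 <- numeric(S)
  for (c in seq_len(n_cols)) v2 <- v2 + M[, c] * v[nxt[, c] + 1L]
  lambda <- sum(v2 * v) / sum(v * v)
  P <- M * v[nxt + 1L] / (lambda * v)
  P <- P / rowSums(P)                  # exact row normalization
  mu <- u * v
  mu <- mu / sum(mu)
  # stationarity residual check: mu %*% P (as a state chain)
  mu2 <- numeric(S)
  for (c in seq_len(n_cols)) {
    contrib <- mu * P[, c]
    idx <- nxt[, c] + 1L
    agg <- rowsum(contrib, idx)
    mu2[as.integer(rownames(agg))] <- mu2[as.integer(rownames(agg))] + agg
  }
  if (max(abs(mu2 - mu)) > 1e-8)
    warning("stationarity residual ", signif(max(abs(mu2 - mu)), 3),
            " above tolerance")
  # distribution over N x R windows: p(w, c) = mu(w) P(c | w)
  window_dist <- numeric(n_win)
  for (c in 0:(n_cols - 1L))
    window_dist[states + c * S + 1L] <- mu * P[, c + 1L]
  obj <- list(n_neurons = N, memory = D, range = R, n_states = S,
              lambda = lambda, pressure = log(lambda),
              transition = P, next_state = nxt, mu = mu,
              window_dist = window_dist, col_prob = NULL,
              potential = potential)
  class(obj) <- "gibbs_chain"
  obj
}

#' @export
print.gibbs_chain <- function(x, ...) {
  cat(sprintf(
    "gibbs_chain: N = %d, memory D = %d, %d states, pressure = %.6g\n",
    x$n_neurons, x$memory, x$n_states, x$pressure))
  invisible(x)
}

#' Pressure (log Perron eigenvalue) of a Gibbs chain
#'
#' The free energy per time step, `log(lambda)`; enters the
#' Kullback-Leibler estimate `KL = P(phi) - pi(phi) - S(pi)`.
#'
#' @param chain a [build_chain()] result.
#' @return scalar `log(lambda)`.
#' @export
pressure <- function(chain) {
  stopifnot(inherits(chain, "gibbs_chain"))
  chain$pressure
}

#' Exact stationary averages of monomials
#'
#' Expectation of each monomial under the stationary Gibbs chain, computed
#' from the exact distribution of N x R windows.
#'
#' @param chain a [build_chain()] result.
#' @param monomials list of monomials (2-column matrices), with offsets not
#'   exceeding the chain memory `D`.
#' @return numeric vector of stationary averages in `[0, 1]`.
#' @export
exact_averages <- function(chain, monomials) {
  stopifnot(inherits(chain, "gibbs_chain"))
  N <- chain$n_neurons
  n_win <- length(chain$window_dist)
  codes <- 0:(n_win - 1L)
  vapply(monomials, function(m) {
    if (max(m[, "tau"]) > chain$memory)
      stop("monomial depth ", max(m[, "tau"]),
           " exceeds chain memory ", chain$memory)
    on <- rep(TRUE, n_win)
    for (e in seq_len(nrow(m))) {
      bit <- bitwShiftL(1L, (m[e, "neuron"] - 1L) + N * m[e, "tau"])
      on <- on & bitwAnd(codes, bit) > 0L
    }
    sum(chain$window_dist[on])
  }, numeric(1))
}

#' Exact stationary probability of a spike block
#'
#' Probability of observing a given N x len binary pattern in a window of
#' the stationary chain. Lengths up to `R` are marginals of the exact
#' window distribution; longer blocks are obtained by multiplying
#' transition probabilities along the chain.
#'
#' @param chain a [build_chain()] result.
#' @param block N x len binary matrix (columns = successive steps), or an
#'   integer block code.
#' @param len block length in steps (required when `block` is a code).
#' @return stationary probability of the block.
#' @export
exact_block_probability <- function(chain, block, len = NULL) {
  stopifnot(inherits(chain, "gibbs_chain"))
  N <- chain$n_neurons
  if (is.matrix(block)) {
    if (nrow(block) != N) stop("block has ", nrow(block),
                               " rows but chain has ", N, " neurons")
    len <- ncol(block)
    code <- 0
    p2 <- 1
    for (s in seq_len(len)) for (i in seq_len(N)) {
      code <- code + p2 * (block[i, s] != 0)
      p2 <- p2 * 2
    }
  } else {
    if (is.null(len)) stop("len required when block is given as a code")
    code <- as.numeric(block)
  }
  cols <- integer(len)
  cc <- code
  for (s in seq_len(len)) {
    cols[s] <- cc %% 2^N
    cc <- cc %/% 2^N
  }
  R <- chain$range; D <- chain$memory
  if (len <= R) {
    # marginal of the exact window distribution over the first len columns
    n_win <- length(chain$window_dist)
    wcodes <- 0:(n_win - 1L)
    sum(chain$window_dist[wcodes %% 2^(N * len) == code])
  } else if (D == 0L) {
    prod(chain$col_prob[cols + 1L])
  } else {
    w <- sum(cols[seq_len(D)] * 2^(N * (seq_len(D) - 1L)))
    p <- chain$mu[w + 1L]
    for (s in (D + 1L):len) {
      p <- p * chain$transition[w + 1L, cols[s] + 1L]
      w <- chain$next_state[w + 1L, cols[s] + 1L]
    }
    p
  }
}

#' Exact distribution over all blocks of a given length
#'
#' Convenience companion to [exact_block_probability()] for lengths up to
#' the chain range: returns the full vector of stationary probabilities of
#' all `2^(N*len)` blocks, summing to 1.
#'
#' @param chain a [build_chain()] result.
#' @param len block length, `1 <= len <= R`.
#' @return numeric vector indexed by block code + 1.
#' @export
exact_block_distribution <- function(chain, len) {
  stopifnot(inherits(chain, "gibbs_chain"))
  len <- as.integer(len)
  if (len < 1L || len > chain$range)
    stop("len must be in [1, R]; use exact_block_probability for longer")
  N <- chain$n_neurons
  n_win <- length(chain$window_dist)
  wcodes <- 0:(n_win - 1L)
  out <- rowsum(chain$window_dist, wcodes %% 2^(N * len))
  as.vector(out)
}
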