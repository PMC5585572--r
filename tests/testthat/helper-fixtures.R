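# Shared generators for randomized round-trip and oracle tests.

random_raster <- function(n_neurons, n_bins, rate = 0.2) {
  spikes <- lapply(seq_len(n_neurons), function(i) {
    s <- which(stats::runif(n_bins) < rate)
    s
  })
  # guarantee at least one spike somewhere
  if (sum(lengths(spikes)) == 0) spikes[[1]] <- 1L
  spike_raster(spikes, n_bins = n_bins)
}

random_potential <- function(n_neurons, range, n_terms, h_scale = 1) {
  mono <- list()
  keys <- character(0)
  while (length(mono) < n_terms) {
    deg <- sample(1:2, 1)
    neu <- sample(n_neurons, deg, replace = deg > 1)
    tau <- sample(0:(range - 1), deg, replace = TRUE)
    ev <- unique(cbind(neu, tau))
    key <- paste(sort(paste(ev[, 2], ev[, 1], sep = ":")), collapse = ",")
    if (key %in% keys) next
    keys <- c(keys, key)
    mono[[length(mono) + 1L]] <- ev
  }
  gibbs_potential(stats::runif(n_terms, -h_scale, h_scale), mono,
                  n_neurons = n_neurons, range = range)
}

# brute-force energy: sum phi over all windows via potential_value
brute_energy <- function(potential, raster) {
  M <- as.matrix(raster)
  R <- potential$range
  total <- 0
  for (t in seq_len(raster$n_bins - R + 1))
    total <- total + potential_value(potential,
                                     M[, t:(t + R - 1), drop = FALSE])
  total
}
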