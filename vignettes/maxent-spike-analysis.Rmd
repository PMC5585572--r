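---
title: "Maximum-entropy models of spike rasters: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-entropy models of spike rasters: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikegibbs)
```

## The model

A spike raster is a binary matrix $\omega$ with $N$ rows (neurons) and $T$
columns (time bins); $\omega_i(t) = 1$ when neuron $i$ fired in bin $t$.
`spikegibbs` models the stationary statistics of such rasters with Gibbs
(maximum-entropy) distributions. The building blocks are *monomials*
$m_l(\omega) = \omega_{i_1}(\tau_1)\cdots\omega_{i_n}(\tau_n)$ — indicator
products of spike events at time offsets $\tau_k \in [0, D]$ — and a
*potential*

$$\phi(\omega) = \sum_{l} h_l\, m_l(\omega),$$

whose range is $R = D + 1$ ($D$ is the memory depth). The probability of a
raster is proportional to $e^{E(\omega)}$ with
$E(\omega) = \sum_t \phi$ evaluated on the window starting at $t$. The
canned model families are the classical ones: Bernoulli (independent
neurons, range 1), Ising (singles plus same-time pairs), pairwise +
triplets, and the spatio-temporal pairwise model with cross-time pairs
$\omega_i(0)\omega_j(k)$, $1 \le k \le D$. Arbitrary user potentials are
read from a line-oriented text grammar (`h=<float> : w0(0) w1(1) ...`,
0-based neuron indices on disk).

Fitting maximizes statistical entropy under the constraints that the model
averages $\mu[m_l]$ match the empirical window averages $\pi[m_l]$,
equivalently minimizing the Kullback–Leibler divergence from the empirical
measure. For finite rasters exact constraint satisfaction is generally
impossible; the fit approaches it and reports its distance.

## The exact engine

For a range-$R$ potential, the Gibbs distribution is the invariant measure
of a Markov chain with memory $D = R - 1$ over the $2^{ND}$ spatio-temporal
block states. `build_chain()` constructs the transfer matrix
$M(w, c) = e^{\phi(w\cdot c)}$ over state/new-column pairs, extracts the
Perron eigenvalue $\lambda$ and left/right eigenvectors by power iteration
(stationarity residual below $10^{-8}$, Perron vectors normalized positive
and unit-sum; any consistent eigen-normalization yields the same invariant
measure), and exposes transition probabilities, the invariant distribution
$\mu$, exact monomial averages, exact block probabilities, and the pressure
$\log\lambda$. Range-1 potentials take a product-measure fast path with no
state memory. The default size cap is $N\max(D,1) \le 14$ (at most 16,384
states, configurable); everything larger is served by Monte Carlo. The
exact engine doubles as the ground-truth oracle in the test suite.

## Sampling

Two samplers generate rasters from a potential:

* `sample_chain()` draws the initial memory block from $\mu$ and each
  subsequent spike column from the transition probabilities — an exact
  sample of the stationary distribution.
* `sample_metropolis()` runs single-spike-flip Metropolis on the
  finite-window measure $\propto \exp(\sum_{t} \phi)$, accepting a flip
  with probability $\min(1, e^{\Delta E})$ where $\Delta E$ is recomputed
  from only the windows covering the flipped bin. Bins within $R - 1$ of
  the raster edges participate in fewer windows; this finite-size dialect
  of the stationary measure is indistinguishable from the chain sample at
  $T \gg R$, which the tests verify at 4 Monte-Carlo standard errors.

One *sweep* proposes `flips_per_neuron` $\times N \times T$ flips at
uniformly random (neuron, bin) positions, so the burn-in length
(default 100 sweeps) has a mixing meaning independent of the raster size.
Identical seeds give identical rasters.

## Fitting procedure and its knobs

`fit_maxent()` starts from $h = 0$ (an independent fair-coin model; a
potential with non-zero coefficients acts as a warm start) and iterates:

1. estimate the model averages $\mu[m_l]$ — exactly via the transfer
   matrix when the state space permits, else on a Metropolis raster of
   `mc_raster_length` bins;
2. record the **Hellinger error**, the mean per-monomial Bernoulli
   Hellinger distance between $\pi$ and $\mu$ — the package's canonical
   convergence metric;
3. update coefficients. The coordinate step is the standard
   maximum-entropy update
   $h_l \mathrel{+}= \log\frac{\pi_l(1-\mu_l)}{\mu_l(1-\pi_l)}$.
   `n_parallel_iterations` damped all-coordinate steps run first (damping
   defaults to $1/R_{\text{active}}$, the reciprocal of the largest number
   of monomials simultaneously active on any data window, which bounds the
   feature sum that joint-update convergence arguments require), followed
   by `n_sequential_iterations` single-coordinate steps for fine-tuning.

In the Monte-Carlo engine, a step with $\|\delta h\|_\infty <$ `delta`
updates $\mu$ through the **linear response**
$\mu' = \mu + C\,\delta h$ ($C$ the monomial covariance estimated from the
current sample) instead of re-sampling. Iteration stops early when the
Hellinger error falls below `convergence_bound`.

Numerical safeguards: probabilities are clamped to
$[1/(2n_{\text{win}}),\, 1 - 1/(2n_{\text{win}})]$ before log-ratios, so
never-observed events cannot push coefficients to $-\infty$; the
`tolerance_coefficient` filter removes monomials observed at most that
many times before fitting (0 removes only never-observed ones, and
raising it never enlarges the retained set); coefficients are clamped at
$|h_l| \le 20$ with a divergence flag. One master seed drives all
stochastic sub-steps, so identical configurations reproduce identical
error traces.

## Goodness of fit

* **Confidence plot** (`confidence_plot()`): for every spike block
  observed in the data (lengths up to `max_len`), the empirical
  probability $\hat p$ is paired with the model probability $p$ and the
  central-limit standard error
  $\sigma_l = \sqrt{\hat p(1-\hat p)/n_{\text{win}}}$, computed per block
  length. Under a perfect model about 99.7% of points fall within
  $3\sigma_l$ of the diagonal. Because successive windows of one raster
  overlap, block counts are serially correlated and the i.i.d. binomial
  $\sigma_l$ slightly understates the true sampling variability; measured
  coverage therefore sits a few tenths of a percentage point below the
  nominal 99.7% even for the true generator. We keep the plain binomial
  $\sigma_l$ (it is the estimator a practitioner can always compute) and
  document the effect rather than correcting for it. A model-based
  $\sigma$ is available behind a flag.
* **Kullback–Leibler estimate** (`kl_estimate()`): uses the thermodynamic
  identity $KL = P(\phi) - \pi(\phi) - S(\pi)$, with $P$ the pressure,
  $\pi(\phi) = \sum_l h_l \pi[m_l]$, and $S(\pi)$ the empirical entropy
  rate obtained by extrapolating block entropies $H_n$ ($n \le$ `n_max`,
  default 6): a least-squares line through the last three $(n, H_n)$
  points whose slope is the rate. Each $H_n$ carries a Miller–Madow
  correction $(K-1)/2n_{\text{win}}$ ($K$ = observed patterns), removing
  the leading small-sample bias, which would otherwise be of the same
  order as the divergences being measured at $T = 10^5$. The correction
  can be disabled. The raw (possibly slightly negative) estimate is
  reported alongside a floored-at-zero value so estimator bias stays
  visible.

## Retina simulator

The stimulus-to-spikes pipeline has two stages. A linear front-end
(`compute_drive()`) tiles difference-of-Gaussians model cells over the
image; each frame's center and surround responses pass through first-order
exponential low-pass filters (defaults: center $\sigma = 2$ px, surround
$3\times$ wider with weight 0.8, time constants 10 and 30 ms, unit gain),
giving the drive current $I_i(t)$. This deliberately simple linear stage
is a pluggable provider — externally computed current matrices are
accepted in its place — and does not attempt to model nonlinear inner
retinal processing (shunting feedback, contrast gain control).

The spiking stage is a coupled discrete-time leaky integrate-and-fire
network at $dt = 1$ ms:

$$V_i(t+1) = \gamma V_i(t)\,(1 - Z_i(t)) + \frac{I_i(t)}{C} +
  \frac{1}{C}\sum_j W_{ij} Z_j(t) + \frac{\sigma_B}{C} B_i(t),$$

with $Z_i = 1$ iff $V_i \ge \theta$, leak factor
$\gamma = 1 - dt/\tau_L \in [0,1]$, and i.i.d. standard Gaussian noise
$B$. The reset acts only through the $(1 - Z_i)$ factor (no extra
refractory period), and potentials are measured relative to the leak
reversal so the reset value is 0. Defaults: $\gamma = 0.9$
($\tau_L = 10$ ms), $C = 1$, $\theta = 1$, $\sigma_B = 0.1$. Connectivity
$W_{ij}$ (presynaptic $j$ onto postsynaptic $i$) comes in `none`,
`sparse` (exact non-zero count), `dense`, or `file` schemes; default
weights are zero-mean Gaussians scaled by the inverse square root of the
expected in-degree. Noise is pre-generated per neuron and bin from the
seed, so results are independent of iteration order. With $W = 0$ and
$\sigma_B = 0$ the trajectory follows the affine closed form between
spikes to machine precision — constant subthreshold drive converges to
$I/(C(1-\gamma))$, and suprathreshold drive fires with period
$n^\* = \min\{n : (I/C)(1-\gamma^n)/(1-\gamma) \ge \theta\}$ — which the
tests assert exactly.

## Receptive fields

`compute_sta()` estimates spike-triggered-average receptive fields as 3D
volumes $RF(x, y, z)$: slice $z$ (0-based) averages the frame on screen at
lag $-(n_f - 1 - z)\,t_d$ before each spike, where $t_d$ is the mean
successive time-stamp difference. A lag maps to the unique frame whose
onset interval contains it (the last frame's interval extends one $t_d$
past its onset); spikes whose earliest lag has no frame are skipped and
excluded from `n_spikes_used`. Spike times are taken at bin starts. The
peak temporal profile passes through the global argmax, with ties broken
deterministically by smallest $(z, y, x)$. Spatial downsampling ($s_d$)
is optional block averaging, default 1. Export writes min–max-normalized
PNG slices (constants recorded) plus a lossless JSON volume.

## Synthetic data and what the tests show

Built-in generators supply all test inputs: independent Bernoulli rasters,
periodic rasters, binary or Gaussian white-noise stimuli with uniform time
stamps (binary by default, matching checkerboard-style mapping protocols),
and thresholded-linear (LN) model spikes with a planted spatial kernel.
These fixtures emulate the statistical structure the methods address —
prescribed rates, spatio-temporal correlations from known Gibbs models,
stimulus-locked spiking — but not the nonstationarity, refractoriness,
spike-sorting artifacts or adaptation of real recordings, so green tests
certify the estimators against their own model class, not biological
fidelity.

Study problem sizes: samplers and fits are validated on rasters of
$10^5$ bins for models up to $N = 5$, $R = 2$; parameter recovery of
random coefficients in $[-1, 1]$ is required to max absolute error 0.15;
confidence-region coverage is measured over 20 independent model/raster
draws; LN filter recovery uses on the order of 5,000 spikes.

## Known limitations

* The exact engine is capped at desk scale ($2^{14}$ states); large-$N$
  work relies on the Metropolis sampler, whose samples are serially
  correlated (effective sample sizes below $T$).
* Confidence-region coverage inherits the overlapping-window correlation
  noted above.
* The simulator's front-end is linear; inner-retina nonlinearities and
  structured amacrine coupling are out of scope.
* Statistics are stationary by construction; nonstationary rasters
  violate the model assumptions silently.
* Archival raster and RF-volume files use the package's documented JSON
  container; plain-text spike files cover the common MEA export dialects
  (pairs, per-neuron rows).
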