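---
title: "Uncovering diffusive states from single-particle trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncovering diffusive states from single-particle trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pemtrack)
```

## The problem

Single-particle tracking by photoactivated localization microscopy (sptPALM)
yields thousands of trajectories of individual membrane proteins, but each
trajectory is short — typically 15-60 frames before the fluorophore
bleaches — and each recorded position is corrupted by two noise sources.
*Static localization noise* (standard deviation $\sigma$, from finite photon
counts) adds independent error to every position, which inflates the apparent
displacement variance and induces a *negative* correlation between
consecutive displacements. *Dynamic localization noise* (motion blur) arises
because the camera averages the particle's position over the exposure; it
*reduces* the apparent variance and adds a positive contribution to the
nearest-neighbour correlation.

A protein switching between biochemical interaction partners realizes
different diffusive states, each characterized by a diffusivity $D_k$ and a
static noise $\sigma_k$. A single short track cannot pin these down: the
single-track covariance-based estimate (CVE) of $D$ has a relative standard
deviation of order $\sqrt{6/N}$, around 50% at $N = 25$ displacements. The
population, however, can. `pemtrack` fits all $M$ trajectories at once with
a mixture model and lets the trajectories share statistical strength.

## The model

For one trajectory the displacement vector
$\Delta x_m = (\Delta x_m(1), \ldots, \Delta x_m(N_m))$ in one spatial
dimension is, under normal diffusion, a zero-mean multivariate Gaussian with
symmetric tridiagonal covariance

$$\Sigma_k(i,j) = \begin{cases}
  2D_k\Delta t + 2\sigma_k^2 - 4RD_k\Delta t & i = j\\
  -\sigma_k^2 + 2RD_k\Delta t & j = i \pm 1\\
  0 & \text{otherwise,}
\end{cases}$$

where $\Delta t$ is the frame interval and $R$ the motion-blur coefficient
($R = 1/6$ for full-frame exposure, $R = (1/6)\,\Delta t_E/\Delta t$ in
general). The population log-likelihood is a $K$-component Gaussian mixture
over trajectories,

$$\ln\mathcal L = \sum_{m=1}^M \ln \sum_{k=1}^K \pi_k\,
  P(\Delta x_m \mid \Sigma_k),$$

with population fractions $\pi_k$. The two spatial dimensions are treated
isotropically: the complete log-likelihood sums the per-dimension mixture
log-likelihoods, and reported parameters average the per-dimension
estimates.

The likelihood of every track under every state is evaluated in $O(N)$ by an
LDL$^\mathsf{T}$ recursion on the tridiagonal covariance; the diagonal
dominance of the band ($2D\Delta t + 2\sigma^2 - 4RD\Delta t >
2\,|{-\sigma^2 + 2RD\Delta t}|$ for $D > 0$, $R \le 1/4$) guarantees positive
definiteness. Because the pivots of the length-$N_{\max}$ recursion factorize
every leading submatrix, one pivot vector per state serves all track lengths,
and the per-track sweep is a single pass in compiled code.

## Estimation: EM with a covariance-based M-step

The expectation step computes, per dimension, the posterior probability
$\gamma_{mk}$ that track $m$ realizes state $k$ (log-domain arithmetic with
log-sum-exp normalization). The maximization step uses the covariance-based
(CVE) moment expressions

$$D_k = \frac{1}{2\Delta t M_k}\sum_m \gamma_{mk}\left(
  \langle\Delta x_m^2\rangle +
  2\langle\Delta x_m(n)\,\Delta x_m(n+1)\rangle\right),
  \qquad M_k = \sum_m \gamma_{mk},$$

$$\sigma_k^2 = \frac{1}{2M_k}\sum_m \gamma_{mk}\langle\Delta x_m^2\rangle
  - D_k\Delta t(1 - 2R), \qquad \pi_k = M_k / M,$$

where the angle brackets are per-track means, so every track carries equal
weight regardless of its length. Iteration stops when the relative
log-likelihood change falls below `tol` (default `1e-7`, chosen so that
500-track fits converge in well under a second) or after `max_iter`
iterations (default 500).

### Two numerical facts worth knowing

**The iteration is a fixed-point scheme, not an exact EM.** The CVE
expressions are moment estimators, not the maximizers of the EM surrogate,
so the likelihood trace is not mathematically guaranteed to be monotone.
In practice it rises steeply, can overshoot the fixed-point value by a small
amount (up to a few nats from a random start), and then relaxes
geometrically onto the fixed point — the decrements shrink by roughly an
order of magnitude per iteration. The package reports the full trace in
every fit so this behaviour is visible; the tests assert the honest
contract (large net rise, decaying relaxation, exact one-step fixed point
at $K = 1$) rather than strict monotonicity.

**Which posterior drives the M-step matters.** The reported posterior is the
average of the two per-dimension posteriors, and classification uses it.
For the *M-step*, however, each dimension's update is driven by that
dimension's own posterior (`gamma_mode = "per_dim"`, the default), making
each dimension's update a complete 1D M-step before the two parameter
estimates are averaged. The alternative — driving both dimensions with the
dimension-averaged posterior (`gamma_mode = "averaged"`) — looks more
symmetric but is measurably worse: the averaged responsibilities are soft
enough that the moment fixed point merges neighbouring slow states even
when the iteration is started at the generating parameters, and four-state
benchmarks then collapse to three states. Since the per-dimension
convention is the one that reproduces model-size recovery from realistic
track numbers, it is the default; the averaged variant stays available for
comparison.

Raw CVE and M-step estimates of $D$ and $\sigma^2$ may legitimately be
negative for short tracks; they are preserved for reporting, and only the
covariance construction floors them ($D \ge 10^{-9}\,\mu m^2/s$,
$\sigma^2 \ge 10^{-12}\,\mu m^2$) to keep the matrix positive definite.
States whose effective membership falls below $10^{-6}$ are kept with
floored parameters rather than deleted, so the model size is constant
within a run.

## Escaping local maxima: perturbation EM

EM converges to a local maximum that depends strongly on the start. Instead
of brute-force restarting, `pem_fit()` perturbs the likelihood surface:
it draws a Monte-Carlo bootstrap resample of the trajectories (same $M$,
sampled with replacement), runs EM on the resample starting from the current
parameters, and then *verifies* the candidate on the original data — the
candidate is adopted only if it improves the original-data likelihood, in
which case EM is re-run on the original data from the candidate parameters.
Only verified improvements are kept, so the sequence of adopted parameter
sets moves strictly upward on the unperturbed likelihood surface. A restart
gives up after `n_perturb` consecutive fruitless trials.

Initialization is non-parametric: $K$ uniform draws are normalized into
fractions $\pi^0$; the initial $D_k^0$ are the empirical quantiles of the
per-track CVE diffusivity distribution at the midpoints of the $K$ regions
the fractions delimit; the initial noise is the population-mean CVE noise.

Each restart owns its perturbation budget (the restarts are independent and
could run in parallel without changing results, since each consumes its own
stream of draws sequentially).

## Choosing the number of states

The sweep `pem()` fits each candidate $K$ and scores it with
$\mathrm{BIC} = \ln\mathcal L - K\ln M$, selecting the maximum and breaking
ties toward smaller $K$. This penalty counts *states* rather than free
parameters; the conventional $\frac{3K-1}{2}\ln M$ penalty is available via
`penalty = "parameters"` for sensitivity analysis. Defaults are
`K = 1:6`, `n_restarts = 10`, `n_perturb = 20`; the worked analyses below
and the package's own benchmark runs use 3 restarts with a 5-trial budget,
which at $M = 500$ reproduces the model-size results in about half a minute
per sweep.

## The simulator

`simulate_tracks()` generates the conditions the estimator is built for:

* **Brownian micro-stepping**: positions evolve as
  $x_{i+1} = x_i + \sqrt{2D\,\delta t}\,W_i$ at a micro-interval
  $\delta t = \Delta t / n_{micro}$ (default $n_{micro} = 32$; at
  $\Delta t = 32$ ms that is a 1 ms micro-step).
* **Motion blur**: each recorded frame position is the average of the
  micro-positions inside the exposure window; full-frame exposure averages
  all 32 (the discrete 32-point average realizes an effective blur
  coefficient $(n^2-1)/(6n^2)$, within 0.1% of the continuum $1/6$).
* **Static noise**: independent $\mathcal N(0, \sigma^2)$ added per frame
  and dimension.
* **Track lengths**: $N = \lfloor (N_{\max}-N_{\min})e^{-rZ} +
  N_{\min}\rfloor$ with $Z \sim U(0,1)$ and
  $r = (N_{\max}-N_{\min})/(\langle N\rangle - N_{\min})$; the defaults
  (15, 60, mean 25, hence $r = 4.5$) mimic bleaching-limited sptPALM track
  durations. Flooring the real-valued length makes the printed minimum of
  15 attainable.
* **Mixtures**: state $k$ contributes $\mathrm{round}(\pi_k M)$ tracks
  (rounding remainders go to the largest-fraction state, deterministically);
  the per-track generating state is recorded as ground truth.
* **State switching** (`simulate_switching_track()`): a per-frame Markov
  chain for robustness studies of the no-transition assumption.

What the simulator does *not* emulate: confined or anomalous diffusion,
transitions within a track (except through the dedicated switching
generator), localization-dependent noise, and tracking errors
(misconnections, gaps). Passing the in-silico benchmarks therefore
demonstrates correctness of the estimator under its own model assumptions,
not robustness to every pathology of real data.

## Benchmark conditions

Two standard four-state configurations (`benchmark_states()`) span the
diffusivity range typical of membrane proteins (about $10^{-3}$ to
$1\,\mu m^2/s$) with constant $\sigma = 0.05\,\mu m$ and equal fractions:

* *separated*: $D = 0.002, 0.035, 0.2, 0.7\ \mu m^2/s$ — neighbouring
  single-track CVE distributions barely overlap;
* *overlapping*: $D = 0.02, 0.08, 0.2, 0.45\ \mu m^2/s$ — neighbours within
  a factor 2-4, substantially overlapping single-track distributions.

With 500 variable-length tracks, sweeps over $K = 1..6$ select $K = 4$ as
the modal choice across replicate populations in both regimes; the
two-state recovery benchmark ($D = 0.02/0.5$, $\pi = 0.5/0.5$, $M = 1000$)
returns diffusivities within a few percent and fractions within a few
hundredths. These are exactly the quantities `scripts/acceptance.R`
recomputes from scratch.

## The CDF baseline

For benchmarking, `fit_cdf()` implements the classical pooled approach: the
empirical cumulative distribution of all squared 2D displacements
$\Delta r^2$ is fit by
$1 - \sum_k \pi_k e^{-\Delta r^2/(2\rho_k)}$ with
$\rho_k = 2D_k\Delta t + 2\sigma^2 - 4RD_k\Delta t$, by box-constrained
Levenberg-Marquardt least squares evaluated at every observed $\Delta r^2$.
Its two structural weaknesses are visible in the formula: $\sigma$ must be
supplied (it cannot be separated from $D$ with pooled single-lag data), and
pooling destroys the per-track correlation information that lets the
mixture likelihood separate overlapping states. On matched simulations the
mixture fit's diffusivity error is never worse.

## Classification and downstream analyses

`predict()` on a fitted model yields maximum-a-posteriori state labels with
confidences (ties break deterministically to the lower state index), or the
full posterior matrix. `posterior_weighted_map()` exports per-track
centroids weighted by state membership — the data behind posterior-weighted
spatial maps, with rendering left to the caller.
`decompose_activation()` expresses an intermediate population's empirical
diffusivity CDF as the best convex combination $wF_a + (1-w)F_b$ of two
reference conditions, solved in closed form on the pooled grid of observed
values (no binning) and clipped to $[0,1]$.

## Design choices where the design was open

* *Minimum track length* counts displacements (default 15); the flag is
  exposed in `read_tracks()` since conventions differ.
* *Frame gaps* drop the track by default (a gap breaks the uniform-$\Delta t$
  covariance); splitting at gaps is available behind `split_gaps`.
* *Initial diffusivity quantiles* use the inverse-ECDF quantile
  (`type = 1`), the literal empirical distribution.
* *Empty-state handling* floors rather than deletes, keeping $K$ fixed so
  the BIC sweep compares what it claims to compare.
* *Ties in BIC* go to the smaller model.
* *CLI configuration* uses JSON (flags override file values); every run
  writes a `config.json` snapshot with the seed and package version so an
  output directory reproduces bit-for-bit.

## Limitations

The model assumes every track stays in one normal-diffusive state; with
frequent switching the fractions degrade first (the switching simulator is
provided to quantify this). Estimates for states with small $D$ rely on the
noise-correlation structure and need larger $M$; model-size recovery for
many overlapping or rare states requires thousands of tracks. The BIC
penalty $K\ln M$ is deliberately mild; with very large $M$ it may admit an
extra marginal state, which the parameter-counting variant penalizes more
harshly.
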