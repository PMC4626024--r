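# pemtrack

Population-level analysis of single-particle trajectories: `pemtrack`
uncovers the number and properties of **normal diffusive states** — each a
pair of diffusivity *D* (μm²/s) and static localization noise *σ* (μm) with
a population fraction *π* — from large collections of short, noisy 2D
tracks, the kind produced by sptPALM imaging of membrane proteins
(Rho GTPases being the archetypal application). Distinct biochemical
interaction states of a protein manifest as distinct diffusive states; the
package is for cell biologists and microscopists who want to resolve that
system of states from trajectory data alone.

## The method in brief

Individual tracks are too short (15–60 frames) to estimate their own
diffusive state reliably, so all *M* tracks are fit at once. In one spatial
dimension the displacement vector of a track in state *k* is multivariate
normal with symmetric tridiagonal covariance

    Σ_k(i,i)   = 2 D_k Δt + 2 σ_k² − 4 R D_k Δt
    Σ_k(i,i±1) = −σ_k² + 2 R D_k Δt

(Δt = frame interval, R = motion-blur coefficient, 1/6 at full-frame
exposure): static noise inflates the variance and anti-correlates
neighbouring displacements, blur does the reverse. The population
log-likelihood is the Gaussian mixture

    ln L = Σ_m ln Σ_k π_k P(Δx_m | Σ_k),

maximized by expectation-maximization whose M-step uses covariance-based
(CVE) moment updates for D_k and σ_k². To escape local maxima, converged
solutions are *perturbed*: EM is re-run on Monte-Carlo bootstrap resamples
of the track set and a candidate is adopted only if it verifiably improves
the original-data likelihood (perturbation EM, "pEM"). The number of states
is selected by sweeping K and maximizing BIC = ln L − K ln M.

The package also provides the trajectory simulator used for validation
(Brownian micro-stepping, 32-point motion blur, static noise, realistic
track-length distribution, known ground truth), per-track CVE estimators,
posterior-based classification and posterior-weighted spatial maps, an
activation-level CDF decomposition, and the classical pooled
squared-displacement CDF fit as a baseline.

## Worked example

Simulate a two-state population and recover it:

```r
library(pemtrack)

acq <- acquisition_params(dt = 0.032)          # 31 Hz imaging, R = 1/6
sim <- simulate_tracks(D = c(0.02, 0.5), sigma = 0.05, pi = c(0.5, 0.5),
                       M = 500, acq = acq, seed = 1)
fit <- pem(sim$tracks, K = 1:4, n_restarts = 3, n_perturb = 5, seed = 2)
fit
#> Perturbation-EM diffusive-state analysis
#>   500 trajectories; candidate K = 1, 2, 3, 4; selected K = 2
#>   lnL = 19327.4029, BIC = 19314.9737
#> 2 diffusive state(s):
#>  state       D   sigma     pi
#>      1 0.02036 0.05027 0.5008
#>      2 0.49070 0.04977 0.4992
```

Both generating states (D = 0.02 and 0.5 μm²/s, σ = 0.05 μm, equal
fractions) are recovered within ~2%, and BIC picks K = 2: adding a third
state buys only ~0.2 nats of likelihood, far less than the ln 500 ≈ 6.2
penalty per state:

```r
summary(fit)$table
#>   K   loglik      BIC converged n_iter
#> 1 1 15736.02 15729.81      TRUE      2
#> 2 2 19327.40 19314.97      TRUE      5
#> 3 3 19327.62 19308.98      TRUE    351
#> 4 4 19327.82 19302.96      TRUE    386

table(predicted = predict(fit)$state, truth = sim$truth$state)
#>          truth
#> predicted   1   2
#>         1 250   0
#>         2   0 250
```

Every track is classified to its generating state here because the two
states are well separated; `predict(fit, type = "posterior")` retains the
soft memberships for harder mixtures. Real data enter through
`read_tracks("tracks.csv", acq)` (columns `track_id,frame,x,y`, positions
in μm), and a command-line wrapper with `simulate` / `fit` / `cdf`
subcommands is installed at
`system.file("cli", "pemtrack.R", package = "pemtrack")`.

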