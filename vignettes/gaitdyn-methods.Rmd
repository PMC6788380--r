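---
title: "Methods: latent locomotor dynamics and kinematic decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latent locomotor dynamics and kinematic decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models it fits, the
numerical choices behind them, what the synthetic-data generator does and does
not emulate, and where the design was genuinely open. It states no empirical
result that the test-suite does not itself compute.

## 1. The state-space model and its assumptions

`gaitdyn` models a population of simultaneously recorded motor-cortex units
during locomotion as a Poisson linear dynamical system (PLDS). A latent state
$x_t \in \mathbb{R}^p$ evolves once per 10 ms bin as a linear-Gaussian Markov
chain, and the spike count of unit $i$ in bin $t$ is conditionally Poisson
with an exponential link:

$$x_1 \sim N(x_0, Q_0), \qquad x_{t+1} = A x_t + w_t,\; w_t \sim N(0, Q),$$
$$y_{it} \mid x_t \sim \mathrm{Poisson}\!\left(\exp(c_i^\top x_t + d_i)\right).$$

The assumptions this buys and their costs:

* **Linearity of the dynamics.** Gait is quasi-periodic; a linear $A$ with a
  complex-conjugate eigenvalue pair represents a (damped) rotation, which is
  the dominant structure of locomotor population activity. Nonlinear limit
  cycles are approximated, not represented.
* **Conditional Poisson counts.** Variance equals the conditional mean. Real
  cortical counts are often overdispersed; overdispersion is absorbed,
  imperfectly, into latent variance.
* **Trials as independent sequences.** Each gait cycle restarts from
  $(x_0, Q_0)$ and shares parameters. This matches cycle-segmented data and
  keeps the E-step embarrassingly parallel across trials, at the cost of
  discarding continuity of the latent across cycle boundaries.
* **10 ms bins.** Fixed by the 100 Hz kinematic frame clock; all bin/frame
  indexing in the package is 1:1 by construction.

## 2. Inference: Laplace E-step on the whole trajectory

The posterior over one trial's latent path $x_{1:T}$ given counts is
non-Gaussian. `plds_laplace_estep()` finds its mode by Newton's method on the
log joint of the full sequence. The negative Hessian is symmetric
block-tridiagonal ($p \times p$ blocks: prior precision terms plus
$C^\top \mathrm{diag}(\lambda_t) C$ per bin), so each Newton solve, the
log-determinant for the Laplace evidence, and the diagonal and first
off-diagonal blocks of the inverse (posterior covariances and adjacent-bin
cross-covariances) are all computed by a forward Schur-complement recursion in
$O(T p^3)$ — never by dense $Tp \times Tp$ algebra. The same block algebra is
implemented twice: a pure-R reference and an Armadillo fast path; the suite
asserts their agreement to ~1e-10.

Numerical safeguards: backtracking (Armijo) line search on the log joint; a
cap of 100 Newton iterations with gradient tolerance $10^{-8}$; the linear
predictor is clamped at 30 before exponentiation (an overflow guard — a rate
of $e^{30}$ per 10 ms is six orders of magnitude beyond physiology); and a
stall rule accepts the mode when the line search hits the arithmetic floor
with the gradient already below $10^{-5}$. Non-convergence is an error that
reports the final gradient norm, not a silent result.

**The Gaussian test hook.** With `family = "gaussian"` the observation term is
quadratic, the "approximation" is exact, and the E-step must reproduce a
Kalman (RTS) smoother and brute-force conditioning of the joint multivariate
normal. This three-way agreement (to 1e-8) is the package's primary inference
correctness check, because the three routes share no code: the smoother is a
separate filter/smoother implementation and the brute-force oracle lives in
the test helpers.

A causal point-process filter (`plds_decode(..., causal = TRUE)`) is provided
for real-time-style decoding; the smoothed posterior mean remains the default
latent feature, since nothing in the offline analysis forbids acausal
estimates. (Whether the original analyses filtered or smoothed test trials is
not documented; we chose smoothing and expose the option.)

## 3. Learning: EM with an ascent safeguard

The M-step is standard where it can be: $A, Q, x_0, Q_0$ have closed forms in
the posterior first/second moments. The loadings $(C, d)$ are updated by
per-unit Newton ascent on the expected Poisson log likelihood using
$E[e^{c^\top x}] = e^{c^\top\mu + c^\top\Sigma c/2}$; each unit's problem is
$(p{+}1)$-dimensional and concave.

Because the evidence itself is Laplace-approximated, the M-step maximises a
surrogate, and a full parameter step can *decrease* the approximate evidence
(classical behaviour of Laplace EM). We therefore evaluate the evidence after
each M-step and, if it decreased, halve the parameter step toward the previous
iterate (covariances re-symmetrised and eigenvalue-floored) up to six times;
if no ascent remains, EM stops at what is then a local maximum of the
approximate evidence. This keeps the reported objective trace non-decreasing
(the acceptance suite checks a $10^{-6}$-scaled tolerance) at the cost of one
extra evidence pass per iteration. Convergence is declared when the relative
objective change falls below `tol` (default $10^{-6}$) or after `max_iter`
(default 100) iterations; both are logged in the fit object together with the
worst observed decrease and the number of damping events.

**Initialisation** (seed-controlled): PCA on z-scored, square-root-transformed,
lightly smoothed counts gives a latent basis; $C, d$ come from per-unit
log-linear regression on those scores. The initial $A$ is estimated from
*unsmoothed* scores — smoothing makes measurement noise mimic a slow real
mode — using the two-lag ratio $M_2 M_1^{-1}$ of lagged regression
coefficients, which cancels the attenuation that white measurement noise
induces on a one-lag AR fit and would otherwise bias rotation frequencies
toward zero. We found the one-lag initialisation sent EM into a
real-eigenvalue local optimum on low-rate fixtures; the two-lag form fixed
this without touching the EM itself.

Latent bases are identifiable only up to an invertible map $M$:
$(A,Q,C,x_0,Q_0) \to (MAM^{-1}, MQM^\top, CM^{-1}, Mx_0, MQ_0M^\top)$ leaves
rates and evidence unchanged (asserted by test). Recovery checks therefore
compare similarity invariants — eigenvalue moduli/angles of $A$ and principal
angles between loading column spaces — never raw matrix entries.

## 4. Decoding design

**Features.** Four feature sets feed the same decoder: `fp` (z-scored
firing rates of all units), `pca` (top components of the z-scored rates),
`pss` (z-scored rates of a greedily chosen unit subset), `plds`
(posterior-mean latents). Rate features use a 100 ms trailing window (sum of
the current and previous nine 10 ms counts divided by 0.1 s) computed on the
continuous recording, so within-trial rates always have full context; the
first nine bins of a continuous epoch use the partial window divided by its
actual duration. PLDS consumes the raw 10 ms counts.

**Wiener filter.** Order 10 (lags 0-9), multi-output least squares with an
intercept, solved by QR; a rank-deficient design falls back to the
minimum-norm (SVD) solution with a warning. The lagged design is built within
each trial and the first `order - 1` samples of every trial are excluded from
fitting *and* scoring. The alternative — borrowing lag context from the
continuous recording — is available to rate features but not to per-trial
PLDS latents; uniform exclusion makes the scored samples identical across all
four decoders, so their $R^2$ values are paired sample-for-sample. With
~50-100-bin gait cycles this discards <20% of samples.

**Scoring.** $R^2 = 1 - \sum(y_i-\hat y_i)^2 / \sum(y_i-\bar y)^2$ per trial
per variable, with $\bar y$ the *per-trial* mean; it is unbounded below and
at most 1. Constant-target trials are skipped with a warning (zero
denominator). An independently coded formula must agree to 1e-12 (test).

**Cross-validation.** All trials of all tasks are shuffled (seeded) and split
into 10 blocks whose sizes differ by at most one (remainders to the earliest
blocks). Every feature stage — z-scoring statistics, PCA projection, PSS
selection, PLDS EM — is fitted on the nine training blocks only. Kinematic
variables are decoded only for trials with kinematics; the gait-phase ramp is
decoded for every trial, so sessions without any kinematics still yield
phase results. Gait phase is decoded as the raw 0-100% ramp rather than its
sine/cosine: each trial spans exactly one cycle, so the wrap discontinuity
never occurs inside a scored segment.

**Dimensionality sweep.** `dim_sweep()` repeats the CV at each dimensionality
and reports mean $R^2$ (for PLDS also the held-out Laplace evidence); the
plateau is the first dimensionality whose increment over the previous one is
below 0.001. With a single dimensionality the plateau is undefined (NA).

**PSS criterion.** Forward selection maximises the mean validation $R^2$
across *all* target variables of a Wiener decoder trained on the current
subset, evaluated on a 20% inner split of the training trials; ties break to
the lowest unit index. The cited prior work does not restate whether its
criterion was single- or multi-variable; the multi-variable mean matches the
multi-output decoder use and is the documented default.

## 5. Trajectory geometry

`normalize_gait_cycle()` resamples each trial's latents onto a 100-point
gait-percent grid by linear interpolation against the within-trial phase
(stance 0-60%, swing 60-100%); grid point 60 carries the toe-off bin exactly
and point 100 the cycle's last sample (values beyond the last sampled phase
are held, not extrapolated). `mahalanobis_profile()` estimates the reference
distribution *per grid point* (mean and covariance across reference trials at
that point, in the full requested dimensionality) rather than pooling over
the cycle: distance-vs-gait-percent profiles require a per-point
distribution, and pooling would mix stance and swing geometry. This is a
documented choice, not a claim about the original implementation. With few
reference trials a $p$-dimensional per-point covariance is singular, so it is
shrunk toward its diagonal with intensity $\alpha = p/(p + n_\mathrm{ref})$
(automatic when $n_\mathrm{ref} \le p$, zero otherwise, overridable), plus a
$10^{-10}$ ridge; the intensity is recorded on the result. Mahalanobis
distance is affine-invariant only with shrinkage off, and the test asserts
exactly that. Speed separation is summarised by the Spearman rank correlation
between each speed's mean distance to the fastest-speed reference and the
absolute speed difference; with fewer than three comparison speeds it is
reported as NA.

## 6. Spectral smoothness and statistics

Decoder-output smoothness is compared via Thomson multitaper PSDs. No
multitaper package is available in the target environment, so DPSS tapers are
computed from the standard symmetric tridiagonal commuting-operator
formulation (eigenvectors, unit energy, deterministic sign), verified against
frozen `scipy.signal.windows.dpss` values. Defaults: time-bandwidth NW = 4
with 7 tapers (the source analysis names only "Thomson's multitaper method");
per-trial spectra are one-sided, mean-removed (so a constant trial carries no
power — the variance, not the offset, is the quantity of interest), and
interpolated onto a common 0-50 Hz grid before averaging across trials of
unequal length, a choice the original description leaves open. The PSD
integrates to the signal variance within taper bias (tested). Smoothness is
the fraction of total power above a cutoff (10 Hz default).

Decoder comparisons across sessions use a two-tailed Wilcoxon signed-rank
test on per-session mean $R^2$ paired against the full-population baseline,
with Benjamini-Hochberg step-up at FDR 10% across variables within each
decoder. The signed-rank null distribution is exact (dynamic programming over
rank subsets) for $n \le 25$ untied pairs and a normal approximation with
continuity and tie corrections beyond; zero differences are dropped, and an
all-zero difference vector is flagged degenerate with $p = 1$. Both the exact
distribution and the BH rule are tested against brute-force enumeration. (The
source text mentions parametric tests once in passing but names the
signed-rank test in its methods; the named test is what is implemented.)

## 7. The synthetic world

`generate_session()` states a ground-truth world with the structure the
analysis assumes. One session is a continuous epoch of back-to-back gait
cycles:

* **Latents**: a deterministic rotating mean — phase advances exactly one
  rotation per cycle on dims 1-2 (radius 1), a 0.4-amplitude second harmonic
  on dims 3-4 — plus stationary AR(1) noise (coefficient 0.95 per bin,
  stationary SD `latent_noise_sd`, default 0.12). The phase is continuous
  across cycles and never reset. A free-running stochastic oscillator was
  considered and rejected: with variable cycle durations a single transition
  matrix cannot complete exactly one rotation per cycle, and free-running
  phase noise accumulates across a session, destroying the gait phase-locking
  that real locomotor trajectories show. The per-cycle rotation rate keeps
  trajectories phase-locked while `params_true` records the mean-period
  dynamics matrix as the LDS summary of the mean flow.
* **Conditions**: each trial carries a task label and a treadmill speed
  (defaults: the seven training speeds 1.1-6.4 km/h); speed shifts the latent
  mean on one axis (`speed_offset_gain`, default 0.3 latent units per km/h,
  centred on the mean speed) and each non-treadmill task gets a fixed random
  offset — the separation-along-one-dimension structure seen in real
  sessions.
* **Counts**: conditionally Poisson with rate $\exp(Cx + d)$; tuning vectors
  have norms 0.4-1.2 (modulation up to roughly $e^{\pm 1}$ over a cycle) and
  baselines `base_log_rate_range` default $[-3, -0.8]$ log(spikes/bin), i.e.
  5-45 spikes/s — typical of task-modulated M1 units during active
  locomotion. Configurations whose rates could exceed 20 spikes per 10 ms bin
  are rejected (overflow guard and physiological bound).
* **Kinematics**: six hind-limb markers (iliac crest = origin) as affine
  functions of the latents around a macaque-like base pose, cm-scale
  excursions growing proximal to distal, plus i.i.d. Gaussian noise
  (`kinematic_noise_sd`, default 3 mm — video-tracking scale). Frames align
  1:1 with bins. Gait events sit at phase 0 and 60% of each cycle; a
  configurable fraction of trials (default 15%) has kinematics flagged
  absent, mimicking video occlusion.
* **Inter-trial variability** is exposed as `latent_noise_sd` rather than
  fixed, because no magnitude is documented for the real data.

What the generator does **not** emulate — and hence what a green test does
not establish: count overdispersion and non-Poisson spiking statistics;
neural structure outside the latent subspace (in this world the latents carry
*all* shared signal, which flatters model-based decoders relative to raw-rate
decoders more than real data would); biomechanical constraints linking
markers (readouts are affine, so derived joint angles are soft nonlinear
functions rather than rigid-segment kinematics); electrode drift or
nonstationarity; and spike sorting artefacts. Marker positions are exactly
affine in the latents, so the noise-free ideal-decoding ceiling is exactly 1
for positions but necessarily below 1 for the trigonometric angle variables,
leg extension (a Euclidean norm) and the phase ramp — the tests assert the
exact ceiling only where it exists.

## 8. Runtime scaling in the acceptance suite

The acceptance properties run at the stated sizes (e.g. parameter recovery at
30 units, latent dimension 4, 200 trials, 3 seeds). Two concessions keep the
suite inside its compute budget, both affecting iteration caps only, never
thresholds or tolerances: per-fold PLDS EM in the ten-session decoding-parity
check is capped at 12 iterations (tol $10^{-4}$), and those sessions use 45
trials each (within the range of the real recording days). The
decoding-parity criterion is one-sided — the 12-dimensional PLDS decoder must
decode every variable at least as well as the full population minus 0.05 —
because the claim it mirrors is "just as well or better"; on this synthetic
world PLDS in fact wins by a clear margin (reported by the test), for the
flattering reason documented in section 7.

## 9. Known limitations

* Laplace EM maximises an approximate evidence; the ascent safeguard
  guarantees a monotone trace but can stop at ridges of the surrogate where
  unsafeguarded EM would wander (slightly downhill) to a different solution.
* The per-point Mahalanobis reference needs either many reference trials or
  shrinkage; distances under heavy shrinkage are not comparable across
  different shrinkage intensities.
* The Wiener decoder is linear; nonlinear readouts (e.g. of the phase ramp)
  cap its $R^2$ below the information-theoretic ceiling for every feature
  set.
* The plain-text session container favours portability over speed; very long
  recordings would warrant a binary store.
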