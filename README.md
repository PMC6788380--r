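# gaitdyn

Low-dimensional latent dynamics and kinematic decoding for motor-cortex
population activity during locomotion.

Populations of motor-cortex neurons recorded during walking fire in
coordinated, gait-locked patterns that occupy far fewer dimensions than the
number of recorded units. `gaitdyn` is for researchers who have simultaneous
spike trains (tens of units, 10 ms count bins) and 100 Hz hind-limb marker
kinematics segmented into single gait cycles, and who want to ask: *do a few
latent dimensions preserve the kinematic and gait-phase information carried by
the full population?* The package provides the full analysis chain — latent
state-space modelling, four competing neural feature sets, lagged linear
decoding, gait-cycle trajectory geometry, spectral smoothness comparison, and
a ground-truth synthetic session generator so every stage is testable without
animal data.

## The model

The core is a Poisson linear dynamical system (PLDS). Latents `x_t` (dimension
`p`, one step per 10 ms bin) follow a linear-Gaussian Markov chain and spike
counts `y_t` (one entry per unit) are conditionally Poisson through an
exponential link:

```
x_1 ~ N(x0, Q0),   x_{t+1} = A x_t + w_t,  w_t ~ N(0, Q)
y_t | x_t ~ Poisson( exp(C x_t + d) )        per 10 ms bin
```

Parameters `(A, Q, C, d, x0, Q0)` are learned by EM. The E-step computes a
Laplace approximation to the posterior over each trial's latent trajectory:
Newton's method on the log joint of the whole sequence, whose block-tridiagonal
Hessian is factorised in `O(T p^3)`; the posterior mode is the latent estimate,
and blocks of the inverse Hessian supply the covariances and adjacent-bin
cross-covariances that the M-step needs. For decoding, trials are scored with a
lag-10 Wiener filter

```
y[t] = b0 + sum_{n=0..9} A_n X[t-n]        (least squares, 10 ms steps)
```

driven by one of four feature sets: the z-scored full-population firing rates
(`fp`), PLDS posterior-mean latents (`plds`), PCA components (`pca`), or a
greedily selected neuron subset (`pss`). Accuracy is the per-trial coefficient
of determination `R^2 = 1 - SS_res / SS_tot` under 10-fold cross-validation
with all feature stages fitted on training folds only. Trajectory geometry is
compared after time-normalizing each cycle to a 100-point gait-percent grid
(foot-strike = 0/100 %, toe-off = 60 %) via per-grid-point Mahalanobis distance
to a reference condition; decoder smoothness via Thomson multitaper spectra.

## Worked example

```r
library(gaitdyn)

cfg <- gait_config(n_units = 30, latent_dim = 4, n_trials_per_condition = 15,
                   conditions = data.frame(task = "TRM", speed = c(2.4, 4.0, 6.4)),
                   seed = 1)
session <- generate_session(cfg)
session
#> Synthetic locomotor session: 30 units, 2732 bins (10 ms), 45 trials
#>   trials per task: TRM=45
#>   kinematics available: 37/45 trials

cv_fp   <- cv_decode(session, "fp",   folds = 10, seed = 1)
cv_plds <- cv_decode(session, "plds", dims = 4, folds = 10, seed = 1,
                     plds_control = list(max_iter = 15, tol = 1e-4))

fp   <- aggregate(r_squared ~ variable, cv_fp,   mean)
plds <- aggregate(r_squared ~ variable, cv_plds, mean)
tab <- merge(fp, plds, by = "variable", suffixes = c("_fp", "_plds"))
head(tab[order(-tab$r_squared_plds), ], 6)
#>         variable r_squared_fp r_squared_plds
#> 13        meta_h        0.738          0.889
#> 19         toe_h        0.745          0.888
#> 20         toe_v        0.730          0.885
#> 1        ankle_h        0.711          0.883
#> 14        meta_v        0.738          0.882
#> 12 leg_extension        0.694          0.877
```

The table lists cross-validated mean `R^2` per decoded variable (horizontal/
vertical marker positions relative to the iliac crest, sine/cosine of the
joint angles, leg extension in meters, gait-cycle phase in percent). Here a
4-dimensional PLDS feature set decodes toe and metatarsal trajectories better
than all 30 z-scored rate channels (0.88-0.89 vs 0.71-0.75) because the
smoothed latents suppress Poisson count noise that the 100 ms rate windows
pass through — the qualitative behaviour the package is built to measure.

Other entry points: `dim_sweep()` (R^2 and held-out likelihood vs latent
dimensionality, with the <0.001-increment plateau rule), `normalize_gait_cycle()` /
`mahalanobis_profile()` / `speed_separation()` (trajectory geometry),
`multitaper_psd()` / `smoothness_compare()` (output smoothness),
`compare_decoders()` (per-variable Wilcoxon signed-rank across sessions with
Benjamini-Hochberg correction at FDR 10%), `write_session()` / `load_session()`
(plain-text session container), `run_pipeline()` and the `inst/cli/gaitdyn.R`
command-line driver (`simulate`, `decode`, `sweep`, `trajectories`, `run-all`).

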