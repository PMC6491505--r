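---
title: "Simulating precision-weighted vibrotactile discrimination and its prefrontal network models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating precision-weighted vibrotactile discrimination and its prefrontal network models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`precistim` emulates, end to end, a paired vibrotactile flutter
discrimination study and the model-based analysis of its imaging data. All
data are synthetic and carry known ground truth, so every stage can be
validated by recovery rather than by comparison with irreproducible human
measurements. This vignette is the package's account of the science: the
models it implements, the assumptions they make, the parameters that
matter, and what the synthetic data can and cannot show.

```{r setup}
library(precistim)
```

## Stimuli: flutter with per-cycle wavelength jitter

A stimulus is a 512 ms sinusoid in the flutter range (10-50 Hz; the task's
base frequency is 34 Hz). "Noisy" stimuli degrade the temporal structure by
adding independent zero-mean Gaussian jitter to the wavelength of each
cycle, with SD equal to `noise_fraction` of the base cycle length. At the
standard level of 0.08, a 40 Hz stimulus has cycles of mean length 25 ms
and SD 2 ms:

```{r stimulus}
spec <- stimulus_spec(40, duration = 2000, noise_fraction = 0.08, seed = 1)
w <- synthesize_noisy(spec)
unlist(cycle_stats(w))
```

Design choices worth stating:

* Jitter lives in the **period (wavelength) domain**. The expected cycle
  period equals the base period, so the mean *instantaneous frequency*
  slightly exceeds the nominal frequency (Jensen's inequality). This is a
  property of wavelength jitter and is documented rather than "corrected".
* The SD convention is **population** (divide by N): the quantity of
  interest is the cycle-length variability *within* one stimulus.
* Non-positive drawn periods are rejected and redrawn. At 8% jitter this
  has probability ~1e-36 per cycle; the rule only makes the generator
  total.
* Each cycle is a full sine period starting at zero phase, so the waveform
  is continuous at every cycle boundary. The final partial cycle is
  truncated at exactly the stimulus duration and excluded from the stored
  period list (`final_cycle = "complete"` finishes it instead, since the
  original truncation behaviour is not knowable). The sample rate (default
  8 kHz) is likewise configurable; amplitude is normalized to 1 because
  mechanical amplitude plays no computational role.

## Titration: interleaved transformed up-down staircases

The staircase steps the base-comparison frequency difference down by 10%
after an accumulated tally of correct responses (6 on the easy track, 2 on
the hard track) and up by 10% after every error. Three readings of the
procedure required a decision:

* the tally **persists through errors** and resets only on a step-down
  (the "non-consecutive" rule);
* a step-up does **not** reset the tally;
* track selection per trial is uniform 50/50.

Balancing expected up- and down-step rates, `1 - p = p/m`, gives the
asymptotic proportion correct `p = m/(m+1)`: 2/3 for the hard track and
6/7 ~ 0.857 for the easy track. The conventional "~90%" description of a
6-up rule is therefore an optimistic rounding; the package asserts the
analytic value. Simulated observers are cumulative-Gaussian in the
frequency difference (`pnorm(delta / (sqrt(2) * sd))`, the accuracy of a
two-interval comparison with independent encoding noise of SD `sd` per
percept).

```{r staircase}
tit <- run_titration(make_gaussian_observer(1.5), n_trials = 2000, seed = 1)
tit
equilibrium_accuracy(c(2, 6))
```

Converged deltas are estimated as the geometric mean of each track's delta
over its final third (the estimator is otherwise unconstrained; the
geometric mean matches the multiplicative step structure), and the medium
difficulty is the geometric mean of the two converged deltas, targeting
~75% accuracy.

## The observer: percepts with known precision

Each stimulus is encoded as a Gaussian percept. Its SD combines internal
noise `sigma_p` with an external component from stimulus roughness: a
jittered stimulus conveys its frequency through the mean of its ~17-20
cycle periods, so the roughness-induced frequency SD is
`noise_fraction * f / sqrt(n_cycles)` (about 0.65 Hz at 34 Hz and 8%
jitter), scaled by a free coupling `kappa`. The observer knows its own
uncertainty - `known_sd` - but not the jitter realization.

Two decision rules operate on a percept pair:

* **faster-slower**: respond on the sign of the difference. No criterion,
  no precision.
* **same-different**: respond "different" when
  `|v2 - v1| / sqrt(sd1^2 + sd2^2) > c` (precision weighting), or, for the
  control observer, when `|v2 - v1| > c` in Hz (raw difference).

On same-noisy trials the two stimuli reuse the identical jitter sequence,
so the roughness component of the two percepts is one shared draw that
cancels in the difference, while `known_sd` still includes it. This is the
mechanism of the behavioral crossover: noise inflates the denominator
without inflating the numerator on same trials (fewer false "different"
responses) and dilutes the signal on different trials (fewer hits). A
raw-difference observer, lacking the denominator, shows no same-trial
noise benefit:

```{r observer}
sched <- generate_schedule(2000, schedule_config(delta = 2), seed = 1)
acc <- cell_accuracies(simulate_session(sched, observer_params(), seed = 2))
round(acc$cell_accuracy, 3)
round(acc$interaction, 3)
```

Defaults `sigma_p = 1` Hz, `kappa = 1`, `c = 1.5` place same-different
accuracy in the 60-90% band the titration targets; none of the three is
empirically known, and the qualitative signatures hold over a wide range.
Perceptual SD is frequency-independent by default (the 10-50 Hz range is
narrow); Weber-like scaling can be emulated by passing a different
`perceptual_sd`. The criterion is fixed within a context; reaction times
are intentionally not modeled (the trial table carries an `rt`
placeholder). Sensitivity is summarized by `d' = z(hit) - z(false alarm)`
with the 1/(2N) edge correction. At matched encoding parameters the
faster-slower task yields the higher d' - the direction, not the
magnitude, of the corresponding human result, which is not a target here.

## The network models: seven motifs over a common base

Four regions - IPL, rPFC, DLPFC, SFG - with one neural state each. Every
motif shares a base: stimulus drive into IPL; IPL to rPFC modulated on
regular trials; IPL to DLPFC modulated on different trials; a backward
DLPFC-to-IPL connection. The motifs differ in how activity reaches SFG:
serially through both intermediates (Diamond), in parallel directly from
IPL with both modulations (Fork), hierarchically with one modulation at
the top (Legs 1: regular; Legs 2: different), or nonlinearly, with rPFC
activity gating DLPFC-to-SFG (Stork 1), DLPFC activity gating rPFC-to-SFG
(Stork 2), or both gates at once (Stork 3). Edge lists live in
`inst/extdata/dcm_model_space.json`; an alternative reading of a motif is
a configuration edit, not a code change. One caption-level ambiguity was
resolved as follows: Fork's direct IPL-to-SFG route replaces, rather than
complements, the rPFC/DLPFC-to-SFG edges, keeping the space non-redundant
(parallel vs serial, not both).

Neural dynamics follow the standard one-state nonlinear form

    dx/dt = (A + sum_j u_j B_j + sum_k x_k D_k) x + C u

with self-connections `-0.5 * exp(theta_self)` (negativity enforced by
parameterization). Hemodynamics are the balloon model (signal decay 0.64/s,
feedback 0.32/s, transit time 2 s, stiffness 0.32, resting extraction 0.4,
resting volume 0.04; BOLD constants k1 = 7 E0, k2 = 2, k3 = 2 E0 - 0.2).
Integration is fixed-step RK4 with inputs zero-order-held on the grid;
halving the step changes sampled BOLD at fourth order, and the test suite
checks agreement with a ten-fold finer grid. States are guarded (volume,
deoxyhemoglobin positivity; neural blow-up) and violations surface as
errors naming the failure time.

## Synthetic group data as a designed experiment

`generate_group()` draws per-subject connection strengths as group means
plus Gaussian deviations (SD 0.1), builds per-subject schedules and input
streams, integrates BOLD, and adds white observation noise scaled per
region to a target SNR (signal SD / noise SD; AR(1) noise is available in
`simulate_bold()` but the group default is white). Hemodynamic constants
are shared across subjects by default. Everything is hierarchically
seeded - master seed, per-subject seeds, per-stimulus jitter seeds - so a
single subject regenerates bit-identically, and same-noisy stimulus reuse
is expressed as shared per-stimulus seeds.

The group means are not arbitrary: they implement the factorial logic of
the task as a *designed, identifiable* experiment. The forward routes have
weak baselines (0.2/s) and strong condition modulations (0.8/s), so rPFC
activity is largely specific to regular trials and DLPFC activity to
different trials; the SFG afferents (0.15/s) and gates (1.0 per unit
state) then give the SFG series three components of comparable variance -
two condition main effects and an activity-dependent interaction. A power
calculation drove these choices: on noise-free data from Stork 3 every
rival motif must leave a residual of at least ~15% of the SFG signal SD,
so that at SNR 1 the per-subject evidence gap is several nats. Two
structural facts shaped the design. First, with one state per region the
two gates of Stork 3 enter the SFG equation through the *same* product
`x_rPFC * x_DLPFC`; only their sum is identified, and motif discrimination
rests on the product term plus the two linear afferents being separately
resolvable. Second, SFG is a sink in every motif, so gate strength cannot
destabilize the system.

Default session structure is one continuous run whose length fixes the
trial count (~26 trials in 360 s at the mean 9 s ITI); multi-session
designs are a configuration choice. Trial counts per session in the
original study are not public; the defaults are documented assumptions.

## Inversion: MAP with a Laplace evidence approximation

`fit_model()` maximizes the Gaussian log-joint of a motif's RK4
predictions by Levenberg-damped Gauss-Newton with a forward-difference
Jacobian, interleaving closed-form EM updates of per-region noise
precision, and reports the Laplace free energy

    F = accuracy - complexity
      = log p(y | mu_post) - 1/2 [ (mu_post - mu_0)' P_0 (mu_post - mu_0)
                                   + ln det(Sigma_0) - ln det(Sigma_p) ]

which is exact for linear-Gaussian models (verified against the conjugate
evidence to 1e-3 nats). This is a deliberately defined, reproducible
approximation of the variational objective used by standard DCM software;
a full variational scheme would be a compatible extension. Convergence is
`|dF| < 1e-4` on three successive iterations, capped at 24 iterations;
non-convergence flags the estimate instead of raising.

Priors are zero-mean Gaussians: variance 0.25 on A off-diagonals, B, C
*and* D; 0.0625 on self-connection log-scales and per-region log transit
time (all other hemodynamic constants fixed). The D prior deserves a note,
because a tighter D prior (e.g. variance 0.0625) looks attractive on
weak-identifiability grounds but has a structural consequence: the
quadratic prior cost of a gate at its generating scale then *exceeds* its
likelihood gain at SNR 1, the MAP solution sets every gate to zero for
every subject, and the nonlinear motifs become likelihood-equivalent to
their bilinear skeletons - the prior, not the data, decides the model
comparison. Matching the D prior to the B prior keeps that decision with
the data; `prior_spec(var_d = ...)` restores any tighter choice.

The fit starts deterministically at the prior mean. Multiple seeded
restarts (`fit_control(n_starts = k)`) are available but default to one:
across the recovery studies the damped scheme from the prior mean reaches
the same optimum as jittered restarts, which triple cost without changing
the winner. Group generation and inversion run on a 20 ms input grid (the
schedule-level default is 10 ms): at these time constants the RK4 error at
20 ms is orders of magnitude below observation noise, and the oracle test
pins the difference below 1e-6 BOLD units.

## Model selection and recovery

`rfx_bms()` treats model identity as a random effect: variational updates
of a Dirichlet over model frequencies (responsibilities proportional to
`exp(F + digamma(alpha_k) - digamma(sum alpha))`), with exceedance
probabilities - the probability that a model is the most frequent in the
population - estimated from 1e6 Dirichlet draws (sampling, because the
closed form is impractical at K = 7; the K = 2 case is checked against
Beta quadrature). When every subject favours one model by many nats the
procedure reduces to the fixed-effects ranking.

`model_recovery()` closes the loop: generate a group from one motif, fit
all seven to every subject, select by exceedance, and compare posterior
means and 90% credible intervals against the generating parameters. At the
reference conditions (8 subjects, 360 s sessions, SNR 1) the double
nonlinear motif is recovered decisively and A/B coverage exceeds the 80%
calibration bar; gating parameters are reported but not gated, since the
shared-product degeneracy and shrinkage make their marginal intervals
conservative. Exceedance magnitudes themselves are seed-dependent and are
treated ordinally (winner identity), not numerically.

## Problem sizes and limitations

Reference problem sizes, chosen as the package's own desk-scale defaults:
stimulus statistics over ~10,500 cycles; staircase equilibria over 5,000
trials with the first half discarded; behavioral contrasts over 4,000-6,000
trials; recovery with 8 subjects, 360 s sessions, TR 2 s, SNR 1.

What the synthetic data do not emulate: scanner drift and physiological
noise (observation noise is white or AR(1)); voxel space, smoothing and
cluster inference (the package works at the extracted-ROI level by
construction); reaction times; learning, lapses, and criterion drift in
the observer; multi-state or two-state neural models. Passing tests
therefore demonstrate internal validity - the chain of methods recovers
what it assumes - not that the assumed forms describe human data. The
human effect magnitudes from the original behavioral tables are
deliberately out of scope; only their directions are asserted, and only
for the simulated observer.
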