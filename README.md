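# precistim

Simulation and model-based analysis of paired vibrotactile flutter
discrimination, for researchers studying how perceptual *precision* (the
inverse variance of a percept) enters decision making and how prefrontal
regions might exchange that information.

The package emulates a complete study with synthetic data and known ground
truth:

1. **Stimuli** — 512 ms flutter sinusoids (base 34 Hz) whose per-cycle
   wavelength can be jittered by Gaussian noise with SD equal to 8% of the
   base cycle length, plus cycle statistics (a 40 Hz noisy stimulus has
   cycles of mean 25 ms, SD 2 ms).
2. **Titration** — interleaved transformed up-down staircases (step up on
   every error, step down after a tally of m = 6 or m = 2 correct
   responses, 10% multiplicative steps). The drift-balance equilibrium
   accuracy is m/(m+1): 6/7 for the easy and 2/3 for the hard track, with
   the medium difficulty the geometric mean of the converged differences.
3. **Observer** — each stimulus becomes a Gaussian percept with known SD
   (internal noise plus stimulus roughness). Faster-slower answers on the
   sign of the difference; same-different answers on the precision-weighted
   statistic |v2 − v1| / √(sd1² + sd2²) > c. Verbatim jitter reuse on
   same-noisy trials makes the shared roughness cancel in the numerator but
   not the denominator, producing the noise × difference accuracy
   crossover; d′ summaries included.
4. **Network models** — a four-region (IPL, rPFC, DLPFC, SFG) dynamic
   causal model space of seven motifs (Diamond, Fork, Legs 1/2 bilinear;
   Stork 1/2/3 nonlinear, where one region's activity gates a connection
   between two others):
   dx/dt = (A + Σⱼ uⱼ B⁽ʲ⁾ + Σₖ xₖ D⁽ᵏ⁾) x + C u,
   coupled to balloon hemodynamics and integrated by fixed-step RK4
   (compiled core).
5. **Inversion and selection** — MAP estimation (damped Gauss-Newton + EM
   noise updates) with a Laplace free energy F = accuracy − complexity as
   the evidence approximation, and random-effects Bayesian model selection
   (Dirichlet over model frequencies, exceedance probabilities by
   Monte-Carlo).
6. **Recovery** — generate a synthetic group from one motif, invert all
   seven per subject, and check that BMS returns the generating motif and
   that credible intervals cover the generating parameters.

## Worked example

```r
library(precistim)

# noisy stimulus statistics
w <- synthesize_noisy(stimulus_spec(40, duration = 5000,
                                    noise_fraction = 0.08, seed = 1))
unlist(cycle_stats(w))
#>  mean_period    sd_period     n_cycles     sd_ratio
#>  25.0752664    1.8572508  199.0000000    0.0742900

# staircase titration against a simulated observer
tit <- run_titration(make_gaussian_observer(1.5), n_trials = 2000, seed = 1)
tit
#> <titration> easy 2.434 Hz (acc 0.843), hard 0.825 Hz (acc 0.639), medium 1.417 Hz

# behavioral crossover of the precision-weighted observer
sched <- generate_schedule(2000, schedule_config(delta = 2), seed = 1)
acc <- cell_accuracies(simulate_session(sched, observer_params(), seed = 2))
round(acc$cell_accuracy, 3)
#>      same_regular different_regular        same_noisy   different_noisy
#>             0.878             0.462             0.910             0.392

# group-level model recovery (~3 min)
space <- build_model_space()
rec <- model_recovery(space, "Stork3",
                      group_config(n_subjects = 8, session_length = 360,
                                   SNR = 1), seed = 11)
rec
#> <recovery_result> generated from Stork3, winner Stork3 (recovered)
#> exceedance probabilities:
#> Diamond    Fork   Legs1   Legs2  Stork1  Stork2  Stork3
#>  0.0042  0.0035  0.0047  0.0045  0.0088  0.0041  0.9703
#> A/B 90% CI coverage: 1.00; D coverage: 0.94
```

Reading the numbers: the noisy 40 Hz stimulus shows the 25 ms / 2 ms cycle
statistics within sampling error at ~200 cycles (the acceptance script
verifies them over 10,000); the hard staircase sits at its 2/3 equilibrium and the
easy one near 6/7; same-trial accuracy is *higher* under stimulus noise
while different-trial accuracy is lower (the precision-weighting
signature); and random-effects model selection identifies the double
nonlinear motif that generated the group data, with generating A/B
parameters covered by their 90% posterior intervals.

`run_pipeline(pipeline_config(out_dir = "out"))` chains all stages
(titration → schedules → behavior → group BOLD → inversion → BMS) and
writes CSV/TSV/JSON outputs with seeds and a config hash.

The methods vignette
(`vignettes/precision-weighted-discrimination.Rmd`) documents the models,
assumptions, priors, numerical choices, and limitations.

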