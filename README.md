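# csdscale

Scaling laws of critical slowing down at the transition to neuronal spiking.

## What this package is for

When a neuron is driven slowly towards its spiking threshold by an
increasing current, its subthreshold state approaches a bifurcation: at a
critical current *I*<sub>c</sub> quiescence ends and repetitive firing
begins.  Near the bifurcation the membrane recovers more slowly from small
perturbations, and its fluctuations grow — *critical slowing down*.  The
two generic transition mechanisms differ quantitatively in how the recovery
rate λ and the voltage variance *v* scale with the distance
ΔI = *I*<sub>c</sub> − *I*:

| bifurcation | λ ~ ΔI<sup>θ</sup> | v ~ ΔI<sup>τ</sup> |
|---|---|---|
| saddle-node (fold) | θ = 0.5 | τ = −0.5 |
| subcritical Hopf | θ = 1 | τ = −1 |

so fitted exponents identify the governing bifurcation, and a known θ turns
the scaling law λ = a (V<sub>c</sub> − V)<sup>θ</sup> into a predictor of
the critical voltage from a truncated window of observation.

`csdscale` is aimed at researchers studying early-warning signals and
neuronal excitability.  It provides:

* stochastic simulators of the saddle-node and subcritical Hopf normal
  forms under slow parameter drift with impulsive perturbations
  (`simulate_saddle_node()`, `simulate_hopf()`), integrated in compiled
  code and bit-reproducible under a seed;
* an emulator of a patch-clamp stimulation protocol (3 pA / 4.01 s current
  steps, 50 pA / 5 ms pulses, 25 kHz sampling, onset-terminated) producing
  voltage/current recordings in physical units
  (`emulate_patch_recording()`, `simulate_trial_batch()`), including a
  no-bifurcation control mode;
* per-perturbation markers — exponential recovery rate, pre-pulse variance
  and lag-normalized autocorrelation (`compute_markers()`);
* power-law exponent estimation in log–log space with a minimal-ΔI cutoff
  sweep and R² ≥ 0.1 acceptance (`fit_power_law()`, `sweep_exponents()`),
  plus nearest-template bifurcation classification
  (`classify_bifurcation()`);
* critical-voltage prediction with a fixed exponent and across-trial
  evaluation (`predict_critical_voltage()`, `correlate_predictions()`);
* file round-tripping (tidy CSV/TSV + JSON sidecars) and a command-line
  pipeline (`run_simulate()`, `run_analyze()`, `run_predict()`; thin
  script in `inst/cli/csd`).

## Worked example

Simulate the stochastic saddle-node normal form with slow drift and a
pulse train, estimate the markers, and fit the scaling exponents:

```r
library(csdscale)

tr <- simulate_saddle_node(sde_config(seed = 3))
tr
#> <csd_trajectory: saddle_node normal form>
#>   266667 samples, dt = 0.006, span [0, 1600]
#>   y: 1.6 -> 4e-06 (t_c = 1600), 26 pulses every 60

m  <- compute_markers(tr)
th <- sweep_exponents(m, "lambda")
ta <- sweep_exponents(m, "variance")
th
#> <exponent_estimate: theta (lambda) = 0.499 +/- 0.011 over 8/8 cutoffs>
ta
#> <exponent_estimate: tau (variance) = -0.569 +/- 0.055 over 7/8 cutoffs>
classify_bifurcation(th, ta)
#> <bifurcation_class: saddle_node (theta = 0.499, tau = -0.569, distance = 0.069)>
```

The recovery-rate exponent 0.499 ± 0.011 (mean ± sd over the cutoff sweep)
and the variance exponent −0.57 sit at the ±0.5 pair expected for a fold,
so the trial is classified as saddle-node; `distance` is the Euclidean
distance to the nearest exponent template.

Tipping-point prediction across an emulated batch of 25 recording trials
with cell-to-cell variability:

```r
recs <- simulate_trial_batch(seed = 100)
ms   <- lapply(recs, compute_markers)
p5   <- lapply(ms, predict_critical_voltage, theta = 0.5)  # fold exponent
p1   <- lapply(ms, predict_critical_voltage, theta = 1.0)  # Hopf exponent
correlate_predictions(p5)
#> <prediction_correlation: r = 0.598, p = 0.00159 (n = 25, theta = 0.5)>
correlate_predictions(p1)
#> <prediction_correlation: r = 0.423, p = 0.0352 (n = 25, theta = 1)>
```

Predicted and measured distances to threshold correlate markedly better
when the prediction uses the saddle-node exponent than the Hopf one —
knowing the governing bifurcation improves tipping-point estimation.

The same pipeline is scriptable from a shell:

```sh
inst/cli/csd simulate --config cfg.json --out runs/sim --seed 7
inst/cli/csd analyze  --config cfg.json --input runs/sim/trajectory --out runs/ana
```

See `vignettes/critical-slowing-scaling.Rmd` for the model systems, window
layout, the integration-step calibration for the Hopf recovery window, the
emulator's unit maps, and design rationale.

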