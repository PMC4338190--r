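---
title: "Scaling laws of critical slowing down near the spiking threshold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaling laws of critical slowing down near the spiking threshold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csdscale)
```

## The problem

A neuron driven by a slowly increasing current sits near a bifurcation: at a
critical current $I_c$ its quiescent (subthreshold) state disappears and
repetitive spiking begins.  Dynamical systems theory identifies two generic
routes — a saddle-node (fold) bifurcation, where a stable and an unstable
equilibrium collide, and a subcritical Hopf bifurcation, where a focus loses
stability as a complex eigenvalue pair crosses the imaginary axis.  Close to
either bifurcation, recovery from small perturbations slows down (*critical
slowing down*), fluctuations grow, and autocorrelation rises.  Crucially, the
two mechanisms differ *quantitatively*: with $\Delta I = I_c - I$ the distance
to the bifurcation,

$$\lambda \sim \Delta I^{\,\theta}, \qquad v \sim \Delta I^{\,\tau},$$

with $(\theta, \tau) = (0.5, -0.5)$ for a saddle-node and $(1, -1)$ for a
Hopf bifurcation.  Measuring these exponents therefore identifies the
governing bifurcation, and — once $\theta$ is known — the scaling law can be
extrapolated to *predict* the tipping point from a truncated observation
window.

`csdscale` implements this programme end to end: stochastic normal-form
simulators, an emulator of the experimental stimulation protocol,
per-perturbation markers ($\lambda$, variance, lag-normalized
autocorrelation), log–log exponent fits with a minimal-distance sweep,
bifurcation classification, and critical-voltage prediction.

## Model systems

The saddle-node system is
$$dV = (-y + \rho V^2)\,dt + \sigma_1\,dW, \qquad y(t) = y_0 - \epsilon t,$$
with stable branch $V^-(y) = -\sqrt{y/\rho}$ for $y > 0$ and linearized
recovery rate $\lambda(y) = 2\sqrt{\rho y}$.  The two-component subcritical
Hopf system is
$$dV_1 = \big(yV_1 - V_2 + V_1 r^2\big)dt + \sigma_1 dW_1,\qquad
  dV_2 = \big(V_1 + yV_2 + V_2 r^2\big)dt + \sigma_2 dW_2,$$
with $r^2 = V_1^2+V_2^2$, stable at the origin for $y<0$ with recovery rate
$|y|$ and rotation frequency 1.  In both systems the control parameter
drifts towards the bifurcation at $y_c = 0$, reaching it at
$t_c = |y_0|/\epsilon$; brief additive kicks every `pulse_spacing` time
units play the role of the experimental perturbation pulses.  (Both drifts
are written so that $y$ moves *towards* $y_c$; the crossing-time identity
$t_c = |y_0|/\epsilon$ holds exactly for both.)

Default parameters are the standard illustration values: saddle-node
$y_0 = 1.6$, $V_0 = -4$, $\epsilon = 10^{-3}$, $\rho = 0.1$,
$\sigma_1 = 10^{-3}$, kicks of $0.1$ every 60 time units ($t_c = 1600$);
Hopf $y_0 = -2$, $\sigma_{1,2} = 10^{-3}$, kicks of $5\times10^{-3}$ on
both components ($t_c = 2000$).  Integration is explicit Euler–Maruyama at
fixed step; the analyses need only first-order pathwise accuracy, and the
stationary-variance bias of the scheme at the default steps is below one
percent.  Noise is drawn from R's RNG, so a configuration plus a seed
reproduces a path bit for bit.

Two noise-term readings deserve mention.  The printed form of the Hopf
system can be read as feeding the *sum* of both Wiener increments to each
component; we use one independent increment per component, which leaves
every stationary statistic of interest unchanged.  Pulse times are read as
a spacing ("every 60 time units"), not a single onset, matching the pulse
trains visible in the trajectory figures.

## Window layout and the integration step

Markers are computed per perturbation: an exponential
$V(t) = a e^{-\lambda t} + b$ is fitted to the post-pulse window
(mean-subtracted, scale-free start values, $\lambda$ bounded to half the
sampling rate), and variance plus lag-normalized autocorrelation
$ACF(s) = ACF^*(s)/ACF^*(1)$ are computed on the unperturbed pre-pulse
window.  Model-unit analyses use 5000-sample pre-windows and recovery
windows of 5000 samples (saddle-node) or 500 samples (Hopf).

For the saddle-node system `dt = 0.006` makes each 60-unit inter-pulse
interval hold exactly 10000 samples, tiling it into the 5000-sample
statistics window and the 5000-sample recovery window.

The Hopf step needs more care, and is the one place where the window
layout interacts with the physics.  The observable $V_1$ spirals into the
origin: after a kick it follows $\propto e^{y t}\cos(t + \varphi)$.  An
exponential fitted to a *rotating* recovery only measures something
proportional to $|y|$ while the window stays well inside the first quarter
cycle; as the window grows past it, the fitted rate saturates and the
fitted exponent of $\lambda$ versus $|y|$ collapses (we measured the
deterministic log–log slope falling from $\approx 1$ to $\approx 0.4$ as
the window grows from a quarter to half a rotation period).  Since the
500-sample window length is fixed by the procedure, the step size sets the
window duration.  We calibrated `dt` against the analytically known unit
exponent of the normal form, over four independent 20-seed replications of
the full pipeline, and froze `dt = 0.0032`: the recovery window then spans
1.6 time units, almost exactly a quarter of the rotation period $2\pi$,
and the pipeline recovers $\theta \approx 1$ without bias.  A consequence
worth knowing: the *absolute* fitted rate on $V_1$ exceeds $|y|$ by a
factor $\approx 1.6$–$1.8$ (the rotation contributes apparent decay); the
scaling analysis is immune because only the exponent, not the prefactor,
is interpreted.  The true decay rate is recovered exactly (to the 2%
tolerance of the oracle tests) by fitting the envelope radius
$\sqrt{V_1^2+V_2^2}$ instead.

## Exponent estimation and classification

For each marker, $\log x$ is regressed on $\log \Delta I$ by ordinary
least squares ($\Delta I \le 0$, missing $\lambda$, and non-positive
marker values excluded); fits with $R^2 < 0.1$ are rejected.  Because the
fitted exponent should not depend on the fit interval, the fit is repeated
over a grid of minimal distances $\Delta I_{\min}$ (default: 8
log-spaced cutoffs between the 5th and 60th percentile of the observed
positive $\Delta I$; the source procedure sweeps cutoffs but does not
state its grid, so the grid is configurable and recorded in outputs).
The exponent estimate is the mean over accepted fits with its spread.

Classification is nearest-template in $(\theta, \tau)$ space against
$(0.5, -0.5)$ and $(1, -1)$, returning `indeterminate` when both
templates are farther than 0.35 (configurable), when they are equidistant,
or when $\theta$ and $\tau$ individually favour different templates.  The
autocorrelation exponent $\kappa$ is reported but never classified: it
depends on the lag at which the autocorrelation is evaluated.

## The patch-protocol emulator

No recordings are distributed with the original experiments, so the
package ships an emulator that binds the normal-form dynamics to the
stimulation protocol: a step current rising 3 pA every 4.01 s, 50 pA /
5 ms perturbation pulses at 1800 ms and 3805 ms within each step, 25 kHz
voltage and 2.5 kHz current sampling, and termination at the first spike.
The staircase maps affinely onto the control parameter (3 pA per step
$\leftrightarrow$ a fixed $\Delta y$), so $\Delta I \propto |y|$ exactly
and the exponents are preserved.

The voltage composition is the emulator's one substantive modelling
choice.  The recorded trace is
$$V(t) = V_\mathrm{rest} + R_\mathrm{in}\,(I(t) - I_0) + g\,V_d(t),$$
an *ohmic* mean depolarization plus the detrended normal-form fluctuations.
The ohmic term matters for the prediction study: on the bare normal form
the recovery rate is exactly linear in the stable-branch voltage
($\lambda = 2\rho\,(V_c - V^-)$), whereas a real membrane's mean potential
tracks injected current through its input resistance over the subthreshold
range, making $\lambda \propto \Delta I^{1/2} \propto (V_c - V)^{1/2}$ in
voltage — the geometry in which the square-root prediction fit is correct.
An optional `parabolic_range` continues the fold's parabolic I–V relation
linearly far below threshold (a passive-conductance far field, which
confines the square-root law to the last decade of $\Delta I$); the default
is the pure normal form.  When the model state escapes its basin the
emulator writes a stereotyped spike sample and truncates, because normal
forms diverge rather than produce action potentials.

Default unit maps: 100 pA per $y$-unit, 100 time units per second (so
recovery rates span roughly 10–45 s$^{-1}$ over a ramp, with time
constants of 20–100 ms), 10 mV per state unit for the fluctuations,
$V_\mathrm{rest} = -70$ mV, $R_\mathrm{in} = 0.55$ mV/pA (550 M$\Omega$),
$y_0 = 0.5$ (a 50 pA climb to threshold), $\sigma_1 = 1.5\times10^{-3}$.
These were chosen once to give subthreshold statistics of realistic
magnitude while keeping each 192 ms recovery window many fluctuation
correlation times long, which is what makes single-pulse $\lambda$
estimates stable.

## The prediction study and its trial heterogeneity

`predict_critical_voltage()` fits $\lambda = a\,(V_{cp} - V)^\theta$ with
$\theta$ fixed and $(a, V_{cp})$ free, after withholding the five last
pre-onset samples, initialized scale-free and with $V_{cp}$ constrained
above every fitted voltage (and within 50 mV of the last one).  Across
trials, the predicted distance $\Delta V_p = V_{cp} - V_\mathrm{last}$ is
regressed on the measured distance $\Delta V_m = V_{cm} - V_\mathrm{last}$.

`simulate_trial_batch()` encodes the across-cell variability of the
emulated study: rheobase ($y_0$, $\pm50\%$), input resistance
($\pm25\%$), and intrinsic noise ($\pm30\%$), each uniform and
per-trial-seeded.  The proportions are deliberate.  $\Delta V_m$ is a
*difference*, so common shifts of threshold cancel; its genuine
across-trial spread comes from the voltage spacing of perturbation pulses
(set by input resistance) and from where each trial's ramp stops.  A
misspecified linear ($\theta = 1$) fit, by contrast, is an OLS line whose
threshold overshoot grows with the voltage span of the fitted window
($\approx$ one third of it on square-root data); wide rheobase spread
varies that span independently of $\Delta V_m$ and thereby decorrelates
the misspecified prediction, while the correctly specified square-root fit
is anchored by the near-threshold curvature and tracks.  With narrow
rheobase spread the two exponents become empirically indistinguishable in
this design — a caveat worth remembering when interpreting such contrasts
on real data.

## What the generator does and does not emulate

The synthetic data carry the features the analyses rely on: normal-form
scaling of recovery, variance and autocorrelation with distance to the
bifurcation; the staircase-plus-pulses stimulation timing; physical units;
cell-to-cell parameter spread; and a no-bifurcation control (`control =
TRUE`, the pharmacological-blockade analogue) in which the staircase ramps
while the dynamics stay fixed, abolishing every slowing-down signature by
construction.  They do *not* contain spike waveforms beyond a stereotyped
onset marker, synaptic bombardment, channel-noise nonstationarity,
electrode artefacts, within-segment drift beyond the protocol's own
staircase, or adaptation.  Passing tests therefore demonstrate that the
estimators recover the constructed truth under realistic geometry and
noise — not that real neurons obey these scaling laws; establishing the
latter requires recordings.

## Numerical choices and degenerate inputs

* Recovery fits never raise on non-convergence; they return
  `converged = FALSE` and the event keeps its variance/autocorrelation so
  series retain full length.  Constant segments are a classed error.
* The lag-1-normalized autocorrelation divides by $ACF^*(1)$; segments
  whose lag-1 autocorrelation is numerically near zero (white-noise
  dominated) raise a classed error instead of amplifying noise.
* Variance uses the population convention (divide by $N$), consistent with
  the autocorrelation normalization; exponents are unaffected by the
  convention.
* Windows are dropped — with a logged count — whenever they would cross
  the onset, the bifurcation crossing, a neighbouring pulse, or another
  window.
* Simulations stop at an escape criterion (past the unstable branch + 1
  for the fold; radius beyond $\max(2\sqrt{-y}, 0.5)$ for the Hopf
  system), since normal forms diverge in finite time after the basin is
  lost.
* Explicit-Euler stability is guarded: steps violating
  $dt < 2/\lambda(y_0)$ are rejected with a diagnostic error rather than
  allowed to explode.
* Classification ties (equidistant templates) are `indeterminate` rather
  than broken arbitrarily.

## Problem sizes

The shipped tests and the acceptance script run 20-seed replications of
the full saddle-node and Hopf pipelines (260k–630k integration steps per
path, 26–33 perturbation events each), 25-trial prediction batches
(about 2 million voltage samples per trial), and an 8-seed control study;
the complete suite takes a few minutes on one core.  All synthetic inputs
are generated in code at run time; nothing is downloaded or bundled.

## Known limitations

* The Hopf recovery rate fitted on $V_1$ is proportional to, not equal
  to, the true decay rate (rotation bias); use the envelope for absolute
  rates.
* Exponent recovery assumes quasi-stationarity between pulses; for much
  faster ramps ($\epsilon$ large relative to $\lambda^2$) the estimates
  lag the true distance.
* The prediction contrast between exponents is a property of the
  across-trial design as much as of the fit; see above.
* The emulator's spike is a marker, not a biophysical waveform; analyses
  that depend on spike shape are out of scope.
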