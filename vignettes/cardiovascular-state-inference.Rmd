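---
title: "Inferring hidden cardiovascular states from bedside pressure signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring hidden cardiovascular states from bedside pressure signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvstate)
```

## The model

`cvstate` implements a lumped-parameter model of the systemic circulation
written entirely in terms of pressures, because arterial and venous
pressures are the two quantities continuously measured in an intensive
care unit. The circulation is a closed serial loop: a one-chamber heart
acting as a pump, a compliant arterial compartment, the peripheral organs
lumped into a single linear resistance $R$, and a compliant venous
compartment. Two ordinary differential equations govern the mean arterial
pressure $P_a$ and mean venous pressure $P_v$:

$$C_a \dot P_a = C_a \, \mathrm{Hr} \, P_p - \frac{P_a - P_v}{R},
\qquad
C_a \dot P_a + C_v \dot P_v - \Delta V_{v0} \dot S_{tot} = I_{ex}.$$

The first equation balances cardiac inflow into the arterial tree (heart
rate $\mathrm{Hr}$ times stroke volume, approximated as $C_a P_p$ with
$P_p$ the pulse pressure) against resistive outflow into the organs. The
second is volume bookkeeping: total stressed volume changes only through
the external rate $I_{ex}$ (bleeding when negative, fluid administration
when positive) and through recruitment of the unstressed venous reservoir
$\Delta V_{v0}$ by the autonomic activation $S_{tot}$.

Autonomic control enters through three sigmoids:

* the **baroreflex** $S_b = 1 - \sigma(k_b (P_a - P_{set}))$, a negative
  feedback around the set point $P_{set}$ with fixed sensitivity
  $k_b = 0.1838\ \mathrm{mmHg^{-1}}$;
* the **total activation** $S_{tot} = \sigma(3.3 (S_b + S - 1))$, which
  folds in a pressure-*independent* drive $S$ (arousal, pain,
  sympathomimetics) and stays in $(0,1)$, roughly the mean of its inputs;
* the **resistance modulation**
  $R_{mod} = \sigma(3.3 (S_{tot} + M_{SVR}))$, where
  $M_{SVR} \in [-1, 1]$ is a non-autonomic vascular tone term
  (vasoplegia, vasopressors).

Heart rate, peripheral resistance and cardiac contractility interpolate
linearly between subject-specific floors and ceilings driven by these
activations; the contractility chain closes the system with
$P_p = \tilde K(S_{tot}) \, P_v / (P_a - P_v)$, where
$\tilde K = K C_{ven}/C_a$ is the *relative contractility* (mmHg) — the
only combination in which contractility and ventricular compliance ever
appear. The venous pressure stands in for the end-diastolic filling
pressure; this approximation degrades when venous pressure greatly
exceeds true diastolic filling (pulmonary hypertension, valve stenosis),
and the package imposes no guard beyond requiring a positive
arterial-venous gradient, since no quantitative regime bound is
available.

Three hidden parameters map onto the canonical shock categories:
$\bar I_{ex} = \tilde I_{ex} / \Delta \tilde V_{v0}$ (per minute,
weight-independent) is negative under ongoing volume loss
(hypovolemic/hemorrhagic shock); $M_{SVR} < 0$ marks maladaptive
vasodilation (distributive shock); a depressed $\tilde K_{max}$ marks
cardiogenic dysfunction.

## Scaled parameterization

Pressure recordings cannot identify volumes and compliances separately.
All estimation therefore happens in scaled units: compliances relative to
the arterial compliance ($\tilde C_v = C_v / C_a$), volumes divided by
the arterial compliance (so $\Delta \tilde V_{v0}$ and $\tilde I_{ex}$
carry units of mmHg and mmHg/s), and resistances as
$\tilde R = \alpha_{RC} C_a R$ (seconds), where $\alpha_{RC}$ absorbs the
unknown calibration of the pulse-contour resistance estimate. Fifteen
parameters are estimated per segment; `as_scaled_params()` converts a
physical simulation subject into this space exactly, which is how the
recovery tests know their ground truth.

## Forward simulation

`simulate_cvs()` integrates the two ODEs with a fixed-step fourth-order
Runge-Kutta scheme, default step 0.1 s. The step resolves the fastest
feedback time constant (about 0.1 s$^{-1}$ near the operating point) with
a wide stability margin; halving it moves terminal pressures by well
under 0.1 mmHg. Volume conservation
($C_a P_a + C_v P_v - \Delta V_{v0} S_{tot}$ tracking
$\int I_{ex}\,dt$) is used as an integrator oracle; with the default
step the residual is a few thousandths of a ml and is dominated by the
initial transient away from the textbook initial state (48/4 mmHg), so
conservation checks in the tests integrate at 0.05 s.

`scenario_library()` provides the artificial patients: `control`,
`hypovolemic` (volume withdrawal ramping from zero to -0.06 ml/s between
minutes 5 and 20), `distributive` ($M_{SVR}$ ramping to -0.5 over the
same period), `combined`, and `fight_or_flight` (the independent drive
$S$ stepping up). The ramp magnitudes are not dictated by the model; they
were chosen once so that a simulated neonate (the printed parameter set:
$P_{set}=50$ mmHg, Hr 100–180 bpm, $\tilde K$ 200–800 mmHg, $R$ 0.8–1.8
mmHg·s/ml, $C_a=0.45$, $C_v=10$ ml/mmHg, $\Delta V_{v0}=65$ ml) stays
inside the validity ranges of the segment screen throughout — about a
15% blood-volume loss over 15 minutes, a brisk but survivable
hemorrhage. With the baroreflex compensating, the fight-or-flight rise
in pulse pressure only emerges from a settled baseline; comparisons in
the tests therefore start at the end of the 5-minute hold-in period.

## Waveform synthesis and feature extraction

The estimator consumes five observables at 10 Hz: mean arterial and
venous pressure, heart rate, pulse pressure, and $\widehat{RC}$, the
scaled resistance-compliance product read off the diastolic decay. Real
monitors provide 125 Hz waveforms, so the package includes both
directions:

* `synthesize_waveforms()` renders an observable series as a
  beat-resolved record: each beat is a raised half-cosine systolic
  upstroke over 30% of the cycle followed by an exponential diastolic
  run-off with time constant $RC/\alpha_{RC}$; systolic peak and decay
  asymptote are solved per beat so the peak-to-trough range equals the
  pulse pressure and the beat average equals the mean pressure. The
  morphology itself is a modelling convenience — only the per-beat mean,
  range, rate and decay constant carry information downstream — so no
  dicrotic notch or wave-propagation detail is attempted.
* `extract_observables()` inverts it: trough-onset beat detection
  (slope threshold plus a 0.2 s refractory period), per-beat extrema, a
  per-beat log-linear fit of the diastolic run-off for the decay
  constant, robust outlier clamping, and linear interpolation onto the
  10 Hz grid, with mean pressures as 10-s moving averages of the raw
  channels.

Numerical choices worth stating: the decay-constant fit first estimates
the per-beat asymptote from the lag-1 difference regression (exact for an
exponential whatever its floor) and then fits
$\log(P - P_{floor})$ against time; fits with $R^2 < 0.5$ are flagged
and imputed from neighbouring beats. Outlier clamping replaces samples
outside local median $\pm$ 3 scaled-MAD (20 s windows) by the violated
threshold itself, with the MAD floored at 0.5 mmHg (1 bpm for heart
rate, 0.05 s for RC) so a degenerate constant window clamps nothing. A
configurable low-pass stage exists but defaults to pass-through: on a
10 Hz series any cutoff above 5 Hz is meaningless, and the moving
averages already suppress beat-scale energy.

Segments of 300 s (starting every 100 s; a 25-minute record yields 12
windows, the flush-ended window being dropped) are screened before
estimation: every sample must satisfy
$20 < \hat P_a < 250$, $0 < \hat P_v < 25$ mmHg, $\widehat{RC} > 0$,
$30 < \widehat{Hr} < 250$ bpm, $\hat P_p > 10$ mmHg.

## The estimation problem

Per valid segment, the fifteen parameters minimize the time integral (a
left-Riemann sum on the 10 Hz grid) of five weighted, normalized squared
residuals: heart rate, scaled resistance, pulse pressure, volume
bookkeeping, and arterial flow balance (the last two involve smoothed
derivative channels, built with a Savitzky–Golay first-derivative filter,
window 30 s, order 2). Weights are $w_H = 1$, $w_R = w_P = w_I = 0.2$,
$w_a = 10$; normalizers are the segment means of the corresponding
observed channels (the volume term is normalized by the upper bound of
$\tilde I_{ex}$). A history penalty (weight $\beta = 0.1$, memory
constant $\tau = 500$ s, recency-weighted $e^{-(t - \bar t)/\tau}$) ties
the slowly-varying parameters — compliance ratio, unstressed-volume
reserve, set point, and the heart-rate and resistance range ends — to
their earlier estimates, scaled by the squared upper bound of each
parameter. The drives $S(t)$ and $M_{SVR}(t)$ are linear within a
segment (time measured from segment start) and clipped to their
admissible ranges; the baroreflex is evaluated on the *measured*
arterial pressure, which keeps every residual algebraic in the
parameters.

Bounds come from pediatric normative tables by age bracket (set point,
heart-rate floors and ceilings) and from a per-kg blood-volume argument
for the volume terms: blood volume 100 ml/kg up to 3 months of age
(75 ml/kg after), an unstressed venous reserve of 10–30% of blood
volume, and a volume-change rate capped at 25% of blood volume per hour,
each divided by the arterial-compliance-per-kg range
(0.02–0.15 ml/(mmHg·kg)) so that weight cancels in scaled units. The
printed neonatal simulation values fall inside these intervals, which is
the consistency check the bounds were built against. $\alpha_{RC}$,
absent from the normative tables, spans $[0.1, 10]$. As data accrue the
rate bounds tighten monotonically: the minimal heart rate cannot exceed
the smallest heart rate already seen, and symmetrically for the maximal
heart rate and the scaled resistance range.

### Optimization

The per-segment problem is box-constrained, smooth, and multimodal. It
is solved in normalized $[0,1]^{15}$ coordinates by L-BFGS-B with an
analytic gradient (verified against central differences in the tests).
Multi-start provides the global component, replacing the commercial
global-search wrapper used in the original analysis: the first restart
is a deterministic *warm start* inverted from the observables
(mid-range heart-rate bounds give an activation profile; the set point,
resistance and contractility ranges then follow by linear least squares;
the volume rate from the bookkeeping residual), and the remaining
restarts are seeded uniform draws inside the bounds. Plain uniform
restarts alone occasionally left every start of a realization in a
high-cost basin in which the activation sigmoids saturate and gradients
vanish; the warm start reliably seeds the physiological basin.
Everything is reproducible from one master seed, with per-segment
streams derived deterministically, and the best objective value is
non-increasing in the number of restarts for a fixed seed.

### Outputs

Each window yields the optimal parameter set, its objective value and
the winning restart; parameter trajectories are smoothed with a centered
5-segment moving average (the span is a presentation choice, not part of
the inference). `shock_indices()` reports $\bar I_{ex}$ (per minute),
$M_{SVR}$ at the segment midpoint, and $\tilde K_{max}$, with
window-level means and standard errors. `reconstruct_observables()`
closes the loop by regenerating heart rate, scaled resistance and pulse
pressure from the estimates and the measured pressures; Pearson
correlations against the observed channels are the per-segment quality
score. Fast fluctuations are not reproduced by construction, because the
drives are linear within a segment.

## What the synthetic data do and do not show

The package's test battery runs entirely on synthetic subjects: the
forward model generates minute-scale observable envelopes, the waveform
synthesizer dresses them in beats, and the estimator is asked to recover
what was put in. This validates the *pipeline* — identifiability of the
shock signatures under the model's own dynamics, correctness of the
algebra, robustness of the optimization — at problem sizes a laptop
handles in minutes (recovery experiments use the developed-shock window,
minutes 10–25 of each scenario, split into three 300-s segments, with
5 restarts and 5 master seeds). It does not validate the model against
real monitor data: real records carry arrhythmias, damped catheter
lines, drug boluses, ventilation coupling and movement artifacts far
richer than the seeded spikes, dropouts and baseline wander that
`inject_artifacts()` provides. Accuracy figures on synthetic recovery
are therefore upper bounds on clinical performance, not estimates of it.

Known limitations, inherited from the model's scope: one heart chamber
(no pulmonary circulation or inter-chamber interaction), no ventilation
or pericardial coupling, contractility identified only up to the
ventricular-compliance scale (so $\tilde K_{max}$ is not comparable
across patients), and a weakly identified $M_{SVR}$ when the autonomic
and non-autonomic tone components move together — the estimator reports
its variability honestly through the per-segment scatter and standard
errors rather than hiding it.
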