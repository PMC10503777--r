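# cvstate

Mechanistic inference of hidden cardiovascular states from the two
pressure signals routinely available at an intensive-care bedside.

## The problem

Clinicians at the bedside infer quantities nobody measures directly —
intravascular volume loss, vascular tone, cardiac contractility — from
arterial and venous pressure traces, and use that mental model to
classify shock (hypovolemic, distributive, cardiogenic) and choose
treatment. `cvstate` implements that inference as an explicit inverse
problem on a lumped-parameter model of the systemic circulation with
autonomic control, requiring no prior knowledge of the patient beyond
age and weight.

The forward model evolves mean arterial and venous pressure:

    C_a dP_a/dt = C_a · Hr · P_p − (P_a − P_v)/R
    C_a dP_a/dt + C_v dP_v/dt − ΔV_v0 · dS_tot/dt = I_ex

with heart rate Hr, pulse pressure P_p, peripheral resistance R and the
unstressed venous reservoir ΔV_v0 all driven by a baroreflex
S_b = 1 − σ(k_b (P_a − P_set)), an independent autonomic drive S, and a
non-autonomic vascular modulation M_SVR ∈ [−1, 1]. The inverse problem
estimates fifteen hidden parameters per 300-second window by constrained
multi-start optimization of a weighted least-squares cost linking the
model to five observables extracted from 125 Hz waveforms: mean arterial
and venous pressure, heart rate, pulse pressure, and the scaled
resistance–compliance product read off the diastolic decay. Three
derived indices flag shock etiologies: Ī_ex = Ĩ_ex/ΔṼ_v0 (1/min,
negative while bleeding, weight-independent), M_SVR (negative in
vasodilatory states) and the maximal relative contractility K̃_max.

The package covers the whole chain — forward simulation of shock
scenarios, beat-resolved waveform synthesis, feature extraction with
validity screening, per-segment estimation with adaptive bounds and a
history prior, and shock-index reporting — each stage usable on its own
(`simulate_cvs()`, `synthesize_waveforms()`, `extract_observables()`,
`estimate_trace()`, `shock_indices()`), plus file-to-file commands
(`cmd_simulate()` … `cmd_report()`) and a thin dispatcher in
`inst/cli/cvstate.R`. The methods vignette
(`vignettes/cardiovascular-state-inference.Rmd`) documents the model,
its assumptions and every numerical choice.

## Worked example

Simulate an artificial neonate bleeding out over 15 minutes, then hand
the estimator only the observables and ask what happened:

```r
library(cvstate)

subject <- physical_params()                 # printed neonatal set
trace <- simulate_cvs(subject, scenario_library("hypovolemic"))
trace
#> cardiovascular trace: scenario 'hypovolemic', 15001 steps of 0.1 s
#>   P_a 48.0 -> 39.0 mmHg | P_v 4.00 -> 1.43 mmHg | Hr 127 -> 145 bpm

obs <- trace_observables(trace)              # noiseless 10 Hz observables
window <- obs[obs$t >= 600, ]; window$t <- window$t - 600
window <- as_observable_series(window, fs = 10)

est <- estimate_trace(window,
                      patient_meta(age_years = 0.02, weight_kg = 3.5),
                      cost_config(stride = 300), seed = 1)
shock_indices(est)$summary
#>   i_bar_ex i_bar_ex_se  m_svr m_svr_se k_max_rel k_max_rel_se
#> 1  -0.0315      0.0112 -0.001   0.0306  692.7849       5.0516
```

The window-average Ī_ex of −0.03 min⁻¹ is the bleeding signature (the
generating truth averages −0.04 min⁻¹ over this window); M_SVR ≈ 0
correctly reports no vasodilatory component, and K̃_max ≈ 690 mmHg sits
near the generating contractility ceiling of 800 mmHg. Running the same
pipeline on the `distributive` scenario yields Ī_ex ≈ 0 with markedly
negative M_SVR instead.

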