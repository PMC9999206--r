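# dropsort

Simulation and evaluation of **label-free, impedance-activated sorting of
cell-encapsulating droplets**.

Random encapsulation loads cells into droplets by a Poisson process with
mean λ (cells per droplet volume). The single-cell fraction peaks at
P(1; λ=1) = λe^{-λ} = 36.8 %, but at that loading P(≥2) ≈ 26.4 %, so the
single-cell purity achievable by rejecting only empty droplets,
P(1)/P(>0), is below 60 %. Dropping to λ ≈ 0.05 restores purity but
caps the sorted single-cell rate at `rate × P(1)` — under 10 droplets/s
for a 200 Hz sorter. An impedance-activated sorter breaks the trade-off:
each droplet crossing two coplanar electrode pairs produces a bipolar
differential current whose peak amplitude grades with the number of
viable cells inside (empty < single < multi, saturating above two
cells), an amplitude gate classifies it in real time, and a travelling
surface-acoustic-wave pulse (force F = Y_T·πr²·E, with Y_T from
fluid-sphere partial-wave scattering) deflects selected droplets to a
target outlet.

`dropsort` implements the full computational chain as composable,
seeded stages:

| stage | functions |
|---|---|
| Poisson encapsulation analytics & stream generation | `poisson_pmf`, `theoretical_purity`, `theoretical_sorted_throughput`, `sample_stream` |
| dielectric model: single-shell cells, Maxwell–Garnett mixing, 2D complex-conductivity field solver | `cell_complex_permittivity`, `droplet_effective_sigma`, `solve_field`, `frequency_spectrum`, `conductivity_spectrum`, `multi_cell_amplitude` |
| acoustic radiation force on droplets vs cells | `radiation_force_factor`, `arf_force`, `deflection_feasible`, `yt_table` |
| differential trace synthesis with ground-truth ledger | `trace_config`, `amplitude_from_model`, `synthesize` |
| event detection, gate calibration, trigger timing | `detect_events`, `calibrate_gates`, `classify_events`, `schedule_triggers`, `screen_trace` |
| virtual sorting and metrics | `virtual_sort`, `sort_metrics`, `gate_tradeoff`, `throughput_comparison` |
| orchestration | `run_config`, `demo_config`, `run_pipeline`, `report_metrics` |

The numbered scripts under `analysis/` run the studies in order
(encapsulation statistics, dielectric spectra, acoustic forces, signal
screening, virtual sorting, throughput comparison) and write their
tables under `results/`. The methods vignette
(`vignettes/droplet-sorting-model.Rmd`) documents the models,
assumptions, parameter defaults and numerical choices.

## Worked example

An end-to-end virtual sort of 2,000 droplets at high loading (λ = 0.5),
selecting single-cell droplets with auto-calibrated gates:

```r
library(dropsort)
res <- run_pipeline(demo_config("paper_high", n_droplets = 2000, seed = 1))
report_metrics(res$metrics)
```

```
droplets sorted: 2000 (target 527, waste 1473) in 10.0 s
pre-sort composition  (all droplets): empty 60.0% single 30.8% multi 9.2%
post-sort composition (target outlet): empty 0.6% single 99.4% multi 0.0%
purity (single in target outlet): 99.4%
recovery (of all true single droplets): 85.1%
enrichment: 3.23-fold (all-droplet basis)
target-outlet throughput: 52.7 droplets/s
```

Reading the output: the generator produced the Poisson mix expected at
λ = 0.5 (60 % empty, 31 % single, 9 % multi). Screening classified the
synthetic impedance trace, the trigger logic fired on gated single-cell
events under a 5 ms pulse / 200 Hz cap, and the sorter collected a
target pool that is 99.4 % single-cell — versus the 58 % ceiling that
empty-droplet removal alone could reach at this loading. Recovery is
85 %: the missing singles are mostly trigger-timing skips (two targets
inside one actuator lockout), as in the real device. Switching to
`demo_config("multi_mode")` reverses the selection and enriches
multi-cell droplets instead; `demo_config("paper_low")` reproduces the
conventional low-loading condition.

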