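# popchaos

Nonlinear-dynamics tools for detecting reduced resilience in
age-structured populations under sustained chemical stress.

## The problem

Ecotoxicological assessment usually asks whether a stressor changes
*abundance*. popchaos asks whether it changes *dynamics*: a resilient
population fluctuates irregularly (chaotically) over a broad attractor,
and sustained sub-lethal stress can push it toward regular,
low-amplitude dynamics long before abundance collapses. The maximal
Lyapunov exponent λ of the daily abundance series measures that
chaoticity — λ > 0 with bounded dynamics indicates sensitivity to
initial conditions — and the distribution of λ over a Monte-Carlo
ensemble of populations provides a statistical handle on it:

* simulate (or load) an ensemble of daily abundance series per
  treatment level, paired across treatments by shared initial
  conditions;
* estimate λ per run with the Kantz stretching-curve algorithm
  (time-delay embedding with m = 2, d = 1; neighbourhood-based
  divergence tracking; slope of the linear scaling region of
  S(Δn) = ⟨ln mean-neighbour-distance after Δn steps⟩);
* compare treatment distributions of λ to the control with paired
  Wilcoxon signed-rank tests and report the lowest concentration whose
  dynamics differ significantly — a dynamical no-effect threshold.

The package is aimed at stress ecologists and ecotoxicological
modellers who want to test for "emergent" dynamical effects that
individual-level endpoints (reproduction, filtration) and classical
population endpoints (growth rate) cannot show.

It ships a complete synthetic study: an individual-based, food-limited
Daphnia-like population model (neonates < 1.4 mm, juveniles < 2.6 mm,
adults ≥ 2.6 mm; stochasticity confined to randomly assigned fixed
maximum lifetimes) exposed to a press disturbance whose dominant
sub-lethal effect is log-logistic inhibition of reproduction, across
the concentration panel {0, 2.5, 5, 10, 20, 40} µg/l. Recurrence
plots, Poincaré sections, autocorrelation and embedding diagnostics are
included, as is an independent Benettin tangent-map oracle used to
validate the λ estimator on maps with known exponents.

## Worked example

A scaled-down experiment — 20 paired runs per concentration, 365
simulated days each — runs in about a minute:

```r
library(popchaos)
cfg <- experiment_config(n_runs = 20, base_seed = 42)
res <- run_experiment(cfg)
res
#> popchaos result bundle: 6 concentrations x 20 runs
#> Flagged estimates: 18 of 480
#>   neonates   lowest-effect concentration: 2.5 ug/l
#>   juveniles  lowest-effect concentration: 2.5 ug/l
#>   adults     lowest-effect concentration: 2.5 ug/l
#>   total      lowest-effect concentration: 2.5 ug/l

subset(res$summary, age_class == "total")
#>    concentration age_class  mean      sd  n
#>              0.0     total 0.287 0.01701 20
#>              2.5     total 0.223 0.01115 20
#>              5.0     total 0.211 0.00993 20
#>             10.0     total 0.207 0.01200 20
#>             20.0     total 0.183 0.01521 20
#>             40.0     total 0.144 0.02796 20
```

Reading this: the undisturbed control is chaotic (mean λ ≈ 0.29 per
day, every valid run positive), chaoticity declines monotonically with
dose, and already the lowest tested concentration differs significantly
from the control — the dynamical no-effect threshold lies below
2.5 µg/l under these study conditions. "Flagged" estimates are runs
whose stretching curve had no usable scaling region; they are excluded
from summaries and tests, with n reported.

Single-series tools are exported individually
(`estimate_max_lyapunov()`, `recurrence_matrix()`,
`poincare_section()`, `autocorrelation()`, `delay_embed()`, …), and
`analyze_external()` applies the identical analysis chain to
user-supplied CSV ensembles (`conc_<value>/run_<i>.csv`, header
`day,neonates,juveniles,adults,total`).

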