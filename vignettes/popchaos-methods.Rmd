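---
title: "Detecting reduced resilience in stressed age-structured populations"
author: "popchaos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting reduced resilience in stressed age-structured populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popchaos)
```

## The question

A population under a sustained ("press") chemical stressor may look
healthy by every classical endpoint — abundance, growth rate, age
structure — while its *dynamics* have already changed character.
popchaos operationalises a dynamical-systems view of this problem for
age-structured zooplankton populations: chaotic, irregular fluctuation
is treated as a signature of a resilient population exploring a broad
attractor, and the maximal Lyapunov exponent $\lambda$ of the daily
abundance series as a quantitative measure of that chaoticity.  A
stressor that inhibits reproduction shifts the dynamics toward
regularity; the per-treatment distribution of $\lambda$ over a
Monte-Carlo ensemble can then be tested against the control to locate
the lowest concentration with a significant dynamical effect — a
no-effect threshold defined on dynamics rather than on abundance.

The package provides the full chain: a synthetic data generator (an
individual-based population model under a dose-dependent reproduction
inhibition), nonlinear time-series characterisation (delay embedding,
recurrence plots, Poincaré sections, Kantz stretching curves), and
paired rank-based inference over ensembles.

## The individual-based population model

`run_simulation()` advances a Daphnia-like population in daily steps.
Each individual carries an age, a body length, a fixed maximum lifetime
drawn once at birth, a days-since-brood counter and a clutch buffer.
The census classifies individuals by length: neonates (< 1.4 mm),
juveniles (≥ 1.4 and < 2.6 mm) and adults (≥ 2.6 mm), recorded per day
together with the total.

Every day, in fixed order:

1. **Food input.** A well-mixed food pool decays by a fraction
   `food_decay` and receives a constant input `food_input`
   (mg C l⁻¹ d⁻¹).  Food is the only interaction channel between
   individuals (exploitative competition / crowding).
2. **Ingestion.** Individual maximum ingestion scales with length²
   (filtering area) times a Michaelis–Menten factor of food density;
   when total demand exceeds the pool all rations are scaled down
   proportionally.  The realised *ration fraction* (0–1) drives all
   other rates.
3. **Growth.** Von Bertalanffy increment toward the asymptotic length,
   multiplied by the ration fraction — food shortage stalls maturation,
   which lengthens the delayed feedback loop.
4. **Reproduction.** Adults accrue fecundity continuously at
   `brood_max / brood_interval × ration × (1 − inhibition)` eggs per
   day; on each brood date (every `brood_interval` days per mother) the
   integer part of the clutch is released and the fraction carries
   over.  Neonate length at birth rises with the mother's ration
   (maternal provisioning), which staggers cohort development.
5. **Survival.** An individual dies when it has lived out its maximum
   lifetime, or after `starve_days` consecutive days with a ration
   below `starve_coef × length` — maintenance scales with volume while
   intake scales with area, so large animals starve first and crashes
   thin the population from the top down rather than all at once.
6. **Ageing.** Counters advance; newborns (with fresh lifetime draws)
   join the population.

Stochasticity is confined to the uniform integer lifetime draws
(30–60 days); everything else is deterministic given the state.  Runs
start from 5 neonates and 3 adults; run *i* of an ensemble uses seed
`base_seed + i` *independently of the concentration*, so ensembles at
different doses are paired run-by-run through identical initial
conditions — the basis for the paired signed-rank tests downstream.

### Why an egg buffer instead of per-brood rounding

A literal per-brood rule `round(brood_max × ration × (1 − inh))`
quantizes reproduction in units of whole broods.  With moderate brood
sizes this erases sub-lethal effects: a 10 % inhibition of a 6-egg
clutch rounds back to 6, so low doses would have *no* effect at all,
and because the ration is shared, all mothers round the same way on the
same day, locking cohorts into step and producing long plateaus in the
census.  The accrual buffer realises the same expected rate while
responding continuously to small inhibition, and it desynchronises
mothers through their brood phases.

### Dose response

Reproduction inhibition is log-logistic,
$\mathrm{inh}(c) = c^h / (c^h + EC_{50}^h)$, zero at zero dose and 0.5
at the EC50.  The shipped defaults (EC50 = 35 µg/l, Hill slope 0.9)
describe an *effective population-level* sensitivity: shallow slopes
are typical when a chronic individual-level effect is integrated over
heterogeneous exposure histories, and the resulting inhibition spans
roughly 9 % at 2.5 µg/l to 53 % at 40 µg/l — enough for a measurable
dynamical effect at the lowest tested dose while the highest dose
depresses but does not extinguish the population.  Acute mortality
(48-h LC50 = 0.23 mg/l, three orders of magnitude above the panel) is
available as an optional daily hazard but is off by default.

### Calibration

The defaults were fixed by a grid search over the life-history and
resource parameters with four joint requirements on the default panel
{0, 2.5, 5, 10, 20, 40} µg/l: (i) the control persists for a year,
bounded, non-extinct, with irregular fluctuation; (ii) the
ensemble-mean $\lambda$ of the overall population decreases
monotonically with concentration; (iii) every valid per-run exponent is
positive; (iv) the lowest dose is already distinguishable from control
by the paired test.  The search settled at a control-ensemble mean
$\lambda \approx 0.29$ d⁻¹, marginally below the 0.3–0.7 d⁻¹ band we
had targeted for the control; we accepted this rather than trade away
(ii)–(iv), which carry the scientific content.  Population size at the
default food input is a few thousand individuals, large enough that
demographic integer jitter is small relative to the boom–bust
amplitude.

### What the generator does and does not emulate

The generator reproduces the *statistical structure* the analysis
needs — age-structured food-limited boom–bust dynamics, lifetime-only
stochasticity, press exposure acting on reproduction, run pairing — not
any calibrated laboratory population.  Real data add observation error,
environmental forcing, toxicokinetics and behavioural effects that are
absent here.  Passing the ensemble checks therefore demonstrates that
the *method* (estimator + inference chain) recovers a known dynamical
dose–response at realistic series lengths; it does not validate the
biology of any particular system.

## Nonlinear characterisation

All analyses drop the first 50 days (transient from the 8-individual
seed) and work on the remaining 316-sample series.  Scalar analyses use
a delay embedding with dimension $m = 2$ and delay $d = 1$; Poincaré
sections use $m = 3$.  These are deliberately fixed rather than
per-series optimised — `scan_embedding()` reports
false-nearest-neighbour fractions and ACF delay heuristics for
diagnostic use, but a fixed embedding keeps ensembles comparable.
Recurrence matrices default to an absolute neighbourhood of
$\varepsilon = 1$ abundance count (the resolution of the data); a
quantile mode (`eps_quantile()`) is provided because an absolute radius
is scale-sensitive across treatments.  `determinism_score()` reports
standard RQA determinism (fraction of recurrence points on diagonals of
length ≥ 2), quantifying the "pattern formation" that is otherwise
judged visually from recurrence plots.

## The Lyapunov estimator

`estimate_max_lyapunov()` implements the Kantz stretching-curve method:
for each reference point with at least `nf_min = 10` neighbours within
$\varepsilon$ (excluding temporal neighbours inside a Theiler window of
$d(m-1)+1$ samples), the log of the mean absolute scalar distance to
those neighbours is followed $\Delta n = 0 \ldots t_{max}$ steps ahead;
the average over reference points is the curve $S(\Delta n)$, and
$\lambda$ is the slope of its linear (exponential-divergence) segment.
Choices that matter:

* **Radius schedule.** Four log-spaced $\varepsilon$ between the 1st
  and 10th percentile of the pairwise embedded distances; the reported
  $\lambda$ is the median across radii.  Distances at numerical-noise
  level are excluded from the percentiles.
* **Noise-floor screen.** Integer-valued counts carry demographic
  jitter.  A curve whose initial decorrelation jump (up to
  $\Delta n =$ `dn_min`) exceeds 0.5 log units while everything gained
  afterwards stays below 0.3 is measuring that jitter, not divergence;
  such radii are discarded.  If no radius survives, the estimate is
  flagged `no_scaling_region`.
* **Fit window.** Candidate windows start at `dn_min = 2` (the first
  steps reflect noise decorrelation), contain at least 3 points, must
  show a non-negative slope (a declining window on a rising curve is a
  saturation or orbit-phase artifact, not contraction — the method
  cannot measure negative exponents), and exclude the trailing
  saturation band (points within 0.25 log units of the curve maximum,
  when the curve has levelled off).  Among qualifying windows with
  $R^2 \ge 0.9$ the longest wins; if none qualifies the best-$R^2$
  window is used and the estimate is flagged.  Curves that never rise a
  full log unit have no observable divergence: the full-range slope
  (near zero) is reported with the `no_scaling_region` flag.
* **Ties.** Exactly zero scalar distances (integer data) are floored at
  half the minimal nonzero spacing before the logarithm.

Flagged estimates are excluded from summaries and tests, with the
per-cell `n` reported.  `is_chaotic()` applies the positive-exponent
criterion with a 0.05 d⁻¹ margin for estimation noise.

The estimator is validated against an independent oracle:
`oracle_map_lyapunov()` computes exponents by the Benettin tangent-map
method for maps with analytic Jacobians.  On the logistic map at
$r = 4$ (analytic $\lambda = \ln 2$) and the Hénon map
($a = 1.4, b = 0.3$, $\lambda \approx 0.419$) the time-series estimate
agrees to within a few percent; across periodic and chaotic logistic
regimes the two agree wherever the true exponent is positive, and
stable cycles are reported non-chaotic.  A pure sine yields a flat
stretching curve and a near-zero, flagged estimate.

## Ensemble inference

`wilcoxon_signed_rank()` is a paired two-sided signed-rank test: zero
differences are dropped; with ≤ 25 untied pairs the p-value is exact
(subset-sum enumeration of the null distribution of the positive-rank
sum), otherwise a normal approximation with continuity correction and
tie-corrected variance is used.  `pairwise_tests()` tests every
concentration pair for one age class, pairing by run index (valid under
the shared-seed design) and removing flagged estimates pairwise; raw
p-values are reported by default (Holm adjustment is available behind a
flag, but the headline threshold is defined on raw control
comparisons).  `detect_threshold()` returns the lowest non-control
concentration whose distribution differs from control at
$\alpha = 0.05$.

## A worked run

A scaled-down experiment (20 runs per concentration; the full design
uses 100) runs in about a minute:

```{r example, eval = FALSE}
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

The mean exponent declines monotonically with dose, every treatment
differs significantly from control, and the detected threshold sits at
the lowest tested concentration — the dynamical no-effect level lies
below 2.5 µg/l under these conditions.

## Problem sizes and budgets

The shipped test-suite checks run the ensemble at 20 runs per
concentration and the acceptance script at 50; estimator validation
uses 5 000-point logistic and 10 000-point Hénon series; the type-I
calibration of the signed-rank test uses 1 000 null replicates at
$n = 100$.  These sizes were chosen so the entire verification chain
runs on a single CPU in a few minutes while leaving each check
well-powered.

## Limitations

* $\lambda$ on 316-point integer series is a noisy, scale-dependent
  estimate; the absolute values depend on the fit-window conventions
  above and should be compared only within a fixed analysis
  configuration.
* The estimator cannot measure negative exponents; regular dynamics are
  reported as "near zero, flagged", not as contraction rates.
* The threshold is defined by statistical distinguishability at the
  ensemble size used; it tightens with more runs and is not a
  biological no-effect concentration.
* The generator's dose–response and life history are an effective
  parameterisation, not a calibrated toxicokinetic model; transfer to a
  specific system requires recalibration against that system's data.
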