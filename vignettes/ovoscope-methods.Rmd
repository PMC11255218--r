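---
title: "Methods and design notes: embryo respirometry, thermal scope and expression profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovoscope)
```

This vignette is the package's own account of the models it implements,
the tunable parameters that matter, what the synthetic-data generator
does and does not emulate, and the design choices made where the design
was genuinely open. It states no empirical result that the test suite
does not itself compute.

## 1. Closed-chamber respirometry

### Model

An embryo sealed in a micro-plate vial (default 1750 µL) depletes
dissolved oxygen approximately linearly once sensor and handling
transients have settled. The rate is estimated from the best linear
segment of the trace and converted to a respiration rate with

$$\mathrm{MO_2} = (O_{2(A)} - O_{2(B)}) \cdot \frac{V/t}{M},$$

with concentrations in mg O~2~ L^−1^, the effective volume $V$ in litres
(chamber volume minus embryo-displaced volume), elapsed time $t$ in
hours, wet mass $M$ in grams. `process_run()` evaluates the equation at
the window's *fitted* endpoints, which makes it algebraically identical
to $-\text{slope} \cdot V$ (per embryo) and $-\text{slope}\cdot V / M$
(weight-specific); using raw first/last readings instead would re-inject
the very noise the regression removed.

### Window selection

`find_linear_window()` enumerates every contiguous window aligned to
sample points with duration between `min_minutes` (5) and `max_minutes`
(10), fits OLS in each and keeps the window maximizing R² (or minimizing
residual SD). Ties go to the latest-starting, then longest, window — the
steadiest part of the trace. A unit-test oracle re-derives the selection
by brute-force enumeration with `lm()`. Degenerate constant windows
report slope 0 with R² defined as 0. Traces shorter than the minimum
window are an error; traces within two samples of the minimum are used
whole (with a warning), which is how short late-development TIMR-max
records (8 min in practice) remain usable.

### Blank correction

Control vials measure background O~2~ drift (sensor drift, microbial
respiration). The embryo slope is corrected by the *mean* blank slope at
the same temperature. One deliberate asymmetry: blank slopes are fitted
over the **whole trace**, not a max-R² sub-window. A blank trace is flat
noise; selecting its most "linear-looking" 5-min segment systematically
finds spurious steep stretches (in our simulations this overstated a
0.05 mg L^−1^ h^−1^ drift roughly three-fold and biased every corrected
rate). A whole-trace OLS is the standard drift estimate and is unbiased.
Correction is on by default and can be disabled
(`blank_correction = FALSE`); with no blanks available the slope passes
through with a warning (or an error, configurable in
`blank_correct()`).

### Displaced volume

The study design states that $V$ excludes the embryo-displaced volume
but not how that was obtained; we compute it from wet mass assuming a
tissue density of 1.0 g mL^−1^ (`tissue_density` argument), a <7% effect
even for the largest embryos.

## 2. Thermal metabolic scope

Rates at the cold (TIMR-min, 11 °C) and warm (TIMR-max, 30 °C)
exposures come from *different* embryos, so the scope must be computed
from smoothed curves, never from pairwise differences.
`fit_mo2_weight()` uses loess (degree 2, tricube kernel) of per-embryo
MO~2~ on wet weight; `thermal_scope()` evaluates both fits on a common
grid (default 200 points on the intersection of the observed ranges; no
extrapolation) and forms `TMS = HMR − LMR` and `FMS = HMR / LMR`
pointwise. FMS is reported pointwise *and* as the mean of pointwise
ratios (attribute `fms_mean`), because the two summaries answer
different questions and the field uses both.

### Why the loess span is adaptive

The span was genuinely open (the method is described only as "loess").
A fixed span of 0.5 seems a safe default but is demonstrably wrong for
this problem: with a few hundred embryos whose weights pile up at the
small end (exponential growth sampled uniformly over stages), a 0.5
neighborhood at the heavy end spans most of the weight range and
flattens the sharp metabolic step near the activation weight
(~0.09 g), biasing the TMS peak location right by ~15% in our recovery
tests. The default is therefore `min(1, max(0.15, 35/n))`: roughly
35-point neighborhoods, never below 15% of the data, degrading
gracefully to a global quadratic for tiny datasets. Any fixed span can
be forced via `span=` and is recorded in the fit object.

### Features

`locate_scope_features()` reports interior local maxima of TMS on the
grid (optionally after a running-mean smoothing), the global maximum and
the terminal trend (sign of the OLS slope over the last decile of the
grid). Peaks are grid points; no subgrid interpolation is attempted —
the grid (default 200 points) already oversamples any feature loess can
resolve.

## 3. Growth models

`fit_exponential()` fits $W = a e^{b\,\mathrm{stage}}$. The default is
OLS on $\log W$: embryo weight noise is multiplicative and grows with
stage, so log-scale fitting stabilizes the variance; an `nls` refinement
on the original scale is available (skipped automatically when the
log-linear start already fits exactly, where `nls` cannot iterate on
zero residuals). Two parameters keep the inverse prediction
identifiable; `predict_weight()` flags stages outside the fitted domain
as extrapolation — back-predicting stages 6–9 from a model fitted on
10–19 is exactly this flagged mode.

## 4. Biomarker profiles

`stage_profile()` orders groups ovary, un-spawned eggs, then stages
ascending, and reports mean, SD (n−1; `NA` for singleton groups rather
than a misleading 0) and n. `fold_ratio()` uses a seeded percentile
bootstrap (default 2000 resamples, 95%) rather than a parametric test,
since no distributional model is assumed for these assays. A caveat the
tests document: at n = 5–6 per group a 95% percentile interval for a
ratio undercovers (≈83–90% measured coverage) — the usual small-sample
behaviour of percentile intervals; treat the CI as indicative at such n.
Units are free-form strings, validated only for consistency within an
analyte; assay chemistry (absorbance-to-activity conversion) is out of
scope, inputs are already in activity/concentration units.

## 5. qPCR quantification

* **Efficiency**: mean technical-replicate Cq per dilution level,
  OLS of Cq on log~10~ relative input, $E = -1 + 10^{-1/\text{slope}}$.
  Estimates outside 80–110% warn (real assays span roughly 82–107%);
  positive slopes flag the estimate invalid rather than erroring.
* **Relative quantity**: $RQ = (1+E)^{Cq_{cal} - Cq}$ with, by default,
  the gene's mean Cq across samples as calibrator (a fixed calibrator
  sample can be named instead — the choice only rescales all RQs of a
  gene and cancels from between-group contrasts).
* **Normalization**: $NF$ = geometric mean of the sample's
  reference-gene RQs (defaults TufM and Gpam); $NRQ = RQ/NF$. All
  statistics are done on $\ln NRQ$ and summaries stay on the ln scale —
  variances of log-transformed values are not back-transformable.
* **Stability**: the original web tool used for reference-gene choice is
  closed, so the ranking is approximated by two of its published
  components: a geNorm-style M (mean SD of pairwise log~2~ expression
  ratios) and the comparative-ΔCt SD, combined by the geometric mean of
  the component ranks. With technical triplicates averaged first, the
  ranking is invariant to sample permutation and gene relabeling
  (property-tested). One known artifact, visible in the synthetic world:
  a candidate that co-varies with globally drifting targets can look
  "stable" by ratio criteria — stability should be assessed within the
  candidate reference panel, not against strongly regulated targets.
* **Stage comparison**: one-way ANOVA of $\ln NRQ$ across the four
  developmental phases (blastulation, organogenesis, activation,
  growth), Tukey HSD on request, Kruskal–Wallis as a distribution-free
  alternative. The omnibus test used in the original analyses is not
  named beyond the software, so ANOVA is an inference, stated as such.
  With zero within-group variance the F statistic is undefined and the
  result says so instead of fabricating a p-value.

## 6. The synthetic world

The generator (`simulation_config()` + `generate_*()`) emulates the
statistical structure the analysis assumes, with every true parameter
returned alongside the data:

* **Cohort**: weights $a e^{b\,\mathrm{stage}} e^{\varepsilon}$,
  $\varepsilon \sim N(0, \sigma(\mathrm{stage}))$ with σ increasing
  linearly in stage (defaults a = 1.5 mg, b = 0.22, σ from 0.05 to
  ~0.12) — stage means span ~5.6 to ~98 mg, and the spread grows with
  development as in real clutches.
* **Traces**: $O_2(t) = O_{2,0} - (\mathrm{MO_2^{true}} M + d V) t/V$
  plus Gaussian sensor noise (default SD 0.01 mg L^−1^), optional
  exponential settling transient, truncation at 0 with a warning.
  Blank vials carry drift $d$ (default 0.05 mg L^−1^ h^−1^) and noise
  only. The default true MO~2~–weight profile
  (`default_mo2_profile()`) is a piecewise power/logistic shape: cold
  branch a smooth power rise; warm branches a power rise, a sharp step
  at 0.091 g (the activation of heart and circulation), a plateau and a
  pronounced pre-hatch decline. Magnitudes (0.3–11 mg O~2~ L^−1^ h^−1^
  slopes) were chosen once so 20-min traces neither hit anoxia nor
  drown in sensor noise. The implied TMS curve peaks just past the
  step and falls toward hatch.
* **qPCR**: dilution Cq follows the efficiency model exactly; sample Cq
  encodes designed per-phase fold-changes (targets mimic rising CAT and
  MnSOD, organogenesis-peaked CuSOD, blastulation-low HIF1A; TufM and
  Gpam exactly stable; EF1b and hnRNP mildly drifting so a stability
  analysis has something to rank); technical triplicates with Cq noise
  SD 0.15 cycles.
* **Biomarkers**: truncated-normal draws around designed group profiles
  (antioxidant enzymes ovary-high with designed OV/USE ratios of 350
  and 150 for SOD and CAT, rising from activation in embryos; damage
  markers declining below 0.5 nmol mg^−1^ by stage 19; GSH flat).

What the generator does **not** emulate — and hence what a green test
does not establish: serial correlation or drift in optode readings
beyond a linear blank term, stage-misclassification, inter-run qPCR
batch effects, plate-position effects, non-normal biomarker error, and
any claim about the source study's actual fitted curve values. Recovery
tests score estimators against *this* generator's truth, nothing more.

## 7. Numerical choices and degenerate inputs

* Window statistics use centred cumulative sums (exact to ~1e−9
  relative against `lm()` on 200-point traces); candidate ties are
  broken deterministically (latest start, then longest).
* Loess uses `surface = "direct"` so predictions are exact rather than
  interpolated, making the identity `thermal_scope(f, f) ≡ (0, 1)` hold
  to machine precision.
* O~2~ truncation at 0 warns rather than errors (a real trace can touch
  the sensor floor; the window search then avoids the censored tail by
  its linearity criterion).
* Efficiency slope 0 is an error (efficiency undefined); slope > 0 is a
  flagged-invalid result, because a wrong-signed but finite curve is
  diagnosable downstream.
* All generators derive their RNG streams from `seed` plus a fixed
  per-generator offset, so outputs are byte-identical across runs and
  sub-tables are independent of each other.

## 8. Known limitations

* No oxygen solubility/salinity corrections or intermittent-flow
  designs; strictly closed-chamber.
* TIMR proxies are not formal SMR/MMR estimates; no quantile-based
  estimation is attempted.
* The stability ranking approximates, not replicates, the closed web
  tool it stands in for.
* The spec'd YAML simulation config is accepted as JSON instead (no
  YAML parser in the supported dependency set); the schema is the same.
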