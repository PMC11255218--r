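# ovoscope

Quantitative analysis of cephalopod embryo development: closed-chamber
micro-respirometry, thermal metabolic scope, exponential growth models,
oxidative-stress biomarker profiles and efficiency-corrected qPCR relative
expression — with a seeded synthetic-data generator so every estimator can
be validated against known ground truth.

## Who this is for

Ecophysiologists working with octopus (or other cephalopod) embryos who
measure oxygen consumption in sensor-spot micro-plate vials, proxy aerobic
scope with the temperature-induced metabolic rate (TIMR) method, weigh
eggs and embryos across Naef stages, assay antioxidant enzymes and
oxidative damage, and quantify antioxidant-system gene expression by
RT-qPCR.

## The science in brief

**Respirometry.** A closed 1750 µL vial yields an O2-depletion trace
sampled every 15 s. The respiration rate is taken from the best linear
5–10 min segment (exhaustive window search, OLS slope, max-R² criterion),
corrected by the mean slope of blank control vials, and converted with

```
MO2 = (O2(A) − O2(B)) · (V / t) / M
```

where `O2(A)`, `O2(B)` are initial/final concentrations (mg O2 L⁻¹), `V`
the chamber water volume minus the embryo-displaced volume (L), `t` the
elapsed time (h), and `M` the wet mass (g). Rates are reported both per
embryo (mg O2 h⁻¹ embryo⁻¹) and weight-specific (mg O2 h⁻¹ g⁻¹).

**Thermal metabolic scope.** Rates measured after acute exposure to a
cold temperature (TIMR-min, 11 °C, proxy of standard metabolism) and a
warm one (TIMR-max, 30 °C, proxy of maximum metabolism) are smoothed over
embryo wet weight with loess (degree 2, tricube weights); the thermal
metabolic scope is `TMS = HMR − LMR` and the factorial scope
`FMS = HMR / LMR`, evaluated pointwise on a common weight grid. The
temperature sensitivity is summarized by
`Q10 = (MO2_T2 / MO2_T1)^(10 / (T2 − T1))`.

**Growth.** Egg and embryo wet weight follow `W = a·e^(b·stage)` over
Naef stages 6–19 (log-linear OLS by default); inverse prediction
back-fills the unmeasurably small early stages, flagged as extrapolation.

**Biomarkers.** SOD, CAT, GST, GSH, LPO and PO values over ovary (OV),
un-spawned eggs (USE) and embryo stages are summarized as group mean ± SD
(n−1; singletons report NA) and compared as bootstrap fold-ratios.

**qPCR.** Standard-curve slopes give amplification efficiencies
`E = −1 + 10^(−1/slope)`; reference-gene stability is ranked by a
geNorm-style M value combined with the comparative-ΔCt SD; expression is
quantified as efficiency-corrected relative quantities normalized by the
geometric mean of reference-gene RQs (Hellemans framework), analysed on
the natural-log scale with one-way ANOVA across developmental phases.

## Worked example

```r
library(ovoscope)

cfg <- simulation_config(seed = 42, n_embryos_per_stage = 50,
                         temperatures = c(11, 30))
sim <- simulate_all(cfg)                       # cohort, traces, qPCR, biomarkers
run <- process_run(sim$traces$traces, sim$cohort$cohort)
head(run$rates[, c("embryo_id", "stage", "temp_c", "mass_g",
                   "window_r2", "mo2_per_embryo", "mo2_specific")], 3)
#>   embryo_id stage temp_c      mass_g window_r2 mo2_per_embryo mo2_specific
#> 1     E0001     6     11 0.006013537 0.9355317   0.0010617728    0.1765638
#> 2     E0002     6     30 0.005458807 0.9917321   0.0033989911    0.6226619
#> 3     E0003     6     11 0.005718014 0.9050581   0.0008994767    0.1573058
```

Each row is one embryo's metabolic rate with its selected window and R².
Smoothing both temperatures and differencing gives the scope curve:

```r
curve <- thermal_scope(fit_mo2_weight(run$rates, 11),
                       fit_mo2_weight(run$rates, 30))
locate_scope_features(curve)
#>          feature   weight_g        value
#> ...
#> 5     global_max 0.10458695  0.010485039
#> 6 terminal_trend 0.10295389 -1.000000000
```

The TMS maximum sits at ~0.105 g — just past the activation step the
generator placed at 0.091 g — and the negative terminal trend is the
designed pre-hatch decline. `q10(0.05, 11, 0.15, 30)` returns `1.782857`
(a tripling over 19 °C).

```r
eff <- efficiency_from_dilution(sim$qpcr$dilution)
head(eff[, c("gene", "slope", "e_percent", "r2")], 3)
#>    gene     slope e_percent        r2
#> 1   CAT -3.782934  83.79983 0.9998613
#> 2 CuSOD -3.461506  94.48747 0.9997922
#> 3  EF1b -3.288020 101.43475 0.9993675

gm <- fit_exponential(sim$cohort$cohort$stage, sim$cohort$cohort$embryo_ww_mg)
gm
#> <growth_model embryo> W = 1.508 * exp(0.2193 * stage) mg; log-linear fit,
#>   n = 700, R2 = 0.991, stages 6-19
predict_weight(gm, 6:9)   # early-stage back-prediction
```

The recovered slope and efficiencies match the generator's ground truth
(b = 0.22; CAT efficiency 82.3%) within sampling error.

## Command line

```sh
Rscript inst/cli/ovoscope simulate --out sim/ --seed 1
Rscript inst/cli/ovoscope respiro --traces sim/traces.csv --cohort sim/cohort.csv --out rates.csv
Rscript inst/cli/ovoscope scope --rates rates.csv --low 11 --high 30 --out scope/
```

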