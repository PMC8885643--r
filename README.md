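# dualtracer

Simulation study of **staggered dual-injection brain PET** with two
carbon-11 radioligands — a fast, harmine-like MAO-A tracer and a slower,
DASB-like SERT tracer — for researchers in PET kinetic modelling who want to
test whether one dynamic scan can quantify two targets.

Both tracers emit identical 511-keV photons, so a dual session records the
*sum* of their signals. If the second tracer is injected Δ minutes into the
scan, the first Δ minutes contain the first tracer alone; its time-activity
curves (TACs) and arterial input function (AIF) can be fitted there,
extrapolated to scan end, and subtracted from the summed measurement to
estimate the second tracer's curves:

```
TAC_second_est(t) = TAC_dual(t) − TAC_first_ext(t),   t ≥ Δ
AIF_second_est(t) = AIF_dual(t) − AIF_first_ext(t)
```

Each tracer's total volume of distribution is then the Logan-plot slope with
metabolite-corrected plasma input,

```
∫₀ᵗ C_T ds / C_T(t)  =  V_T · ∫₀ᵗ C_p ds / C_T(t) + b ,   t ≥ t*
```

and recovery is scored by the absolute percentage difference
APD = |V_T,test − V_T,ref| / V_T,ref × 100 (median/IQR per region) and by
the Pearson correlation of estimated vs single-tracer V_T pooled over
13 brain regions × subjects.

Because no real dual sessions of this tracer pair are public, the package
ships a tested synthetic-kinetics generator (Feng-type plasma input,
Hill-type parent-fraction decline, two-tissue-compartment TACs with blood
volume, frame-based count noise) that emulates 90-min scans of 8 matched
subjects. A small decay-arithmetic module covers carbon-11 planning of the
delayed second injection (molar activity, remaining yield, per-kg dose).

## Worked example

```r
library(dualtracer)

cohort <- make_cohort(n_pairs = 2, seed = 42)      # matched subject pairs
cmp <- run_protocol_comparison(cohort, stagger = 45, seed = 7)
print(cmp)
#> <protocol_comparison> stagger 45 min, seed 7
#>   HAR first : r(V_T DASB est vs 45) = 0.991 (failed separations: 0%)
#>   DASB first: r(V_T HAR est vs 45) = 0.852 (failed separations: 0%)

print(cmp$har_first$report)
#> <eval_report> HAR first, DASB second (n = 2)
#>   pooled r(V_T DASB est vs 45 min single): 0.991
#>   pooled r(V_T HAR 90 vs 45 min): 0.996
#>   pooled r(V_T DASB 90 vs 45 min): 0.997
#>   median APD (DASB est vs 45): 2.2% across 13 regions
```

Reading: when the **fast tracer goes first**, the separated slow tracer's
V_T agrees closely with its 45-min single-tracer reference (r = 0.991,
median regional APD ≈ 2%); the reverse order degrades recovery (r = 0.852).
Truncating single scans from 90 to 45 min barely changes V_T (r ≈ 0.996).
15- and 30-min staggers are flagged `failed_separation` — the clean window
ends before the first tracer's kinetics are determined.

Dose planning for the delayed injection:

```r
fc <- feasibility_check(decay_plan(delay = 45))   # 100 GBq/umol, 2 GBq, 75 kg
#> molar activity at injection: 21.02 GBq/umol (pass: TRUE)   # limit: 20
#> dose for 75 kg at 4.51 MBq/kg: 338.25 MBq                  # 45 min = 2.25 half-lives
```

## Analysis workflow

The study itself is organised as numbered drivers over the package:

| script | what it does | writes |
|---|---|---|
| `analysis/01_cohort.R` | generate the 8-pair cohort, ground-truth V_T, example scan files | `results/cohort_vt_truth.tsv`, TAC/AIF TSVs |
| `analysis/02_simulate_dual.R` | sum single scans into staggered duals; verify the clean window | `results/S01_dual_*_tac.tsv` |
| `analysis/03_separate.R` | extrapolation–subtraction at Δ = 15/30/45, both orders | `results/separation_status.tsv`, estimated TACs |
| `analysis/04_quantify.R` | Logan V_T for all subjects/conditions/orders | `results/vt_table.tsv`, `results/report.json` |
| `analysis/05_evaluate.R` | per-region APD median/IQR table, pooled correlations | `results/apd_by_region.tsv` |
| `analysis/06_dose_planning.R` | carbon-11 decay/dose table vs delay | `results/dose_plan.tsv` |

Run them in order from the repository root (`Rscript analysis/01_cohort.R`
…). The methods vignette (`vignettes/dual-tracer-simulation.Rmd`) documents
the generative model, parameter defaults, numerical choices and limitations.

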