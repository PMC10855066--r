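# specbind

Binding analysis for titration spectroscopy: from UV-Vis and fluorescence
titration series of small-molecule ligands against DNA or plasma proteins to
association constants, quenching constants, binding-site numbers,
thermodynamic parameters and a rule-based binding-mode verdict.

It is written for the workflow used to characterize drug candidates against
calf thymus DNA and the plasma proteins α1-acid glycoprotein and gamma
globulin, and for anyone who needs those classical linearizations as tested,
scriptable estimators rather than spreadsheet formulas.

## The models

| Quantity | Model | Function |
|---|---|---|
| Chromism | %H = (A₀ − A)/A₀ · 100 | `chromism()` |
| Apparent association constant K_app | 1/(A_obs − A₀) = 1/(A_c − A₀) + 1/(K_app (A_c − A₀)) · 1/c | `benesi_hildebrand()` |
| Gibbs energy | ΔG° = −RT ln K | `gibbs_from_k()` |
| Stern–Volmer constant K_SV, k_q = K_SV/τ₀ | F₀/F = 1 + K_SV[Q] | `stern_volmer()` |
| Inner filter correction | F = F_obs · 10^((A_ex+A_em)/2) | `inner_filter_correct()` |
| Binding constant K_b, sites n | log₁₀((F₀−F)/F) = log₁₀K_b + n log₁₀[Q] | `double_log_fit()` |
| ΔH°, ΔS° | ln K_b = −ΔH°/(RT) + ΔS°/R | `vant_hoff()` |
| Probe displacement | %Ex = (F₀ − F)/F₀ · 100 | `displacement()` |
| Iodide protection | % reduction in K_SV with/without DNA | `ki_protection()` |
| Mode verdict | majority + veto over all DNA assays | `binding_verdict()` |

A seedable synthetic-data module (`ground_truth()`, `gen_uvvis()`,
`gen_quench()`, `gen_inner_filter()`, `gen_vant_hoff()`) draws titrations
from each law exactly, so every estimator is testable by parameter recovery.
Fits return broom-style objects with `tidy()`, `glance()` and `autoplot()`
methods; series read and write plain CSV (long or wide) and JSON.

## Worked example

A UV-Vis DNA titration with known ground truth (K = 5000 1/M, 1% noise),
fitted and classified:

```r
library(specbind)

gt <- ground_truth(k_true = 5e3, a0_true = 0.85, ac_true = 1.25,
                   noise_sd = 0.01, seed = 42)
s  <- gen_uvvis(gt, concs = seq(2e-4, 2e-3, by = 2e-4))

(fit <- benesi_hildebrand(s))
#> <Benesi-Hildebrand fit: Kapp = 5086 1/M (se 97), Ac = 1.25, r2 = 0.9983, 10 points>

gibbs_from_k(fit$kapp, 297)
#> [1] -21073.35

classify_uvvis_mode(fit)
#> # A tibble: 1 × 3
#>    kapp mode            indeterminate
#>   <dbl> <chr>           <lgl>
#> 1 5086. groove_or_mixed FALSE
```

The recovered constant (5086 1/M) sits within two standard errors of the
5000 1/M truth; its Gibbs energy, −21.1 kJ/mol, and the sub-10⁴ magnitude
put the ligand in the groove-or-mixed regime rather than intercalation.

Multi-temperature binding constants give the thermodynamic signature:

```r
kb <- gen_vant_hoff(ground_truth(dh_true = -100e3, ds_true = -250,
                                 noise_sd = 0.01, seed = 7))
(th <- vant_hoff(kb))
#> <van't Hoff fit: dH = -102.1 kJ/mol, dS = -257.1 J/(mol K), r2 = 0.9998>

interaction_forces(th$dh, th$ds)
#> [1] "hbond_vdw"
```

Both signs negative: binding is driven by hydrogen bonds and van der Waals
contacts, spontaneous at all three temperatures (`gibbs_report(th)` gives
ΔG°(297 K) = −25.8 kJ/mol).

Whole assay sets run from a JSON config through `run_pipeline()`, which
writes per-assay CSV tables plus a full-precision JSON report and aggregates
the binding-mode verdict; `inst/cli/specbind` exposes `simulate`, `uvvis`,
`quench`, `thermo` and `report` subcommands over the same functions.

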