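# hfcua

Cost-utility analysis of add-on empagliflozin versus standard therapy in
heart failure with reduced (HFrEF) and preserved (HFpEF) ejection fraction,
from a Chinese healthcare-system perspective.

Health-economic modellers and HTA analysts get a fully tested Markov cohort
engine plus the surrounding decision-analytic machinery: deterministic base
case, one-way (tornado) sensitivity analysis, probabilistic sensitivity
analysis (PSA) with cost-effectiveness acceptability curves (CEAC), scenario
analysis, and a patient-level microsimulation that independently
cross-checks the cohort engine.

## The model

A discrete-time Markov cohort with 3-month cycles over a 10-year horizon for
a cohort starting at age 65. Transient states are NYHA classes I–IV, each
doubled by a one-cycle *post-discharge tunnel* that carries an elevated
readmission risk for the 90 days after an HF hospitalisation; CV death and
non-CV death absorb. Per cycle: competing death
(`1 − (1 − p_cv)(1 − p_ncv)`, apportioned by single-cause probability), NYHA
movement by a published 4×4 matrix, then hospitalisation of survivors.
Costs (standard therapy, drug, hospitalisation) and utilities (by NYHA
class, minus 0.1 per admission) accumulate half-cycle-corrected and
discounted at 5%/year. Trial-level cumulative incidences convert to
per-cycle probabilities under a constant hazard:

    r = −ln(1 − S_inc) / t,   P = 1 − exp(−r·T)

The headline statistic is the incremental cost-effectiveness ratio
`ICER = ΔCost / ΔQALY`, judged against willingness-to-pay thresholds of
$12,652.5 and $37,957.5 per QALY (1× and 3× per-capita GDP), with net
monetary benefit `NMB = λ·ΔE − ΔC` behind the CEAC. The methods vignette
(`vignettes/cost-utility-model.Rmd`) documents every structural choice,
default, and known limitation.

## Worked example

```r
library(hfcua)
params <- load_parameter_set(hf_config_path("hfref"))
run_base_case(params)
```

```
Base case, HFrEF population
           arm total_cost total_qalys life_years cv_deaths hospitalisations
       control    4702.33      4.1026   6.429577 0.5505249        1.3168531
 empagliflozin    5561.07      4.2415   6.614461 0.5221244        0.9697403
delta cost $858.75, delta QALYs 0.1389 -> ICER $6183.74/QALY (trade-off, very_cost_effective)
```

Read: over 10 discounted years, adding empagliflozin costs an extra $858.75
per patient and gains 0.139 QALYs (fewer CV deaths, ~0.35 fewer HF
admissions), i.e. $6,183.74 per QALY gained — below the $12,652.5/QALY
threshold, so the add-on is classified very cost-effective. The HFpEF
configuration (`hf_config_path("hfpef")`) gives $11,078.83/QALY.

The numbered drivers under `analysis/` run the full study and write tables
under `results/`:

```sh
Rscript analysis/01_base_case.R      # per-arm totals, increments, ICER, traces
Rscript analysis/02_owsa.R           # tornado tables
Rscript analysis/03_psa_ceac.R       # 1,000-draw PSA, scatter + CEAC
Rscript analysis/04_scenarios.R      # drug price / hospital level / horizon
Rscript analysis/05_microsim_check.R # cohort engine vs microsimulation
```

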