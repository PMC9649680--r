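---
title: "A Markov cohort cost-utility model for add-on empagliflozin in heart failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort cost-utility model for add-on empagliflozin in heart failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfcua)
```

## The decision problem

`hfcua` evaluates whether adding empagliflozin (10 mg daily) to standard
therapy is cost-effective for 65-year-old patients with heart failure with
reduced (HFrEF) or preserved (HFpEF) ejection fraction, from a Chinese
healthcare-system perspective. The output of interest is the incremental
cost-effectiveness ratio (ICER),

$$\mathrm{ICER} = \frac{\Delta C}{\Delta E}
  = \frac{C_{\text{empagliflozin}} - C_{\text{control}}}
         {E_{\text{empagliflozin}} - E_{\text{control}}},$$

with costs in 2022 USD and effects in quality-adjusted life years (QALYs),
judged against willingness-to-pay thresholds of \$12,652.5/QALY (1×
per-capita GDP) and \$37,957.5/QALY (3×).

## Model structure

The cohort model is a discrete-time Markov chain with a 3-month cycle. The
published structure has five states — NYHA functional classes I–IV plus
death — with death split into cardiovascular (CV) and non-CV causes. Because
the readmission risk is elevated only in the 90 days after an HF
hospitalisation, we expand each NYHA class with a one-cycle *post-discharge
tunnel* flag, giving ten transient states (4 NYHA × tunnel yes/no) and two
absorbing states. A patient hospitalised in cycle $k$ occupies the tunnel
copy of their NYHA class during cycle $k+1$ and faces the readmission
probability instead of the baseline hospitalisation probability; one cycle
later the flag is dropped. The tunnel is what lets a memoryless chain carry
the published 30-day readmission risk.

Within each cycle, events are ordered:

1. **Competing death.** With single-cause per-cycle probabilities $p_{cv}$
   (arm-specific) and $p_{ncv}$ (age-band-specific), the total death
   probability is $1-(1-p_{cv})(1-p_{ncv})$ (independence), apportioned
   between the two absorbing states proportionally to the single-cause
   probabilities.
2. **NYHA movement.** Survivors redistribute over classes by the published
   4×4 transition matrix, whose structural zeros (I→IV, III→I, IV→I, IV→II)
   are enforced exactly.
3. **Hospitalisation.** Survivors are admitted with the baseline probability
   ($p_{hosp}$, arm-specific) from non-tunnel states or the readmission
   probability ($p_{readmit}$, shared across arms) from tunnel states.

The ordering is a modelling choice (the source publication states none):
death first means decedents accrue no event costs in their death cycle,
the usual convention. CV death and hospitalisation probabilities are
NYHA-independent, exactly as published.

## From trial data to per-cycle probabilities

Trial-level cumulative incidences $S_{inc}$ observed over a follow-up of $t$
months are converted under a constant-hazard assumption:

$$r = -\frac{\ln(1 - S_{inc})}{t}, \qquad P = 1 - e^{-rT}, \qquad T = 3
\text{ months}.$$

With follow-ups of 16 months (HFrEF inputs) and 26.2 months (HFpEF inputs)
this reproduces every published per-cycle probability to its printed
precision; the follow-up constants live in the bundled configurations. The
30-day readmission risks (13.4% HFrEF, 18% HFpEF) are treated directly as
monthly rates, $P = 1-e^{-3r}$, the only reading that reproduces the
published 0.331 and 0.417. For the HFpEF CV-death inputs the bundled
configuration uses cumulative incidences of 8.2% (control) and 7.3%
(empagliflozin): these are the source trial's published event rates and the
only pair that reproduces the published per-cycle values 0.00975/0.00864
under the 26.2-month follow-up.

```{r conversion}
cumulative_incidence_to_cycle_prob(0.108, followup = 16)   # HFrEF control CV death
short_rate_to_cycle_prob(0.134, cycle_length = 3)          # HFrEF readmission
```

## Accumulation: discounting, half-cycle correction, disutility

Let $m_k$ be the occupancy vector at cycle node $k$ ($k = 0,\dots,N$;
$N = 40$ for the 10-year base case), $d_k = 1.05^{-k/4}$ the discount
factor, $u(s)$ the NYHA utility, and $e_k$ the expected hospitalisations
during cycle $k$. State-occupancy payoffs use the trapezoid of the
discounted payoff stream — the half-cycle correction:

$$\mathrm{QALY}_{occ} = \sum_{k=1}^{N} \frac{L}{2}
   \left( d_{k-1} \, u^\top m_{k-1} + d_k \, u^\top m_k \right),
   \qquad L = 0.25 \text{ y},$$

and identically for the per-cycle therapy (and, in the add-on arm, drug)
cost multiplied by the alive fraction. Under constant full-health occupancy
and no discounting this is exact (a 10-year immortal cohort accrues exactly
10 QALYs — one of the unit tests). Event payoffs — the hospitalisation cost
and the 0.1-utility admission decrement — belong to the cycle in which they
occur and are discounted at that cycle's end-of-cycle factor $d_k$; the
publication names the half-cycle correction without specifying the variant,
so these conventions are this package's documented choice.

Two readings of "each HF-related hospitalisation reduces utility by 0.1"
are implemented:

* `cycle_weight` — the decrement lasts one cycle: QALY loss
  $0.1 \times L \times e_k$;
* `absolute_qaly` — a fixed loss of $0.1$ QALY per admission.

The bundled configurations ship `absolute_qaly`. This is a calibration of a
genuinely under-specified input: with it the base case lands at
\$6,183.74/QALY (HFrEF) and \$11,078.83/QALY (HFpEF) against the published
\$5,612.06 and \$11,312.65 (+10.2%, −2.1%), whereas `cycle_weight` overshoots
HFrEF by ~30%. The mode in force is recorded in every run manifest.

The initial NYHA distribution is never published; the shipped default —
I 0.00, II 0.75, III 0.24, IV 0.01 — resembles the source trials'
predominantly class II/III enrolment and is explicitly an assumption (also
recorded in manifests). Base-case reproduction is conditional on it. Non-CV
mortality is taken as per-cycle probabilities for ages 65–79 in 5-year
bands; beyond the last band the default carries the last value forward
(needed only for 15/20-year horizons), with a log-linear-in-age alternative
available in configuration.

## Sensitivity analyses

**One-way (tornado).** Each parameter with a published range is pushed to
its endpoints with all else fixed; the tornado reports the ICER at each
endpoint and the swing. ICERs here are the raw ratio $\Delta C/\Delta E$, so
a sign flip in $\Delta E$ (which happens at the CV-death endpoints) shows up
as a very large swing rather than an undefined entry — matching the
published finding that the two CV-death probabilities dominate and exceed
3× GDP at their range limits.

**Probabilistic (PSA).** Ranges are read as 95% intervals, so
$\sigma = (\text{high}-\text{low})/(2 \times 1.96)$. Event probabilities,
utilities, and the disutility magnitude are sampled from beta distributions
fitted by the method of moments ($\alpha = m(m(1-m)/\sigma^2 - 1)$,
$\beta = \alpha(1-m)/m$); costs from moment-fitted gammas; transition rows
from Dirichlet distributions with concentration `row × ESS` (ESS 1,000 by
default, structural zeros preserved). Infeasible beta moments (the NYHA I
utility has mean 1.0) fall back to a point mass with a warning. Utility
draws violating the severity ordering are resampled. The discount rate and
non-CV mortality are not sampled. One integer seed makes the whole PSA
reproducible.

A caveat worth stating plainly: the publication reports 59.4% (HFrEF) and
53.1% (HFpEF) probability of cost-effectiveness at 1× GDP from its
1,000-draw PSA, but does not state how its distributions were parameterised.
Under the moment rules above, this package's PSA (see
`analysis/03_psa_ceac.R`) concentrates draws more tightly around the base
case and yields a noticeably higher acceptability for HFrEF (~78%) while
matching HFpEF (~59%). The published acceptability of only 72.6% at 3× GDP
implies a draw spread several times wider than Table-style ranges support
under any moment rule; we keep the documented rule rather than tune the
spread to the published curve.

**CEAC.** At each willingness to pay the probability cost-effective is the
fraction of draws with strictly positive net monetary benefit
$\mathrm{NMB} = \lambda \Delta E - \Delta C$ (ties count as not
cost-effective).

**Scenarios.** The bundled scenario set overrides the drug price (national
purchase price \$0.275/10 mg → \$24.75/cycle), the hospitalisation cost
(five hospital levels from \$1,029.73 to \$3,336.39), and the horizon (15,
20 years).

## The microsimulation oracle

`simulate_patients()` realises the same per-cycle event logic patient by
patient with Bernoulli/categorical draws and accumulates payoffs with
per-patient arithmetic — deliberately sharing no occupancy-vector algebra
with the cohort engine — so agreement between the two is evidence of
correctness rather than tautology. The test suite requires agreement within
3 Monte-Carlo standard errors at $n = 20{,}000$ patients on 20 randomly
generated parameter sets (and `analysis/05_microsim_check.R` shows
$n = 50{,}000$ on the bundled cohorts). `generate_random_param_set()`
supplies those random models: probabilities uniform on $[0, 0.3]$, ordered
utilities, costs to \$10,000, Dirichlet-perturbed transition rows with the
structural zeros kept. These are stress inputs for invariants (mass
conservation, monotonicity, oracle agreement), not realistic cohorts; a
passing sweep says the arithmetic is right, not that the model is clinically
calibrated.

## Numerical choices and problem sizes

* Occupancy sums are enforced to 1 within $10^{-9}$; transition-row sums
  likewise.
* Threshold equality classifies to the more favourable WTP class.
* The property suite runs mass conservation over $10^4$ random models and
  the oracle comparison at $n = 20{,}000$; the PSA uses 1,000 draws per
  population, matching the published repetition count. These sizes keep the
  full suite in the tens of seconds on one core while leaving Monte-Carlo
  error well below the decision-relevant differences.

## Limitations

Fixed treatment effects and transition probabilities over the horizon; no
adverse-event modelling; no non-HF hospitalisation; no patient-level
covariates in the cohort engine (heterogeneity lives only in the
microsimulation's sampling variability); currency values are taken as
published, with no inflation or exchange-rate handling. The base case is
conditional on two documented assumptions (initial NYHA mix, disutility
mode), and the PSA on a documented parameterisation rule the source
publication does not state.
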