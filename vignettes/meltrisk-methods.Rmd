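---
title: "Methods: mixture toxic units, source attribution and removal rates for snow-melt screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixture toxic units, source attribution and removal rates for snow-melt screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meltrisk)
```

## Scope and assumptions

`meltrisk` starts where quantification ends: its inputs are long-format
tables of per-sample, per-compound concentrations (ng/L), compound metadata
(source category, log Kow, log10 solubility), experimental acute EC50
records, and — for the treatment-plant analysis — dated influent and
effluent composite series with daily inlet flows. Peak picking,
quantification and enrichment correction are upstream and out of scope.

The risk model rests on two standard assumptions. First, acute toxicity of
the mixture follows **concentration addition**: each component acts as a
dilution of a common toxicant, so toxic units are summable within an
organism group. Second, where no experimental effect data exist, a
compound's toxicity is at least **baseline (narcotic) toxicity**, a linear
function of hydrophobicity on the log scale. Both are deliberately
conservative screening assumptions, not mechanistic claims.

## Toxic units and classification

For sample $s$, compound $i$ and biological quality element
$b \in \{\text{algae}, \text{crustacean}, \text{fish}\}$:

$$\mathrm{TU}_{s,b,i} = \frac{\mathrm{MEC}_{s,i}\,[\mathrm{mg/L}]}{\mathrm{EC50}_{b,i}\,[\mathrm{mg/L}]}, \qquad
\mathrm{TUsum}_{s,b} = \sum_{i\ \mathrm{detected}} \mathrm{TU}_{s,b,i}.$$

Concentrations are stored in ng/L and effect values in mg/L; the factor
$10^{-6}$ is applied exactly once, inside `toxic_unit()`, so no intermediate
quantity can be double-converted.

Tunable parameters, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| chronic thresholds | algae 0.02, crustacean 0.001, fish 0.01 (TUsum) | widely used prioritisation thresholds per organism group |
| acute threshold | 1 per BQE | TUsum = 1 places the mixture at its median acute effect level; configurable because screening practice varies |
| `min_tu` | 0.01 | smallest toxic unit named individually when ranking drivers; everything smaller is aggregated as "further compounds" |
| `cap_tolerance` | 0.5 log10 units | slack before the solubility cap engages, absorbing uncertainty in solubility estimates |
| percentile convention | type 7 (linear interpolation) | see below; exposed for sensitivity analysis |

Exceedance is **strict** (`tusum > threshold`): a mixture exactly at a
threshold is not flagged. Ties in driver ranking break lexicographically by
compound id, so ranks are reproducible.

## The EC50 selection hierarchy

For each compound and BQE, `select_ec50()` applies, in order:

1. **Experimental data.** If any experimental EC50 records exist for the
   pair, their 5th percentile is used and prediction is never consulted.
   The percentile is taken across *all supplied records*, species
   duplicates included: the record set is treated as the evidence base, and
   collapsing to species means would discard within-species replication.
   The convention is linear interpolation between order statistics
   (quantile type 7); with a single record the value passes through
   unchanged.
2. **Baseline QSAR.** $\log_{10}\mathrm{EC50} = a_b \cdot \log K_{ow} + b_b$
   per BQE. The shipped coefficients (`inst/extdata/baseline_model.yaml`)
   are generic narcosis-style values treated as *data, not code*: tests use
   synthetic coefficients, so nothing in the package's correctness depends
   on any particular QSAR parameterisation, and real analyses should supply
   fitted coefficients.
3. **Solubility cap.** Hydrophobic compounds get large predicted log Kow
   and hence implausibly large *toxic* predictions in linear models; an
   effect concentration also cannot exceed aqueous solubility. When
   $\log_{10}\mathrm{EC50}_{pred} - \log_{10} S > 0.5$, the prediction is
   replaced by $S$ and the provenance recorded as `solubility_capped`.
   Capping is contractive — it can only lower the EC50 and therefore only
   raise toxic units, the conservative direction for a screen.
4. **Exclusion.** No experimental data and no log Kow means no value: the
   compound is excluded from that BQE and listed in an exclusion report.
   Imputation is never attempted; a silent guess would be indistinguishable
   from evidence downstream.

Provenance (`experimental`, `predicted`, `solubility_capped`) travels with
every toxic unit so that risk conclusions resting on predicted values can
be identified and prioritised for experimental confirmation.

## Censoring and detection limits

Method detection limits follow the replicate-injection procedure:
$\mathrm{MDL} = t_{n-1,\,0.99} \times s$ with $s$ the replicate standard
deviation and the one-sided Student-t factor at 99 % confidence.
Concentrations strictly below the MDL are flagged censored; a value exactly
at the MDL counts as detected. Censored entries are retained for audit but
contribute **zero** to every sum, load and toxic unit — the analysis reports
what was detected. An MDL/2 substitution is available (`censored_as =
"half_mdl"`) purely for sensitivity analysis. A compound without an MDL and
without a configured default is a hard error: silent defaults hide data
problems.

Values between the MDL and a limit of quantification are not treated
specially; the package implements a single MDL cutoff.

## Source attribution and removal in the treatment plant

Daily influent concentrations of each compound are rank-correlated with the
inlet flow (Spearman, average ranks for ties; at least three detected days
required). Concentrations can only rise with flow if the compound travels
with the runoff; steady sources (household wastewater) are diluted instead.
With the default cutoff 0.5, $\rho > 0.5$ is `runoff_dominated`,
$\rho < -0.5$ is `diluted_other_source`, and everything else `mixed`. With
only six composite samples the coefficient takes coarse values; no p-values
are computed or used — classification is on the coefficient alone, and the
short series is exactly why the removal analysis below works on aggregated
loads rather than day-by-day ratios.

Cumulative load is $\sum_d c_d \cdot f_d$ (ng/L × m³/day, i.e. µg over the
period, since 1 ng/L × 1 m³ = 1 µg). The removal rate is
$1 - L_{\mathrm{eff}} / L_{\mathrm{inf}}$, never above 1 and legitimately
negative (deconjugation and matrix effects can release compound in-plant).
Bins: a compound whose effluent is censored on every day is its own class
(`effluent_below_mdl`, a lower bound on removal); otherwise > 80 % is
`high`, 50–80 % `medium` (both boundaries inclusive, so exactly 80 % is
medium), [0, 50 %) `low`, and below 0 `negative`. The compound set is the
intersection of influent compounds with an optional external set (typically
the compounds detected in snow), reported alongside the result. Mismatched
influent/effluent date spans truncate to their overlap with a warning; the
analysis window is configuration, defaulting to that overlap.

## Numerical choices

* **Summation.** All TU and load sums use compensated (Kahan) summation
  over sorted addends, making every total a deterministic function of the
  multiset of values — exactly invariant to row order and file splitting,
  which the tests assert with `expect_identical()`.
* **Strictness conventions.** Detected at the MDL boundary; *not* exceeded
  at a risk threshold; `mixed` at the correlation cutoff; 80 % and 50 %
  both `medium`. Each boundary is tested on both sides.
* **Degenerate inputs.** Empty tables propagate to empty, well-typed
  results (zero TUsum, no exceedance) rather than errors; insufficient data
  (fewer than 2 MDL replicates, fewer than 3 correlation pairs, zero
  influent load) raise dedicated condition classes so pipelines can react.
* **Category precedence.** A compound with any traffic-related use resolves
  to the traffic category; remaining precedence is
  pesticide_biocide > human_consumption > other.

## What the generators emulate

`generate_compound_library()`, `generate_snow_samples()` and
`generate_wwtp_series()` are first-class, tested code, and their defaults
*are* the study conditions the rest of the package is validated under.

**Snow.** 20 road and 3 background sites. Road sites share a per-compound
traffic fingerprint: random log-normal weights scaled so the expected
summed traffic concentration is 118 µg/L, a common site-level log-normal
factor with CV 0.37 (totals roughly 59–200 µg/L), and small per-entry noise
(sdlog 0.15). Background sites carry the fingerprint attenuated to 3 %
(≈ 4 µg/L totals). Sixty percent of compounds are singletons placed at
exactly one random site with a broad log-normal level, reproducing the
highly site-specific, long-tailed occupancy of real screening data. Every
emitted entry is clamped to at least the MDL — the table represents
detections — and a stated fraction (default 2 %) of entries is then planted
at half the MDL, so the censored fraction of the output is exact by
construction. When effect data are supplied, one **dominant risk driver**
is planted per road site: its concentration is set so its toxic unit is 5×
the realized sum of all other toxic units at that site for the target BQE.
Dominance is therefore guaranteed by construction, which is the point — the
recovery test checks the ranking machinery, not a probabilistic margin.

**WWTP.** Six daily composites with a rising-then-falling flow (distinct
daily values, so flow ranks are unambiguous). Runoff-driven compounds are
proportional to flow, diluted compounds inversely proportional, each with
multiplicative noise (default sd 5 %). The unrelated ("mixed") compounds
follow a shared household-source day pattern chosen as the permutation of
days whose ranks have the smallest possible |Spearman ρ| against the flow
ranks (exhaustive search over permutations for ≤ 7 days). This makes "no
flow relation" a *property of the generated data* rather than a post-hoc
filter: with six days a genuinely random pattern would land beyond |ρ| = 0.5
far too often for a class label to mean anything. Effluent concentrations
are the influent scaled by $1 - r_i$ day by day with per-compound true
removal rates allocated across the five bins in proportions 13:27:13:6:4;
the full-removal class is constructed so every effluent day falls below the
MDL, and compound base levels are floored so partial-removal effluent never
does. At zero noise every estimator recovers its planted parameter exactly
(to 1e-12), which the round-trip tests assert.

**What they do not emulate.** No mass-spectrometric artefacts (peak
shapes, matrix effects, quantification error), no between-compound
concentration correlations beyond the shared fingerprint and site factors,
no spatial structure among sites, no hydraulic residence time in the plant
(loads are aggregated over the whole window for exactly that reason), and
no claim that the scenario variance reproduces the real spatial field —
only its ranges and means. The synthetic experimental EC50s are log-uniform
over 10⁻⁴–10³ mg/L, which makes synthetic mixtures considerably more toxic
than typical field mixtures; passing tests therefore demonstrate that the
estimators recover planted truth under realistic *structure*, not that any
particular real campaign would yield these risk levels.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen to
exercise every code path with comfortable margins: 60–100-compound
libraries, the full 23-site snow campaign, 6-day WWTP series, 1000-case
oracle cross-checks for the rank statistics, and 20–40 seeds for the
stochastic recovery suites.

## Known limitations

* Chronic risk is assessed by thresholding acute TUsums, not from chronic
  endpoints (no NOEC/EC10 quotients, no species sensitivity distributions).
* Toxic units are mass-based (mg/L), matching the input conventions; a
  molar option is not provided.
* The baseline model is a single linear narcosis surrogate; class-specific
  QSARs for reactive or specifically acting compounds are out of scope, and
  predicted-provenance risk drivers should be read as hypotheses to confirm
  experimentally.
* Spearman classification with n = 6 is coarse by nature; the cutoff 0.5 is
  a screening convention, not an inference procedure.
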