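---
title: "Methods: deriving inhalation TTC values with ttcair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deriving inhalation TTC values with ttcair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttcair)
```

## The procedure and its assumptions

`ttcair` derives Threshold of Toxicological Concern (TTC) values for the
inhalation route. The underlying assumption of any TTC is that the
potency distribution of a *structural* group of tested chemicals is
informative about an untested member of the same group: if exposure to
the untested chemical stays below a conservative quantile of the group's
point-of-departure distribution (divided by an uncertainty factor), the
risk is considered negligible. The pipeline stages are:

1. **Cleaning.** Records with a toxicity value of exactly 0 or −999 are
   ambiguous database artifacts and are removed (counted, never silent).
2. **Annotation.** A `study_length` field is derived: *chronic* when the
   free-text study type says so or the duration exceeds 100 days (weeks
   ×7, months ×30.44); *subchronic* when stated or 35 ≤ d < 100;
   *reproductive / developmental / multigenerational* only when stated —
   duration never promotes a study into these designs; *subacute* below
   35 days. Exactly 100 days is left unclassified: the two stated
   duration rules genuinely leave that point uncovered, and we prefer an
   explicit gap over an arbitrary tie-break (the attrition log reports
   such rows).
3. **Unit standardization.** Values are carried on two parallel tracks,
   mg/m³ and ppm, end-to-end. Within the mg-family, g/m³ ×1000,
   µg/m³ ÷1000, and mg/L ≡ mg/m³. Across families the molar-volume
   relation `mg/m³ = ppm × MW / 24.45` applies, *only* when the
   molecular weight is known — a missing MW leaves the inconvertible
   track missing rather than guessed. The 24.45 L/mol constant is used
   exactly as conventionally printed, not recomputed from temperature
   and pressure.
4. **Relevance filter.** Inhalation route, NO(A)EL/NO(A)EC
   point-of-departure types only (LOAELs are never extrapolated), rodent
   species (rat/mouse/rabbit name variants), and an eligible study
   length. A repeat-dose record whose duration cannot be classified is
   kept and counted separately — dropping it would silently bias toward
   well-curated sources. The four criteria are independent masks, so
   filtering order cannot matter.
5. **Representative values.** Per substance and unit track: a singleton
   study is retained as-is; otherwise a single-pass two-sided Tukey
   fence `[Q1 − 1.5·IQR, Q3 + 1.5·IQR]` removes extreme outliers and the
   minimum survivor becomes the substance's representative value.
6. **Percentiles.** Group 5th percentiles are computed from the
   empirical distribution on the raw mg/m³ scale (log10 is used for
   plotting and normality diagnostics only). Optionally the percentile
   is bootstrapped (default 10,000 replicates) and the replicate median
   used.
7. **TTC formulas.** `TTC = P5 × dexp / 25` (mg/m³),
   `NOEL = P5 × dexp × (Vresp/bw) × 1000` (µg/kg-day),
   `TTC = NOEL × bw / 25` (µg/person-day).

The normality diagnostics (normal-CDF overlay, Q–Q, Shapiro–Wilk) exist
to justify step 6: when a class's log10 distribution fails them, a
parametric lognormal fit of the 5th percentile is *not* appropriate, and
the package deliberately provides no fitted-distribution route.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `dexp` | (6/24)·(5/7) ≈ 0.1786 | — | converts 6 h/d, 5 d/wk study exposure to continuous equivalent |
| `uf_total` | 25 | — | conventional 10 (inter-individual) × 2.5 (inter-species residual) |
| `vresp` | 20 | m³/day | consumer-scenario human respiratory volume |
| `bw` | 60 | kg | conventional human body weight |
| `molar_volume` | 24.45 | L/mol | ideal gas at 25 °C, 1 atm |
| fence `k` | 1.5 | IQR units | the standard Tukey fence multiplier |
| `min_n` | 20 | chemicals | below this a group TTC is tagged `insufficient_n` |

All constants are overridable only through explicit configuration
(`derivation_constants()`); the per-person/day formula is not usually
printed alongside the others, but it is the unique form consistent with
the paired mg/m³ ↔ µg/person-day columns of published tables
(`ttc_person_day(body_dose_noel(p5))` ≡
`air_conc_to_person_day(ttc_air_concentration(p5))`, an identity the
test suite checks to 10 significant digits).

Duration-adjustment factors default to 1.0 for every study length: the
workflow carries duration-adjusted columns, but no factor values are
asserted anywhere we trust, so the default deliberately does nothing and
the factor table is configuration (`adjust_for_duration()`).

## The Kroes decision tree

`kroes_assign()` is the per-substance tier walk: substances outside the
TTC domain (inorganics, polymers, proteins, bioaccumulative substances)
and the five-class cohort of concern (including steroids) are
*excluded*; a genotoxicity alert outside the cohort gets 0.15 µg/day;
organophosphates/carbamates 18 µg/day; otherwise Cramer III/II/I get
90/540/1800 µg/day. A substance with no flags and no Cramer class is
"not assigned" — a value, not an error, because batch pipelines must not
stop on unclassifiable structures. Adding an alert flag can only move an
assignment toward conservatism (a tested monotonicity property).

## Mode-of-action consensus

Three aquatic-toxicity profiler outcomes per substance (two Verhaar
implementations and an OASIS acute MOA profiler) are mapped onto one
canonical label set and combined: unanimity wins; else a strict
majority; else the most conservative label under a configured ordering.
The shipped ordering (baseline < ester < less-inert < narcotic amine <
phenols/anilines < aldehydes < α,β-unsaturated alcohols < specifically
acting < reactive, with *unclassified* below everything for tie-breaking
only) is a declared configuration default: no authority defines
conservativeness between, say, esters and narcotic amines. The choice is
motivated by baseline narcotics separating cleanly from reactive
electrophiles in potency, which is the distinction the final two TTC
groups (baseline, reactive) rely on. When only two labels are present
and they disagree, a majority is impossible and the conservative rule
applies.

One caveat worth stating: under the majority rule, adding a *duplicate*
of a less-conservative label to a disagreeing pair can lower the
consensus (baseline+reactive → reactive, but baseline+baseline+reactive
→ baseline). That is inherent to majority voting, not a defect; the
tested invariant is that duplicating the *consensus* label never lowers
it.

## What the synthetic generator emulates — and what it does not

`synth_config()` / `generate_substances()` / `generate_studies()` emit a
multi-source-database-shaped world with a hidden-truth sidecar:

* per-category NO(A)EC values lognormal on the log10(mg/m³) scale. The
  default category means (0.41 and 0.12 for the two default classes,
  sd 1.0) were chosen once so the analytic 5% quantile
  `10^(mean − 1.645·sd)` lands near published representative-value
  5th percentiles (~0.058 and ~0.030 mg/m³);
* about six studies per substance (1 + geometric with mean 6, truncated
  at 30) — anchored to a published ratio of ~1,525 studies to 244
  chemicals; the *shape* of the distribution is a modeling choice, the
  database's true shape being unpublished;
* mixed units (35% ppm, 35% mg/m³, 10% each mg/L, g/m³, µg/m³), with
  ppm rows generated by exact back-conversion through the substance's
  MW so the round trip is checkable to machine precision;
* free-text study types, day/week/month duration spellings, rodent name
  variants plus 5% non-rodents, 2% ambiguous values (0/−999), 5%
  extreme outliers injected multiplicatively at ×10⁴ so they reliably
  violate Tukey fences *in groups large enough to have fences*;
* three MOA profiler columns that each deviate from the substance's
  true MOA with probability 0.1.

It does **not** emulate: correlated errors between studies of one
substance, source-specific reporting biases, censored/range values,
LOAEL-only substances, non-lognormal potency tails, or the 40-plus
provenance fields of a real aggregated database. A green end-to-end test
therefore establishes that the pipeline's *mechanics* (filtering,
conversion, fencing, quantile and bootstrap estimation) recover a known
stated world — it says nothing about the epistemic quality of any real
database's records.

## Numerical choices and degenerate inputs

* **Quantiles.** Linear interpolation between order statistics is the
  default everywhere (the common statistics-environment default);
  nearest-rank is available by flag and the method is stamped into every
  estimate. The ECDF assigns `p_i = i/n` at the i-th order statistic.
* **Tukey fences** operate on the raw scale, per unit track, in a single
  pass, two-sided by default. Two-sided fencing can remove a *low*-tail
  value and thereby raise the representative minimum — a deliberate,
  visible choice (`tails = "high"` disables it). With 2–3 values and
  linear quartiles the upper fence always exceeds the maximum, so a lone
  extreme value in such small groups mathematically cannot be flagged;
  simultaneous outliers in one substance also mask each other. Measured
  on generator defaults, unconditional recall of injected outliers is
  ~82%, rising to ≥95% exactly where a single-pass fence can act
  (≥4 studies, one outlier) — the documented and tested claim.
* **K-S p-values** are exact when `min(n) ≤ 25` and the pooled sample is
  tie-free, asymptotic otherwise; the D statistic itself is computed by
  direct ECDF enumeration and the method used is recorded.
* **Bootstrap reproducibility.** Replicate r derives its RNG stream
  deterministically from `(seed, r)`, so results are independent of
  scheduling and byte-identical across runs.
* **Degenerate inputs.** Singleton groups skip fencing; constant samples
  yield zero-width bootstrap intervals; a zero-variance overlay warns; a
  fence that would remove everything returns the original set with a
  warning; percentile reports keep ≥6 significant digits internally so
  presentation rounding never feeds back into downstream arithmetic.

## Cross-dataset verification

`rederive_ttc()` recomputes per-class 5th percentiles and TTCs from
supplementary-shaped datasets (dropping exact-zero values with a note,
suppressing percentiles for classes with n < 2);
`carthew_systemic_to_air()` converts systemic mg/kg-day NOAELs to air
concentrations by inverting the body-dose formula
(`C = dose × bw / (dexp × Vresp)`) — the conversion used in the original
publications is unprinted, so this formula-consistent default is a
configurable hook and exact reproduction of their published "reproduced"
values is not claimed. Dataset comparisons use exact identifier set
algebra, Pearson correlation of log10 values, and a Welch t-test on
log10 values (pooled-variance by flag; whether historical comparisons
used Welch or pooled is unstated).

## Known limitations

* No LOAEL→NOAEL or route-to-route extrapolation, no identifier
  resolution, no structural profiling: profiler outcomes and Cramer
  classes are inputs.
* Cramer class II groups are computed but tagged `insufficient_n` at the
  default threshold of 20 chemicals.
* The ppm-track TTCs reuse the same constants as the mg/m³ track; no
  separate uncertainty-factor composition is attempted.
* Population-scale results from real databases (chemical counts,
  specific test statistics) cannot be reproduced without those
  databases; the test suite substitutes property-based checks on the
  synthetic world, as documented in the acceptance tests.
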