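---
title: "Semi-quantitative hazard prioritisation for circular food systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-quantitative hazard prioritisation for circular food systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazrank)
```

## The problem and the model

When a food system is made circular — manure replacing artificial
fertiliser, side streams fed to insects, supply chains shortened —
hazards can reach consumers along routes that the linear chain never
had. Quantitative exposure data for these new routes are usually
absent, so `hazrank` implements a semi-quantitative, three-step
scheme: describe the chain change, long-list candidate hazards, and
rank each hazard on an ordinal low/medium/high (L/M/H) scale.

The ranking is a two-stage composition of ordinal scores:

* **Presence** of the hazard in the final food, combined from
  *occurrence* in the raw material, *persistence* in the environment
  (manure, soil) and *transfer* to the edible product — or, for
  hazards that concentrate in a reared animal, from *occurrence* and
  *accumulation*.
* **Priority**, combined from presence and human-health *severity*.

Both combinations are total, monotone decision matrices over
$\{L, M, H\}$ (27 tuples for the three-way presence matrix, 9 for the
two-way matrices). They are data, not code: `default_matrices()`
ships the published rules, `load_combination_matrices()` accepts
variants (for example a transfer-down-weighted presence matrix),
and every loaded matrix is checked exhaustively for totality,
uniqueness and monotonicity before use. The model deliberately stops
at ordinal scores — no numeric risk product, no probabilistic
aggregation — because the data situations it targets cannot support
more resolution.

## Indicator classifiers and their thresholds

All thresholds live in one `classification_ruleset()`; defaults below,
every one configurable and serialisable (`load_ruleset()` /
`save_ruleset()`).

| Indicator | Evidence | L | M | H |
|---|---|---|---|---|
| persistence (chemical) | DT50 per compartment, days | $<30$ | $[30,100]$ | $>100$ |
| persistence (microbial) | achieved log-reductions $= \text{waiting time}/\text{days-per-log}$ | $\ge 4$ | $[2,4)$ | $<2$ |
| transfer (plant uptake) | $\log_{10} K_{OC}$ | $\ge 2.0$ | $[1.0,2.0)$ | $<1.0$ |
| accumulation | BAF | $\le 1$ | $(1,5]$ | $>5$ |
| occurrence (chemical) | ng/g dm in raw material | $<10^4$ | — | $\ge 2\times10^4$ |
| occurrence (microbial) | cfu/g dm | $<10^6$ | — | $\ge 10^7$ |
| occurrence (exceedance) | fraction of batches above the limit | $\le 3\%$ | unused | $>3\%$ |
| severity (chemical) | HBGV, µg/kg bw/day | $>10$ | — | $\le 10$, or any CMR/STOT-RE endpoint |
| severity (microbial) | DALY/case | $<0.01$ | $[0.01,0.1]$ | $>0.1$ |

Numerical conventions, fixed once and pinned by boundary tests:

* Two-sided bounds are **inclusive in MEDIUM** (DT50 of exactly 30 or
  100 days is M), matching the "<30 / 30–100 / >100" phrasing of the
  source thresholds.
* The exceedance rule is binary and strict: exactly 3% is LOW.
* Weekly guidance values are divided by 7; ADI, TDI, BMDL10 and
  daily-normalised TWI are all compared to the same 10 µg/kg bw/day
  cutoff. This mixes value types of different conservatism under one
  rule, which is inherited from the ranking scheme, not a choice made
  here.
* Antibiotic severity combines two *binary* components — chronic
  toxicity and resistance concern (second/third-choice antibiotic
  classes 2–3 score high) — as high+high→H, one high→M, both low→L.
  MEDIUM inputs are rejected rather than guessed, since the
  combination rule is undefined for them.
* The DT50 scale is $\log_{10} K_{OC}$ throughout. The source
  narrative mixes "$K_{OC} < 1$" with worked values quoted as log
  units ($0.5$ → high transfer, $\ge 2.0$ → low); the worked values
  are authoritative here, so the bounds sit on the log scale.

### Collapsing multi-matrix occurrence

Occurrence is often measured in several raw-material matrices (cattle,
poultry, swine manure). The registry keeps every measurement; the
classifier collapses them with `occurrence_collapse`, default
`"mean"`. The mean is what the published case levels correspond to:
the sulphonamide group averages 6 048 ng/g dm (low) even though its
poultry value alone (10 591) would cross the medium bound, and the
printed low can only be reproduced by averaging. A worst-case `"max"`
policy is available for conservative screening, and the package's
tests document where the two disagree.

### Overrides

A directly assigned level (`persistence_level`, `severity_level`, …)
always wins over the numeric rule and is flagged `override` in the
provenance. The shipped manure-case fixture uses this once:
*Salmonella* at 15.9 days/log over a 60-day waiting time achieves 3.77
logs, which the strict 4-log bound scores MEDIUM, while the published
assessment judged the two pathogens' persistence jointly LOW. The
fixture carries the published verdict; the strict value remains
testable through `classify_microbial_persistence()`.

## Uncertainty as one-level sensitivity

`sensitivity_one_level()` shifts each indicator ±1 level (clamped at
the scale ends), holds the others fixed, and re-derives presence and
priority through the matrices. This is the scheme's own notion of
uncertainty — "what happens to the rank if one underlying score is
wrong by one class" — and is exact, since the matrices are total.
Joint perturbation of several indicators is out of scope.

## The batch-mixing simulation

For the short-chain case study the only indicator that differs between
scenarios is occurrence, quantified as the fraction of flour batches
exceeding the EC maximum limit. Given a pool of per-field
concentrations:

* **short chain**: each batch is one field — one draw per repetition;
* **conventional**: each batch blends $n \sim \mathrm{DiscreteUniform}\{5,\dots,10\}$
  fields — $n$ draws averaged per repetition.

Both use 100 000 repetitions by default and draw **with replacement**;
the source does not state the sampling discipline, and with-replacement
makes repetitions i.i.d. and the short-chain scenario a consistent
estimator of the pool's own summaries (which is exactly how the
published raw-product table relates to the survey summaries). "Between
5 and 10" is read as inclusive of both endpoints. Batch means are
unbiased for the pool mean, so mixing leaves the mean unchanged while
medians and exceedance shift up (more batches touch some
contamination) and maxima shrink (dilution) — the central qualitative
finding, which the tests assert as distributional properties rather
than as shape-dependent point values. Milling is a multiplicative
processing factor in $(0,1]$ applied to concentrations only, limits
unchanged; the published factor ranges (e.g. 0.5–0.8 for DON in white
flour) are exposed as configuration, mid-range by default.

All randomness is seeded (`withr::with_seed`); identical inputs give
bit-identical summaries, and `n_min = n_max = 1` reproduces the
short-chain scenario draw-for-draw.

## Synthesising the concentration pool

The underlying 293-field wheat survey is unpublished; only its
median, mean, maximum and %>ML are printed. `synthesize_pool()`
therefore builds a *synthetic* stand-in from those summaries:

* **Model family**: a point mass at the censoring floor plus a
  log-normal body — the standard shape for right-skewed, LOQ-censored
  mycotoxin field data, supported by the printed medians sitting at or
  near the scenario minima (floors 25/25/10 µg/kg, inferred from the
  scenario table's min column, the one inference made beyond the
  printed numbers).
* **Calibration**: the three parameters (censored fraction, log-mean,
  log-sd) are fitted by Nelder–Mead multi-start on the realised pool,
  whose body uses stratified quantiles with seeded within-stratum
  jitter — so the fit is smooth in the parameters, deterministic per
  seed, and different seeds give different pools with near-identical
  summaries.
* **Post-conditions**: values are clipped into $[\text{floor},
  \text{max}]$ and the single largest value is set to the target
  maximum exactly (the sample maximum is a known datum, and the clip
  guarantees zero exceedance whenever max < limit, as for T-2/HT-2).
* **Tolerances**: median and mean within 5%, exceedance fraction
  within 0.5 percentage points (configurable); synthesis fails loudly
  rather than return an out-of-tolerance pool. Infeasible targets
  (e.g. positive exceedance with max below the limit) are rejected
  before any fitting.

What a green test on this generator establishes — and what it does
not: the simulation results are driven by the pool's *marginal*
distribution, which is matched in four summaries plus a plausible
shape family. Real field data have year and region structure,
multi-analyte correlation and a specific body shape that no summary
recovery can restore. Consequently the short-chain scenario statistics
(which converge to the pool's own summaries) and the conventional mean
(unbiased) are meaningful checks, while the conventional-scenario
median and maximum depend on the unpublished shape and are
deliberately not acceptance-checked.

## Known discrepancies in the published case tables

The strict matrices do not reproduce every printed verdict, and the
package records rather than hides this:

* Insect-substrate case: dioxins/PCBs (presence M, severity H) and the
  two mycotoxins (presence L, severity H) print Medium/Low where the
  matrices give High/Medium. `cmd_prioritize()` can carry a
  `printed_priority` column next to the strict output
  (`case2_printed_verdicts.csv`), and `matches_printed` makes the
  disagreement explicit. No attempt is made to guess the intended
  rule.
* Short-chain case: the running text calls T-2/HT-2 "medium priority"
  while the printed table and the matrices both give High via
  (presence M, severity H); the matrix/table answer is used.
* The insect-substrate case is evaluated one substrate at a time
  (`occurrence_matrix = "household waste"` or `"manure"`), not by
  merging the two printed occurrence columns.

## Limitations

Beyond the generator caveats above: no exposure assessment (the scheme
stops at hazard level), no pathogen growth/inactivation kinetics
beyond the days-per-log summary, no spatial or temporal field
correlation, and occurrence class bounds for raw-material
concentrations are reverse-engineered round defaults — they reproduce
the shipped case tables but must be reviewed for any new application.
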