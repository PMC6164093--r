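---
title: "Methods: scoring and validating a vitamin D FFQ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and validating a vitamin D FFQ}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vidffq)
```

## The instrument and its scoring model

A brief vitamin-D-only FFQ asks, for each of a small set of food items,
how many servings the respondent typically consumes per day, week, or
month. Each item carries a serving size (g), a frequency period, and a
vitamin D content per serving (µg) — the *calculation key*. Daily intake
is the linear combination

$$\text{intake} \;=\; \sum_i f_i \, a_i \, c_i ,$$

with $f_i \ge 0$ the reported servings per period (decimals allowed),
$a_i$ the period-to-day factor, and $c_i$ the resolved per-serving
content. The model is deliberately linear: it is additive over items,
homogeneous in frequencies, and monotone — properties the test suite
checks directly.

Three selection modes resolve $c_i$:

* **fixed** items use the instrument's printed content;
* **choose-from-list** items (the fresh/smoked-fish questions) use the
  arithmetic mean of the per-serving contents of the 1–2 products the
  respondent names as most commonly consumed — the *individualized*
  part of the key. With one selection the mean is that product's
  content, so the resolved content always lies between the minimum and
  maximum of the selected products;
* **free-text** items ("other fish", "fortified products to be
  specified") have no content in the key; the caller supplies µg per
  serving from packaging or external tables, per respondent. A
  zero-frequency answer never requires a selection or a content.

Contents are stored per serving, exactly as the instrument prints them,
rather than per 100 g; the packaged `cro_video_ffq()` key covers 22
question-level items in 7 product groups. The instrument's inclusion
floor (only foods with ≥ 0.01 µg vitamin D per 100 g) is enforced by the
validator after rescaling each serving.

**Period factors.** Daily = 1, weekly = 1/7, monthly = 12/365.25. The
instrument does not fix a month length; we take 365.25/12 ≈ 30.44 days
so that the three factors compose to exactly one year, which keeps
mixed-period totals internally consistent.

## Record scoring and adequacy

The reference method is a 3-day dietary record: three days (two
weekdays, one weekend day), each entry a product and a mass in grams,
scored through a food composition table (µg per 100 g):

$$\text{intake} \;=\; \frac{1}{3}\sum_e \frac{g_e \, c_{100,e}}{100}.$$

The divisor is fixed at 3: a day on which nothing vitamin-D-bearing was
eaten is data, not missingness; a record genuinely missing a day
violates the input contract instead and is rejected. Per-group
decomposition of record intake is available only when the composition
table carries group tags, since records, unlike the FFQ, are not
structured by instrument group.

Adequacy is classified against the Estimated Average Requirement for
vitamin D, 10 µg/day. An intake exactly at the cutpoint counts as
adequate ("meeting the requirement"); the cutpoint is a tunable
parameter (`ear_ug`) for use with other reference values.

## The agreement battery

All validation statistics operate on pairs of per-respondent intake
totals aligned by id.

**Bland–Altman.** Differences $d_j$ (natural scale, or differences of
logs — the default, since intakes are right-skewed and positive), limits
of agreement $\bar d \pm 1.96\,s_d$, and the Bland–Altman index
$100\,(n - n_\text{within})/n$, the percentage of pairs outside the
limits. Membership is inclusive, with a machine-precision guard
(`eps^0.5` scaled to the data) so that two methods agreeing up to
floating-point round-off yield an index of exactly 0 rather than
counting numerical dust as disagreement. The 1.96 multiplier is a
parameter; the a-priori decision rules are ≤ 5 % positive, ≤ 10 %
borderline, otherwise fail. For normally distributed differences about
95 % of points fall within the limits by construction, which the suite
verifies by simulation at n = 10 000.

**Quartile cross-classification.** Each method's vector is cut at its
*own* empirical quartiles using the linear-interpolation quantile
convention (R type 7); a value exactly on a cut goes to the lower
category, deterministically. Heavy ties can leave a category empty —
that is recorded as a warning inside the result, never an error, because
a sparse table is still interpretable. Correct = same quartile;
gross = opposite extreme quartiles. The decision rule is ≥ 50 % correct
and, simultaneously, < 10 % gross.

**Weighted κ.** Linear disagreement weights $w_{ij} = |i-j|/(k-1)$,
$\kappa_w = 1 - \sum w\,o / \sum w\,e$ with expected proportions from
the marginal products. At $k = 2$ this reduces to unweighted Cohen's κ.
If the marginals admit no chance disagreement the statistic is defined
as 1 when none was observed (all mass in one diagonal cell). Labels
follow Landis–Koch with breaks at 0.20/0.40/0.60/0.80; the published
bands leave the interval (0.20, 0.21) unaddressed, and we resolve the
gap by carrying the "slight" band up to 0.20 inclusive, which reproduces
every printed example. Negative values fall in the slight band.

**ICC(3,1).** Two-way mixed model, single measurement, consistency:
$(MS_R - MS_E)/(MS_R + (k-1)\,MS_E)$ from the ANOVA decomposition with
respondents as rows and the two administrations as fixed columns;
confidence limits from the Shrout–Fleiss F-bounds; Cicchetti labels
(< 0.40 poor, 0.40–0.59 fair, 0.60–0.74 good, ≥ 0.75 excellent).
Consistency ICC ignores additive shifts between methods by design. The
error mean square is clamped at zero against floating-point cancellation
when the two columns agree exactly; zero between-subject variance makes
the ICC undefined and is an error. No installed package provides this
estimator, so it is implemented here and pinned, in the tests, to a
brute-force double-loop ANOVA oracle at 1e-10.

**Spearman, Mann–Whitney, Shapiro–Wilk.** These standard tests are
delegated to `stats::cor.test`, `stats::wilcox.test` (exact enumeration
for small untied samples, normal approximation with tie and continuity
correction otherwise), and `stats::shapiro.test`, wrapped behind the
package's interfaces; the tests verify them against definitional
brute-force oracles (mid-rank Pearson formula, pairwise-comparison
count) rather than trusting the wrappers. Reported p-values are printed
as "< 0.0001" rather than 0.

**Rounding.** Reports round half-up to the precision conventional for
each quantity (integer percent for quartile shares, one decimal for the
Bland–Altman index and adequacy shares); all objects keep full
precision internally.

## The validation pipeline

`run_validation()` restricts the cohort to *completers* — respondents
present in FFQ1, FFQ2, and the record — and logs every exclusion by id;
filtering affects membership only, never any per-respondent score.
Validity pairs FFQ1 with the record, reproducibility FFQ1 with FFQ2.
Below 8 completers the run is refused (quartiles lose meaning); below
50 it warns, following the usual recommendation of 50–100 respondents
for FFQ validation. Supplement intake is out of scope by design — the
instrument assesses dietary intake only — and the 6-week retest interval
is study metadata the engine does not enforce. Rendering is
deterministic: identical inputs give byte-identical text, CSV, and JSON
output, plus Bland–Altman figures.

## The synthetic cohort generator

No respondent-level data are deposited for instruments of this kind, so
the generator is the package's test bed. It emulates:

* **right-skewed intakes**: per-respondent true group-level intakes are
  lognormal. Default medians (µg/day: fish 1.05 fresh + 0.35 products,
  meat 0.60, eggs 0.40, dairy 0.30, cereals 0.10, fats 0.10) follow the
  contribution profile observed for young-adult cohorts with low fish
  intake — fish dominant, cereals and fats minor — and give a median
  FFQ total near 3–4 µg/day, far below the 10 µg EAR;
* **the individualized key**: each respondent holds a latent preference
  of 1–2 products per fish question, shared across both
  administrations (whether real respondents keep their selections
  stable across administrations is unknown; the scoring engine itself
  permits them to differ);
* **measurement error**: multiplicative lognormal noise on item
  frequencies (intakes are positive and right-skewed, so additive
  Gaussian noise would be the wrong model), with FFQ1/FFQ2 log-errors
  correlated at `retest_correlation` through a shared-plus-idiosyncratic
  Gaussian construction;
* **record error and bias**: a respondent-level lognormal factor times
  `record_bias`; records under-capture irregularly eaten foods (fish
  above all), so the emulated study preset uses bias 0.58, placing the
  record median near 1.9 µg against an FFQ median near 3.3 µg;
* **dropout**: binomial at `dropout_rate` (default 0.4); non-completers
  keep FFQ1 but lack FFQ2 and the record. The emulated study preset
  instead fixes exactly 63 completers of 106 recruited, since those
  counts are facts of the emulated design, not draws.

Group intake is distributed over a group's items proportionally to each
item's resolved content (habit weight 1 for answerable items, 0 for
free-text items, whose content the generator has no source for); item
frequencies are then back-solved so that scoring the noise-free answers
reproduces the latent truth to floating-point accuracy — the generator
and scorer are exact inverses in the noise-free limit, which anchors the
end-to-end tests. What the generator does **not** emulate: day-to-day
intake autocorrelation within the 3-day record, seasonality, item-level
habit heterogeneity beyond content weighting, digit preference, and
recall bias structure. Passing tests therefore demonstrate the
correctness of the scoring and statistics machinery under a plausible
intake model, not the field performance of any questionnaire.

## Problem sizes and tolerances

The suite exercises: oracle equivalence on 100 random instances of
n ≤ 20 at 1e-10; noise-free end-to-end perfection at n = 30; parameter
recovery of the median at n = 2000 against a 50 000-draw Monte-Carlo
oracle within 5 %; retest-correlation propagation at n = 2000 against a
20 000-draw error-model prediction within ±0.05; Bland–Altman coverage
at n = 10 000 within 95 ± 1 %; and the emulated study preset across 12
seeds for the calibration bands (FFQ1 median 2.5–4.5 µg, record
1.2–2.8 µg, record below FFQ). These sizes were chosen to make the
stochastic checks sharp while keeping the default test run fast.

## Known limitations

* Single-nutrient by design; no multi-nutrient keys.
* Two raters/administrations only — the agreement battery does not
  generalize to k > 2 repeated measures.
* The quantile convention and tie-break for quartile cuts are
  documented choices; other software may bin ties differently, so
  cross-classification counts are reproducible but not guaranteed
  identical across tools.
* Bland–Altman results are reported on both scales because published
  reports are often ambiguous about whether mean difference and limits
  are natural or log quantities; the pipeline defaults to log and
  labels the scale explicitly.
* Household measures are documentation only; no portion-size estimation
  is attempted.
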