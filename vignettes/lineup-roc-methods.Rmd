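---
title: "Methods: ROC, reliability-curve and signal-detection analysis of lineup data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROC, reliability-curve and signal-detection analysis of lineup data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineupROC)
```

## The data structure

The unit of analysis is the lineup outcome table: counts of each response
category at each confidence level, separately for target-present (TP) and
target-absent (TA) six-member simultaneous lineups. TP lineups admit suspect
identifications, filler identifications and rejections ("no ID"); TA lineups
in a design without a designated innocent suspect admit only filler IDs and
rejections — a TA "suspect ID" is undefined and the validators treat it as an
error. Rejection confidence is retained in the data model even though the
ROC and CAC analyses use only identification responses, because the packaged
study tabulates it and the simulator reproduces it.

The packaged fixture (`vo_counts()`) holds the four cells of a large
verbal-overshadowing study — young (18–30) and older (60+) witnesses, each
under a perpetrator-description (experimental) or control task — with 250 TP
and 250 TA lineups per cell and confidence on a 1–7 scale.

## Rate estimators and condition comparisons

The correct ID rate divides TP suspect IDs by the number of TP lineups. The
false ID rate must be *estimated* in a no-designated-suspect design: each TA
filler ID is divided by the lineup size k = 6, because any one of the k
fillers would have stood in for an innocent suspect with equal probability.
Condition contrasts on correct IDs and on TA false alarms use the Pearson
chi-square on the 2×2 table (outcome vs remainder, per condition) *without*
continuity correction — the variant that reproduces the study's four printed
statistics to four decimals — with two-sided p from the χ²(1) distribution.

## Confidence binning

Extreme confidence ratings are rare, so analyses pool the scale into four
bins — low (1–3), medium-low (4), medium-high (5), high (6–7) — the default
scheme of `default_bins()`. Binning only ever sums counts: lineup totals are
conserved, and any ordered partition of 1..7 is accepted. For response-time
analyses the default half-open bins are < 6 s, [6, 12) s, [12, 18) s and
≥ 18 s; a value exactly on an edge falls in the upper bin. That boundary
convention is a package decision (the edge treatment is not otherwise
determined) — it is stated so it can be tested. When a bin holds too few
identification responses for stable bootstrap intervals,
`rebin_on_sparsity()` merges each sparse bin with its smaller neighbour
until every bin holds at least `min_count` responses; the default
`min_count = 10` is a package choice, since the original re-binning was
driven by bootstrap infeasibility without a stated threshold.

## ROC construction and pAUC inference

The ROC accumulates (estimated false ID rate, correct ID rate) pairs from
the strictest confidence bin to the most lenient, with an anchor at the
origin — the operating point of a witness who never identifies anyone. The
rightmost point is the overall pair of rates. Discriminability comparisons
integrate both curves from 0 to a shared cutoff: the rightmost false-ID rate
of the more conservative condition (the smaller of the two rightmost x
values; ties are immaterial). Integration is trapezoidal with linear
interpolation when the cutoff falls inside a segment. If a caller supplies a
cutoff beyond a curve's rightmost point, the final segment is extended
linearly and the result is flagged `extrapolated` — the conservative-cutoff
rule exists precisely to avoid relying on that, but bootstrap replicates of
the conservative condition can shift its rightmost point slightly below the
fixed cutoff, so the extension keeps the replicate statistic defined.

The test statistic is Z = (pAUC₁ − pAUC₂) / sd(pAUC₁\* − pAUC₂\*). The
denominator is the standard deviation of the difference across paired
bootstrap replicates: within each condition, TP and TA lineups are resampled
independently at the trial level (a multinomial draw over the
outcome-by-confidence categories), the curve is rebuilt and the pAUC
recomputed at the *fixed* cutoff. Replicates are paired by index but the two
conditions use independent RNG streams. The two-sided p comes from the
standard normal. 10,000 replicates are the study's setting and the package
default; a zero bootstrap variance (degenerate tables) is reported as an
infinite-Z guard rather than silently.

Published pAUC point values for these data are not exactly recoverable from
the printed frequency table under any stated anchoring convention (the
original analysis tool's interpolation conventions are not published), so
the package treats point pAUCs as convention-dependent: its regression
contract is the inferential pattern — the age contrast significant with
young above older, both description contrasts non-significant — together
with the sign and ordering of the point estimates, all of which reproduce.

## CAC and RAC

Per confidence bin (CAC) or RT bin (RAC), suspect-ID accuracy is
CID / (CID + FID/k), reading k from the table rather than hard-coding 6.
Bins with no identification responses are *undefined* (NA with a warning),
never zero. Intervals are percentile bootstrap at 68% — the bootstrap
analogue of ± 1 SE — from independent TP/TA resampling; a bin empty in more
than half the replicates is flagged `unstable`. Following the graphical
practice of CAC/RAC analysis, differences are judged by the non-overlap of
error bars (`bars_overlap()`), deliberately exposed as a predicate and not
as a p-value. A consistency property ties modules together: each CAC bin
equals the positive predictive value implied by the increments between
consecutive ROC points under the same binning.

## The signal-detection model

The independent-observations equal-variance model: lure strengths are
N(0, 1) (fixing the scale), the target is N(μ_t, 1), each lineup member
draws independently, and the maximum is identified iff it exceeds c₁. The
category probabilities are

- TP suspect ID above c: ∫_c^∞ φ(x − μ_t) Φ(x)^(k−1) dx
- TP filler ID above c: (k−1) ∫_c^∞ φ(x) Φ(x)^(k−2) Φ(x − μ_t) dx
- TA any ID above c: 1 − Φ(c)^k (closed form)

with band probabilities as differences between successive criteria.
Integrals use `stats::integrate` truncated at μ_t + 10σ with absolute
tolerance 1e-8; tiny negative differences from quadrature noise are clamped
at zero before the likelihood sees them.

Fitting maximises the multinomial log-likelihood (TP and TA blocks summed)
over μ_t and the criteria; the likelihood objective is a package decision —
the original description names the model but not the objective — and a
minimum-Pearson-chi-square objective is available behind
`objective = "chisq"` for sensitivity checks. Rejection confidence is
collapsed in the likelihood: the ROC analyses the model supports use only
identification responses, and modelling rejection-confidence criteria would
add parameters the supported analyses never consume. Criteria are optimised
as (c₁, log-increments) to preserve strict ordering; initial values come
from the empirical cumulative TA ID rates through the inverse of
1 − Φ(c)^k, and the optimiser (Nelder–Mead) restarts from three jittered
initialisations under a fixed seed. d′ = (μ_t − μ_l)/σ_l is defined only in
the equal-variance mode; unequal-variance fits are directed to the d_a
family, which this package does not implement. Goodness of fit is reported
as a Pearson chi-square against fitted expected counts with
df = cells − parameters − 2 (one constraint per multinomial block).

## The simulator and what it does (not) emulate

`simulate_trials()` makes the analysis assumptions executable: strengths are
drawn per the model above, the max rule assigns response and confidence (7
identification criteria map onto the 1–7 scale), and rejection confidence
comes from thresholds below c₁ — the further the maximum falls below c₁, the
more confident the rejection. Response times follow a lognormal model,
rt = exp(log(base) − slope·|max − c₁| + ε), ε ~ N(0, σ²): decisions made on
stronger evidence margins are faster. This RT model is a package invention —
the RAC analysis assumes a fast-accurate structure but no generative RT
model is published — with defaults (base 10 s, slope 0.7 per strength unit,
σ = 0.4) chosen once so that simulated records reproduce the qualitative
falling RAC and populate all four default RT bins at realistic proportions.

Default generating parameters (`default_sim_params()`: μ_t = 2, criteria
1.5, 1.8, …, 3.3, k = 6, 250 lineups of each type) were chosen to land near
the untreated control cell of the packaged study (≈ 0.6 correct ID rate,
≈ 1/3 of TA lineups producing a filler ID). The simulator emulates outcome
*structure* only: it has no witness covariates, no own-age effects, no
verbal-description content, and its RT distribution is a convenience. Tests
that pass on simulated data therefore validate the estimators' internal
consistency under the model's assumptions, not the model's fidelity to any
real witness population.

## Power analysis

`power_analysis()` mirrors the planning pipeline: per sample size and
replicate, simulate both conditions, tabulate, bin, take the conservative
cutoff, compute pAUCs, bootstrap the SE of the difference (2,000 replicates
in the planning configuration) and count two-sided rejections at α = 0.05.
With identical generating parameters this measures type-I calibration; the
package checks it at n = 100 lineups per cell with 500 bootstrap replicates
and 200 simulation replicates — sizes at which the whole calibration runs in
seconds while the binomial Monte-Carlo error (±3 SE ≈ ±0.046) is tight
enough to detect gross miscalibration. Degenerate replicates (no
identifications in a condition) are skipped and counted. Every replicate
derives an independent child seed from the caller's seed via a Lehmer step,
so results are reproducible and stages are independent.

## Numerical and degenerate-input conventions

- Binning validates an exact partition of 1..7; non-partitions are errors.
- A table with no identifications yields a flagged single-point ROC; the
  conservative cutoff with such a curve is 0 and pAUC comparison refuses it.
- Zero bootstrap variance warns (pAUC) or yields zero-width intervals (CAC).
- Chi-square with a zero marginal is an error, not NaN.
- `-Inf` log-likelihood (zero predicted probability with observed counts)
  carries a diagnostic message attribute and large finite penalties steer
  the optimiser away from it.

## Known limitations

- No unequal-variance d_a reporting and no model-comparison machinery for
  choosing between variance structures.
- No joint confidence-by-RT analysis; CAC and RAC are marginal curves.
- The bootstrap treats lineups as exchangeable trials; no witness-level
  clustering is modelled (each witness saw one lineup in the packaged
  study, so the two coincide there).
- pAUC point values are convention-dependent near the cutoff; comparisons
  across software should fix the anchoring and interpolation rules first.

## Package shape

The package exposes its computations as ordinary functions plus the numbered
driver scripts under `analysis/`, which reproduce the full results sequence
and write tables under `results/`; `reproduce_analysis()` bundles the same
sequence into one call. This analysis-workflow shape, rather than a shell
CLI, fits how the package is used: against a fixed packaged dataset or
programmatically against a user's own tables.
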