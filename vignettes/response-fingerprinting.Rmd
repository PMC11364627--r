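---
title: "Response-type fingerprinting of Likert questionnaires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response-type fingerprinting of Likert questionnaires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resptyper)
```

## The model

A questionnaire is eight integer ratings on a 1–5 Likert scale: five main
drivers of global biodiversity loss and three distractor ("minor") drivers.
The analysis assumes the population of questionnaires is a finite mixture of
a small number of *response types* — characteristic rating patterns shared
across countries — and that a country is characterised not by a typical
questionnaire but by its *fingerprint*: the proportion of its respondents
falling into each type. Clustering questionnaires first makes the country a
derived, second-level quantity, so no multivariate-normality or sampling
assumptions (of the kind factor-analytic pipelines require) are imposed on
the raw ratings.

The pipeline is: KNN imputation → feature engineering → jitter → Ward
clustering with gap-statistic model selection → profiles → fingerprints →
country dendrogram → Spearman screen against country indices.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `n_neighbors` | 8 | questionnaires | neighbourhood size for imputing a missing item; 8 averages away single-neighbour noise without reaching into unrelated response patterns |
| `jitter_variance` | 0.001 | squared Likert points | just enough to break exact duplicates (common in coarse Likert data, and fatal to some agglomerative implementations) while moving each point by ~0.03 — far below the 1-point item resolution |
| `k_range` | 2–12 | types | brackets any plausible type count for an 8-item instrument; `k = 1` remains available in the API |
| `B` | 50 | reference datasets | gap-statistic Monte-Carlo size; the simulation error term `s_k` carries the `sqrt(1 + 1/B)` correction |
| `min_country_n` | 25 | respondents | a fingerprint is a vector of proportions; below ~25 its binomial noise per component exceeds ±0.1 and between-country distances become noise |
| `missing_rate` | 0.02 | fraction | generator default, a typical online-survey item non-response level |

## Numerical and design choices

**Imputation distance.** Closeness of two questionnaires uses only items
both observed, rescaled by `sqrt(8 / #co-observed)` so that a pair sharing
two items is not automatically "closer" than a pair sharing eight.
Equidistant neighbours are broken by lower row index, making the step
deterministic; imputed values are left continuous rather than re-rounded.
Imputation runs on the eight raw items, before feature engineering.

**Feature engineering.** The three minor items are collapsed into the
discrimination score `D = mean(main) − mean(minor)`. With 1–5 items `D`
lies in `[−4, 4]` and is generally non-integer. `D` shares the scale of the
items, so no standardisation is applied before clustering — the six
coordinates are deliberately left commensurable.

**Profiles on un-jittered features.** The jitter exists to break
duplicates, not to change summaries, so cluster profiles (means ± SD per
item and for `D`) are computed on the features before perturbation;
only the clustering itself sees the jittered data.

**Model selection.** The gap statistic compares observed log within-cluster
dispersion against `B` reference datasets drawn uniformly over each
feature's observed range (the simplest published reference). Selection uses
the one-standard-error rule — smallest `k` with
`gap(k) ≥ gap(k+1) − s(k+1)` — and falls back to the argmax of the curve
when no `k` qualifies; the full curve is always returned so an elbow can be
read off directly. Ward linkage is the greedy minimum-increase-in-SSE
agglomeration; the test suite verifies it against exhaustive agglomeration
on small point sets.

**Profile ordering and matching.** Recovered profiles are ordered by
descending discrimination (ties by climate-change mean), a deterministic
convention; any correspondence to an external numbering is established by
globally optimal assignment (minimum total centroid distance, solved
exactly by dynamic programming over column subsets — never greedily).

**Spearman screen.** Average ranks for ties; two-sided p from the
t-approximation with `n − 2` degrees of freedom; an exact permutation p is
available for `n ≤ 9` as an audit tool (the approximation is coarse at the
very smallest n and agrees with the exact p to 0.02 by n = 9; the screen
itself runs at n = 37 countries where the approximation is accurate). The flag rule is `|r| > 0.3` (moderate) and `p ≤ 0.05`
(significant), with the boundary `p = 0.050` counting as significant. No
multiple-testing correction is applied by default, preserving the screening
character; Benjamini–Hochberg is available behind a flag.

## What the synthetic generator emulates — and what it cannot

`generator_config()` defaults encode the study conditions: the eight
published response-type profiles (packaged as `load_fixture("table2")`),
4000 respondents (an equal mixture, 500 per type), 2% MCAR missingness.
Items are drawn independently within a type from Gaussians discretised onto
the 1–5 grid and moment-matched to the profile's printed mean (to within
0.01) and SD; the three minor items share one distribution with mean
`mean(main means) − discrimination` and the discrimination SD, since no
per-minor-item parameters are published. Synthetic country indices are
generated through a Gaussian-copula rank blend whose latent Pearson
parameter `2·sin(πρ/6)` makes the population Spearman correlation equal the
target.

Two real-data features are deliberately not emulated: within-type
*correlation between items* (the generator draws items independently), and
any non-MCAR missingness mechanism.

The independence choice has a consequence worth stating plainly. The printed
profile SDs are within-cluster SDs of a *hard partition* of the real data;
reproducing them as marginal SDs of independent coordinates produces
ellipsoidal type clouds that overlap substantially more than the real
partition's cells. Under the generator's own true model, the Bayes-optimal
classifier assigns only about 88% of respondents to their generating type
(the test suite computes this ceiling directly from the posterior under the
generating model), so *no* clustering method can recover the generating
labels much beyond that on these populations, and the gap curve
on them rises without a clear local maximum at `k = 8`. Passing pipeline
tests on this generator therefore demonstrate correct mechanics —
imputation, clustering, selection rule, fingerprinting, screening — and
well-separated-mixture recovery (checked with synthetic Gaussian blobs);
they do not certify that eight types would be re-discovered from data this
overlapping, and conversely the types' recovery in the real study suggests
its within-type structure is tighter than independent marginals imply.

## Problem sizes

The packaged checks run at desk scale: recovery uses five seeded replicates
of the default 4000-respondent population with `B = 50` gap references over
`k = 2..12` (a few minutes in total); oracle tests use exhaustive
agglomeration on ≤ 7 points and exact permutation p on ≤ 9 observations;
calibration tests use 1000 replicates at the study's 37 countries.

## Known limitations

- Ward + gap statistic inherits the gap statistic's known conservatism for
  overlapping, non-spherical mixtures; the emitted curve should be
  inspected, not just the selected `k`.
- Fingerprint comparisons treat countries as fixed groups; no uncertainty
  is propagated from cluster assignment into fingerprint distances.
- The correlation screen is exploratory: 40 unadjusted tests at `n = 37`
  imply ≈ 2 false flags under global independence.
- Imputation assumes missingness unrelated to the unobserved rating (MCAR
  at the mechanism level); with informative non-response the imputed means
  are biased toward observed respondents.
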