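# resptyper

Response-type fingerprinting of Likert questionnaires on the drivers of
global biodiversity loss.

## The problem

Cross-country questionnaire studies face a latent-group problem: the same
answer pattern occurs in many countries, so predicting the country from the
answers is hopeless, yet the country plainly shapes how answers distribute.
`resptyper` implements the two-level alternative: first cluster the
*questionnaires* into a small number of **response types** (no country
information used), then describe each *country* by its **fingerprint** — the
vector of proportions of each response type among its respondents — and do
all between-country statistics on fingerprints.

The concrete instrument is a survey in which respondents rate, on a 1
("minor impact") to 5 ("major impact") Likert scale, how strongly eight
presented drivers contribute to the decline of global biodiversity: the five
established main drivers (habitat loss, overexploitation, pollution, climate
change, invasive species) and three distractor "minor" drivers with
negligible global impact (electromagnetic pollution, factory and vehicle
noise, the internet). A ninth presented item, entering nature reserves, is
excluded from all analysis.

## The method

For respondent *i* with main-item ratings *x₁…x₅* and minor-item ratings
*y₁…y₃*:

1. **Imputation.** Missing items are imputed by the unweighted mean of the
   item over the 8 nearest questionnaires observing it, with distance
   `d(u, v) = sqrt(8 / |C|) * sqrt(Σ_{j∈C} (u_j − v_j)²)` over the
   co-observed item set *C*.
2. **Feature engineering.** The minor items are replaced by the
   discrimination score `D = mean(x) − mean(y)` (range −4…4), giving a
   6-dimensional feature vector `(x₁,…,x₅, D)`.
3. **Jitter.** i.i.d. Gaussian noise, mean 0, variance 0.001, per
   coordinate, so duplicated questionnaires become distinct.
4. **Clustering.** Ward's minimum-variance agglomeration on the jittered
   features; the number of types *k* is chosen by the gap statistic
   `gap(k) = (1/B) Σ_b log W_k(ref_b) − log W_k(data)` with uniform
   reference draws over the observed feature ranges and the
   one-standard-error selection rule (argmax fallback).
5. **Fingerprints.** Country *c*'s fingerprint entry *i* is the share of
   its respondents in type *i*; countries under 25 respondents are
   excluded. Countries are compared by Euclidean fingerprint distance and a
   Ward dendrogram (Newick export).
6. **Screen.** Each fingerprint component is correlated with five country
   indices (CO₂ emissions, Environmental Performance Index, Global
   Biodiversity Index, number of invasive species, Legatum Prosperity
   Index) by Spearman rank correlation; cells with `|r| > 0.3` and
   `p ≤ 0.05` are flagged.

A synthetic-data module generates questionnaire populations with exactly
the mixture structure this analysis assumes — respondents drawn from the
eight published response-type profiles (shipped as a fixture), items drawn
from discretised Gaussians moment-matched to the printed means and SDs,
MCAR missingness, and synthetic indices with target rank correlations — so
every stage is testable at desk scale.

## Worked example

```r
library(resptyper)

# simulate a two-country population: types 3 and 7 in opposing 80/20 mixes
cfg <- generator_config(
  country_fingerprints = list(AAA = c(0, 0, .8, 0, 0, 0, .2, 0),
                              BBB = c(0, 0, .2, 0, 0, 0, .8, 0)),
  n_per_country = c(AAA = 150, BBB = 150), missing_rate = 0.02, seed = 77)
paths <- simulate_study(cfg, "demo")

res <- run_pipeline(pipeline_config(paths$responses, out_dir = "demo/run",
                                    B = 15, seed = 909), k = 2)
res$fingerprints
#> Fingerprints: 2 countries x 2 response types
#>     type_1 type_2
#> AAA  0.313  0.687
#> BBB  0.793  0.207
res$profiles[, c("type_id", "invasive_species_mean", "discrimination_mean", "size")]
#>   type_id invasive_species_mean discrimination_mean size
#> 1       1              1.271837           1.0256024  166
#> 2       2              2.732276          -0.4000622  134
```

Recovered type 1 (invasive species rated 1.27, positive discrimination) is
the published type-7 pattern and dominates country BBB; recovered type 2
(uniformly low ratings, discrimination near zero) is the type-3 pattern and
dominates AAA — mirroring the opposing generating mixtures. `demo/run/`
holds the profiles, fingerprints, distance matrix, Newick tree and run log
as files.

On the shipped printed screen, the flag rule reproduces the published
highlighting:

```r
tab3 <- load_fixture("table3")
sum(sapply(c("CO2","EPI","GBI","NIS","LPI"), function(nm)
  sum(flag_cells(tab3[[paste0(nm,"_r")]], tab3[[paste0(nm,"_p")]])$flagged)))
#> [1] 15
```

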