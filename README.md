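# bymtrends

Small-area estimation of health-survey indicator **levels and trends** at
the administrative-block scale. When a survey panel gives each block only a
few dozen respondents per round, raw block proportions are too noisy to
compare or map; `bymtrends` smooths them with the Besag–York–Mollié (BYM)
spatiotemporal model, tests whether trends genuinely differ between blocks,
and classifies each block's trend with a controlled error rate. It is
aimed at analysts of repeated subnational surveys (district/block health
monitoring, program evaluation panels) who need defensible block-level
trend maps rather than raw cross-tabs.

## The model

For block *i* at round time *t* (years since the first round):

```
eta_it = alpha + beta * t + u_i + v_i [+ delta_i * t]

binary:  y_it ~ Binomial(n_it, logit^-1(eta_it))
count:   y_it ~ Poisson(n_it * exp(eta_it))
```

* `u` — spatially structured block effects with an intrinsic CAR (ICAR)
  prior on the block contiguity graph (precision matrix `Q`: degree on the
  diagonal, −1 between neighbours, zero row sums);
* `v` — unstructured iid heterogeneity;
* `beta` — the state-average trend; `exp(beta)` is the average odds (or
  rate) ratio per year;
* `delta_i` — optional per-block trend deviations ("space–time
  interaction"); `exp(beta + delta_i)` is block *i*'s trend ratio per year.

Models with and without `delta` are fitted by a bespoke adaptive
Metropolis-within-Gibbs sampler (Rcpp) and compared by DIC
(`DIC = Dbar + pD`, lower wins). Block trends are summarised from 10,000
posterior resamples of `beta + delta_i` and classified by the
97.5%-probability rule: a 95% credible interval entirely above 1.0 is an
`increase`, entirely below is a `decrease`, anything else
`indeterminate`. Blocks with no respondents are carried through the model
and imputed from their neighbourhood. A synthetic-data generator with
known truth (ICAR field, heterogeneity, trend deviations, survey-scale
denominators, missing blocks) backs all verification.

See `vignettes/bym-spatiotemporal-trends.Rmd` for the full account of the
model, priors, sampler, and limitations.

## Worked example

A 6 × 6 block map, one binary indicator with genuinely opposite block
trends (state-average OR 1.0, per-block trend deviations sd 0.4):

```r
library(bymtrends)

graph <- make_lattice(6, 6)
truth <- scenario("opposite_trends", n_range = c(80L, 80L))
sim   <- generate_dataset(graph, truth, seed = 7, indicator_id = "flw_visit")

fit0 <- fit_bym(sim$dataset, graph, model_spec("binary", FALSE), seed = 11)
fit1 <- fit_bym(sim$dataset, graph, model_spec("binary", TRUE),  seed = 12)
sel  <- select_model(fit0, fit1)
sel$dic_table
#>            model     dbar       pd      dic
#> 1 no_interaction 772.0620 33.63084 805.6928
#> 2    interaction 695.1978 49.81442 745.0122
```

The interaction model wins by ~61 DIC points — correct, since the data
were generated with block-specific trends. Trend estimates and the
97.5%-probability classification:

```r
trends <- block_trends(sel$chosen, resamples = 10000, seed = 13)
head(trends, 3)
#>   block_id  or_point        lo       hi      category
#> 1     r1c1 1.4497100 1.0602240 2.028774      increase
#> 2     r1c2 0.8201746 0.6600491 1.021962 indeterminate
#> 3     r1c3 0.8843692 0.7236081 1.095931 indeterminate

summarize_indicator(trends, sel)
#>   indicator_id interaction_selected dic_no_int  dic_int n_increase n_decrease
#> 1    flw_visit                 TRUE   805.6928 745.0122          7          4
#>   n_indeterminate   or_min   or_max
#> 1              25 0.549609 1.451932
```

Row 1: block `r1c1`'s odds of the indicator rise an estimated 45% per year
(95% CrI 1.06–2.03); since the whole interval is above 1.0, the block has
≥ 97.5% posterior probability of a genuine rise. Across the map, 7 blocks
are confidently rising and 4 confidently declining; every block called
`increase` or `decrease` here is correctly signed against the generating
truth, and no flat block is miscalled:

```r
table(truth = sign(sim$truth$true_or - 1), called = trends$category)
#>      called
#> truth decrease increase indeterminate
#>    -1        4        0            12
#>    1         0        7            13
```

The `analysis/` scripts run the same workflow at full scale: a 534-block
map, four survey rounds, denominators 19–123, four indicators covering a
universal rise, opposite trends, a count indicator without interaction,
and a map with missing blocks (`01_simulate.R`, `02_fit.R`,
`03_report.R`; summary tables land in `results/analysis/`).

Real data enter the same way: an observation CSV
(`indicator_id,family,block_id,round,y,n`, or per-respondent
`count,max_count` rows for count indicators) plus either a GeoJSON of
block polygons or a `block_a,block_b` edge-list CSV, wired through a YAML
config for `run_all()`.

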