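# emoconsensus

Consensus annotation, validation, and physiological noise regressors for
continuous emotion ratings of naturalistic film stimuli.

## The problem

Continuous affect annotation asks several raters to move a slider (0–100,
sampled at 1 Hz) while watching a film, once per emotion *item* — appraisal,
motivation, expression, physiology and feeling dimensions plus discrete
emotion terms. Individual raters differ in scale use (gain and offset), in
noise level, and occasionally in kind: flat traces, extreme spikes, or
ratings that track something other than the shared response. Downstream
analyses (e.g. relating ratings to fMRI) need a single reliable *consensus*
time series per film × item, together with an honest account of which
raters were excluded and why.

`emoconsensus` implements that pipeline for R users:

1. **Normalisation** — each rater's series for an item is z-scored across
   that rater's films (pooled mean, population SD), removing gain and bias
   while preserving between-film level differences.
2. **Screens** — isolated missing samples are imputed from their two
   neighbours; constant series and series with samples beyond |z| = 15 are
   discarded.
3. **Agreement** — for each film × item, Pearson's r over all rater pairs,
   averaged: with raters modelled as `x_i = s + ε_i`,
   `E[r] = σ_s² / (σ_s² + σ_n²)`.
4. **Exclusion cascade** — a series whose removal raises the remaining
   raters' mean pairwise r by more than 0.20 is discarded (greedy,
   iterated), but never below 3 survivors; where five annotations exist,
   the one with the lowest mean correlation to the others is dropped.
5. **Reliability gating** — items with mean agreement across films below
   0.15 are removed (below 0.20 flagged unreliable); films below 0.25
   across items are removed.
6. **Consensus** — the pointwise mean of the surviving z-scored series
   (n ≥ 3), with a fully reconciled exclusion ledger.

Two companion components round the pipeline out:

* **Clip validation** — sparse post-hoc clip ratings (≈21 clips/film, mean
  7 s) are anchored at clip midpoints, linearly interpolated to 1 Hz,
  z-scored, averaged over 3–4 subjects and correlated with the consensus;
  an item-level meta-correlation relates validation to inter-rater
  agreement.
* **Physiological regressors** — raw cardiac-pulse and respiration traces
  (1000 Hz) are downsampled to 40 Hz, low-pass filtered (8 / 2 Hz), peaks
  detected with a prominence + refractory rule, and turned into
  heartbeat-interval (sliding 6 s median of inter-beat intervals, convolved
  with the negated cardiac response function) and respiratory-variance
  (sliding 8 s variance convolved with the respiratory response function)
  nuisance regressors for fMRI.

A synthetic-data module generates annotation studies, clip ratings and
quasi-periodic physiology with exactly the structure the pipeline assumes,
so everything is testable without downloading data.

## Worked example

```r
library(emoconsensus)

cfg <- simulation_config(
  films = default_film_table()[1:4, ],
  items = sprintf("item%02d", 1:12),
  target_agreement = 0.39,
  contamination_rates = c(constant = 0.02, outlier = 0.05, deviant = 0.08),
  seed = 5
)
study <- simulate_annotation_study(cfg)
length(study$series)
#> [1] 192

res <- run_consensus_pipeline(study$series)
table(res$ledger$status)
#>  deviant survivor
#>       14      178

head(res$agreement, 3)
#> # A tibble: 3 × 4
#>   film_id item_id mean_r n_raters
#>   <chr>   <chr>    <dbl>    <int>
#> 1 film01  item01   0.397        4
#> 2 film01  item02   0.368        3
#> 3 film01  item03   0.382        3

res$gating$films_removed
#> [1] "film01"
res$gating$items_removed
#> [1] "item09" "item10"

res$consensus[[1]]
#> <consensus_series> film=film02 item=item01 [808 s, 4 raters, mean level -0.000]

counts <- table(res$ledger$status)
reconcile_ledger(nrow(res$ledger),
                 counts[setdiff(names(counts), "survivor")], n_combos = 48)
#> $survivors
#> [1] 178
#> $combos_with_three
#> [1] 14
#> $combos_with_four
#> [1] 34
```

This run planted two deviant raters among eight. The cascade removed 14 of
their series outright (the ledger reconciles: 178 survivors over 48
combinations means 14 three-rater consensus series); the items and the film
where the residual deviants depressed agreement below the reliability gates
were removed from the consensus set, leaving 30 consensus series.
`write_consensus(dir, res$consensus)` writes one TSV per film (one column
per item) plus a JSON sidecar with the rater counts and exclusion history.

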