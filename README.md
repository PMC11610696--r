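# benthind

Systematic evaluation of benthic state indicators along anthropogenic
pressure gradients, for benthic ecologists and the advisory bodies that
select seabed-integrity indicators.

Soft-sediment monitoring programs can compute many community state
indices; they rarely agree on which. `benthind` computes 18 of them per
station — whole-community biomass `B` and abundance `A`; richness `R`,
relative Margalef `DM`, Shannon `H`, Simpson `SI`, inverse Simpson `IS`;
the group-based biotic indices `AMBI`, `MAMBI`, `BENTIX`, `DKI`; and the
trait-based `TDI`, `mTDI`, `mT`, median longevity `Lm`, `pTDI`, `SoS`,
long-lived fraction `Lf` — and then evaluates the suite on three axes:

* **Complementarity**: Spearman correlations between indicators within
  each bottom-trawl gradient, averaged across gradients and ordered by
  Ward clustering on `d = 1 − ρ̄`, to expose redundant versus
  complementary indicators (a diversity-driven and a trait-driven
  group).
* **Sensitivity**: per gradient, a contrast of low-trawling (swept-area
  ratio SAR < 0.35/yr) against high-trawling (the five most fished
  stations with SAR > 1/yr) station groups, expressed as the log
  response-ratio `lnRR = ln(I_trawled / I_control)` and pooled across
  gradients by inverse-variance random-effects meta-analysis (REML τ²,
  via metafor), overall and per sampling gear; plus a per-gradient OLS
  trend on `log10(SAR + 1)` classified against an intercept-only null
  by AIC (`decline` / `increase` / `no_effect`).
* **Specificity**: the same AIC classification with a penalized-spline
  GAM for non-trawl gradients (eutrophication, oxygen depletion,
  pollution), with the worsening direction of each pressure axis
  handled explicitly.

Indicators whose raw form scores high in degraded communities (AMBI,
mT, Simpson dominance) are orientation-reversed before analysis, so a
decline is the expected trawling response everywhere.

A seeded synthetic-data module (`make_species_pool()`,
`simulate_gradient()`, `simulate_nontrawl_gradient()`,
`simulate_study()`) generates multi-gradient studies with the
statistical structure these analyses assume — trait-targeted depletion,
opportunist compensation, station-level habitat heterogeneity,
overdispersed counts — so the whole pipeline runs and is tested with no
external data. Everything is tidy: data frames in, tibbles out, with
`tidy()`/`glance()` accessors and `autoplot()` methods (correlation
heatmap, forest plot, effect matrix).

## Worked example

```r
library(benthind)

res <- run_full_comparison(seed = 1)
res
#> <benthic_run> seed 1 - 17 gradients, 238 stations
#> cluster order: Lf Lm SoS AMBI BENTIX pTDI TDI mTDI mT B A R DM H SI IS MAMBI DKI

pooled <- tidy(res$meta)
subset(pooled, subgroup == "all" &
              indicator %in% c("SoS", "Lf", "B", "A", "H"))
#> # A tibble: 5 × 9
#>   indicator subgroup     k estimate     se    ci_lb   ci_ub     tau2 significant
#>   <fct>     <chr>    <int>    <dbl>  <dbl>    <dbl>   <dbl>    <dbl> <lgl>
#> 1 B         all         13  -0.203  0.0894 -0.378   -0.0279 0.0516   TRUE
#> 2 A         all         13   0.130  0.0703 -0.00809  0.267  0.0104   FALSE
#> 3 H         all         13  -0.0199 0.0157 -0.0507   0.0108 0.000919 FALSE
#> 4 SoS       all         13  -0.265  0.0657 -0.394   -0.136  0.0313   TRUE
#> 5 Lf        all         13  -0.344  0.127  -0.592   -0.0953 0.148    TRUE
```

Read: across 13 evaluable trawl gradients, the sensitive-biomass
indices decline most (`SoS` −0.27, `Lf` −0.34 on the log scale, i.e.
23% and 29% lower at heavily fished stations, both with 95% CIs
excluding zero), whole-community biomass declines moderately (−0.20),
Shannon diversity barely moves, and total abundance *rises* (+0.13) —
opportunists more than compensate for the sensitive taxa lost. The
cluster order puts the trait-driven indicators (`Lf` `Lm` `SoS` …
`mT`) and the diversity-driven ones (`R` `DM` `H` `SI` `IS` `MAMBI`
`DKI`) in separate blocks: pick at least one from each group.

Per-gradient trend classifications and decline shares:

```r
glance(res$trawl_effects)      # % of gradients declining per indicator
autoplot(res$meta)             # forest plot
autoplot(res$avg, order = res$ward$order)  # correlation heatmap
```

`run_full_comparison(out_dir = "...")` writes every result table as
tidy CSV plus a JSON run manifest; `write_fixtures()` emits the CSV
schemas (`samples.csv`, `stations.csv`, `traits.csv`) that
`read_samples()`, `read_stations()` and `read_traits()` ingest, so the
same pipeline runs on field data.

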