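# ecostab

Quantitative assessment of ecological restoration on reclaimed open-pit
mine refuse dumps, built around a chronosequence design: restoration
sites of different ages plus an undisturbed natural reference per mine,
sampled once, with vegetation censuses and soil properties per plot.

It is written for restoration ecologists and reclamation practitioners
who need more than "did diversity go up": the core statistic is an
**entropy-weighted coupling-coordination index of ecological stability**
that scores how well the vegetation and soil subsystems recover
*together*.

## The model

For the sites of one mine, plant community characteristics (SP, NP,
Shannon–Wiener H′, Simpson D, Pielou J, Margalef Mg) and soil properties
(SMC, BD, pH, TS, OM, TN, AN, AP, AK) are min–max standardized to [0, 1]
(reversed for cost indicators: pH, bulk density) and combined with
entropy weights into subsystem composites

f(x) = Σ aᵢ xᵢ,  f(y) = Σ bⱼ yⱼ.

The coupling index, development level and stability score are

C = 4 f(x) f(y) / (f(x) + f(y))²,  T = α f(x) + β f(y),  D = √(C·T),

with α = β = 0.5. D is banded into five stability categories
(extremely unstable → stable, in steps of 0.2) and the development ratio
f(x)/f(y) into vegetation-lagging (> 1.2), soil-lagging (< 0.8) or
synchronous sub-categories. Around that core the package provides the
full supporting pipeline: diversity indices, ANOVA + Tukey HSD compact
letter displays, a from-first-principles redundancy analysis with a
499-permutation Monte Carlo test and reference-distance trajectories,
logistic succession fits D(t) = K/(1 + a·e^(−rt)), and a synthetic
chronosequence generator with known latent recovery for testing.

## Worked example

```r
library(ecostab)

cfg <- simulation_config(n_mines = 1, seed = 2026)
ds  <- simulate_chronosequence(cfg)

st <- stability_pipeline(ds)
st[c("site_id", "age", "f_x", "f_y", "D", "category", "sub_category")]
#>     site_id age   f_x    f_y     D           category sub_category
#> 1     M1-NA  NA 0.739 1.0000 0.922             Stable           SL
#> 2 M1-RA00.5 0.5 0.174 0.0155 0.169 Extremely unstable           VL
#> 3 M1-RA01.0 1.0 0.170 0.0592 0.296           Unstable           VL
#> 4 M1-RA02.0 2.0 0.566 0.3131 0.635      Nearly stable           VL
#> 5 M1-RA03.0 3.0 0.801 0.5455 0.806             Stable           VL
#> 6 M1-RA04.0 4.0 0.762 0.6883 0.851             Stable          VSD

succession_table(st)
#>   mine_id     K    a    r R2        p n
#> 1      M1 0.863 9.63 1.64  1 0.000106 5
```

Stability climbs from extremely unstable at half a year to stable by
age 3–4, approaching the reference (D = 0.92); the development ratio
shows vegetation leading soil early on (VL) before synchronising (VSD).
The logistic fit estimates the stability asymptote K = 0.86 with
succession rate r = 1.6/yr, significant against a constant-stability
model (p ≈ 1e-4). Ordination against the nine soil properties runs the
same way:

```r
dv <- diversity_table(ds$vegetation)
Y  <- as.matrix(dv[c("SP", "NP", "shannon", "simpson", "pielou", "margalef")])
X  <- as.matrix(ds$soil[setdiff(names(ds$soil), c("plot_id", "site_id"))])
rda_fit(Y, X)$variance_explained          # 0.554
permutation_test(Y, X, n_permutations = 499, seed = 2026)$p  # 0.418
```

(18 plots against 9 predictors is a weak design — the permutation test
rightly declines to call 55% explained variance significant here; real
surveys should and do pool more plots.)

`run_all(cfg, outdir, seed)` executes every stage and writes all stage
CSVs plus a JSON manifest (config, seed, ε, variant, polarities,
truncation rate) so any run is reconstructible.

## Layout

- `R/synthetic_data.R` — chronosequence generator with latent logistic recovery
- `R/diversity.R` — Shannon, Simpson, Pielou, Margalef, per-plot/site tables
- `R/group_stats.R` — ANOVA, Tukey–Kramer HSD, compact letter display
- `R/ordination.R` — RDA, permutation test, marginal effects, reference distances
- `R/stability.R` — standardization, entropy weights, C/T/D, classification
- `R/succession.R` — logistic succession fits and significance
- `R/pipeline.R` — `run_all()`, `validate_inputs()`, manifest
- `vignettes/mine-dump-stability.Rmd` — methods, conventions, limitations
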