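---
title: "Assessing ecological stability on reclaimed mine dumps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing ecological stability on reclaimed mine dumps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecostab)
```

## The problem

Revegetated refuse dumps at open-pit coal mines are usually surveyed as a
*chronosequence*: sites reclaimed in different years are sampled once, and
the age gradient stands in for time (space-for-time substitution). An
undisturbed *natural reference* site near each mine provides the recovery
benchmark. The question is not just whether soil nutrients or plant
diversity increase with restoration age, but whether the vegetation and
soil subsystems recover *together* — a site with lush vegetation on
infertile, compacted spoil is not stable, and neither is fertile soil with
a depauperate sward.

`ecostab` implements that assessment as one pipeline:

1. plant community characteristics per plot (species count SP, individuals
   NP, Shannon–Wiener H′, Simpson D, Pielou J, Margalef Mg);
2. one-way ANOVA with Tukey HSD and a compact letter display across sites;
3. redundancy analysis (RDA) of community characteristics on soil
   properties, with a Monte Carlo permutation test and per-site Euclidean
   distances to the reference centroid;
4. an entropy-weighted coupling-coordination index of ecological
   stability, with a five-band classification;
5. a logistic succession fit of stability against restoration age.

## The coupling-coordination stability model

For the sites of one mine (restoration sites plus the natural reference,
which must share the scale), each indicator is standardized to $[0,1]$ by
the extreme-value (min–max) method, reversed for *cost* indicators — soil
pH and bulk density, which are elevated on disturbed spoil. Entropy
weights are computed per block: with $p_{ij} = (z_{ij} + \varepsilon) /
\sum_i (z_{ij} + \varepsilon)$ and $e_j = -\tfrac{1}{\ln n} \sum_i p_{ij}
\ln p_{ij}$, indicator $j$ receives weight $w_j \propto 1 - e_j$, so
indicators that actually discriminate among sites carry the weight. The
smoothing constant $\varepsilon = 10^{-6}$ keeps standardized zeros inside
the logarithm's domain; it is echoed into the run manifest.

The plant and soil composites are the weighted sums $f(x) = \sum_i a_i
x_i$ and $f(y) = \sum_j b_j y_j$, both in $[0,1]$. From these:

$$C = \frac{4\, f(x) f(y)}{(f(x) + f(y))^2}, \qquad
  T = \alpha f(x) + \beta f(y), \qquad
  D = \sqrt{C\,T},$$

with $\alpha = \beta = 0.5$ (vegetation and soil treated as equally
important). $C \in (0,1]$ measures balance — by the AM–GM inequality
$C = 1$ exactly when $f(x) = f(y)$ — and $T$ measures overall quality.
$D$ is the ecological-stability score, banded as: $(0,0.2]$ extremely
unstable, $(0.2,0.4]$ unstable, $(0.4,0.6]$ sub-stable, $(0.6,0.8]$
nearly stable, $(0.8,1]$ stable (upper bounds inclusive; $D = 0$ falls
outside the open-at-zero bands and is assigned to the lowest with a
warning). The development ratio $f(x)/f(y)$ yields the sub-category:
vegetation-lagging (VL) above 1.2, soil-lagging (SL) below 0.8, and
synchronous in between — synchronous-lagging (VSL) in the two lowest
stability bands, synchronous-development (VSD) in the top three.

### Why $D = \sqrt{C\,T}$ and not $D = C\,T$

Both variants are implemented (`coordination_degree(..., variant =)`),
but the square root is the default, and the choice is falsifiable rather
than aesthetic. Given an observed $(D, k)$ pair with $k = f(x)/f(y)$, the
model inverts: $C = 4k/(1+k)^2$ depends only on the ratio, $T$ follows
from the variant, and $f(x) + f(y) = 2T$. `stability_backsolve()` performs
this inversion. For a stable, vegetation-leading site with $D = 0.90$ and
$k = 1.34$, the product rule forces $f(x) = 1.05 > 1$ — impossible for a
convex combination of $[0,1]$ values — while the square-root rule gives a
feasible $f(x) = 0.95$. The square root is also the standard form of the
coupling-coordination degree in the evaluation literature. The product
variant is retained behind the flag for literal comparability.

One published classification row is knowingly discrepant with the band
rules: a nearly stable site with ratio 1.17 labelled VL, although the
synchronous band covers $[0.8, 1.2]$. `classify_stability()` follows the
band rules; the test suite replays all 18 published $(D, k)$ pairs and
asserts exactly that single sub-category mismatch.

## Redundancy analysis

The RDA is computed from first principles so that every quantity is
auditable: the response matrix (the six community characteristics) is
z-scored column-wise — counts and unit-interval indices are on
incommensurate scales — the soil matrix is centered, fitted values come
from the multivariate least-squares regression, and the constrained axes
from the SVD of those fitted values. The explained fraction is
$\mathrm{tr}(\hat Y^\top \hat Y) / \mathrm{tr}(Y^\top Y)$; the tests
verify it against an explicit normal-equations oracle (tolerance
$10^{-10}$) and against `vegan::rda()`.

Significance uses the Monte Carlo permutation test: the pseudo-F
$(V_c/q) / (V_r/(n-q-1))$ is compared with its distribution under
unrestricted row permutation of the response, and
$p = (\#\{F_\pi \ge F_{obs}\} + 1)/(n_\pi + 1)$, counting ties as
extreme (conservative). With the conventional 499 permutations the
attainable floor is $1/500 = 0.002$. Unrestricted permutation is
appropriate because a global null with no covariables is being tested.
Per-variable shares are *marginal* by default — the variance explained by
each soil property alone as a fraction of the full-model constrained
variance — with sequential (column-order conditional) shares behind
`type = "sequential"`; published per-variable percentages do not state
which convention was used, so both are available.

Site scores use distance-preserving (type 1) scaling, so the Euclidean
distance from each site's centroid to the natural-reference centroid
(`reference_distance()`) is meaningful; on noiseless monotone
chronosequences these distances decrease strictly with age.

## The logistic succession model

Stability versus restoration age is fitted as
$D(t) = K / (1 + a e^{-rt})$: $K$ is the stability asymptote (D units),
$a$ the initial deficit (dimensionless), $r$ the succession rate
(1/years). Natural references have no restoration age and are excluded.
Fitting uses Levenberg–Marquardt least squares over a deterministic
multi-start grid ($a \in \{1, 5, 20, 100\}$, $r \in \{0.1, 0.5, 1, 2\}$,
$K \in \{\max D, 1\}$, bounds $K \le 1.5$), keeping the converged start
with the smallest SSE. Significance is an F-test of the fitted model
against the constant-stability model, $F = ((SST - SSE)/2)/(SSE/(n-3))$.
Two honest caveats, both verified by simulation in the test suite:
parameter recovery at chronosequence scale (5–6 ages) is good for $K$
(median within a few percent under noise SD 0.02) but extrapolative —
the asymptote lies beyond the oldest site; and the F-test is
*conservative* under a pure-noise null (empirical rejection well below
the nominal 5%), because the bounded monotone logistic family cannot
chase noise. A significant fit is therefore trustworthy; a marginal
non-significant one may simply reflect the test's conservatism at n = 5–6.

## The synthetic chronosequence generator

No raw plot data accompany published mine-dump chronosequence studies,
so the generator is a first-class module: it produces datasets with the
statistical structure the analysis assumes, with the latent truth
retained for parameter-recovery tests. Per mine it creates restoration
sites at configurable ages (default 0.5–4 years, matching a
sampled-in-the-reclamation-window design) plus one reference site, with
2–3 plots per site. Soil indicator means interpolate between a disturbed
and a reference state along a logistic recovery curve — the same family
the succession module fits — and plot values add Gaussian noise,
truncated at zero for physically non-negative quantities (the truncation
rate is logged in the manifest). Default magnitudes are typical of
semi-arid spoil recovery: organic matter 6→20 g/kg, total N 0.3→1.0
g/kg, available N 10→60 mg/kg, moisture 7→14%, bulk density 1.55→1.25
g/cm³, pH 8.31→8.05. Field studies of this design rarely report
plot-level variances, so the noise SDs are free parameters of the
generator, set once at roughly 5–10% of each disturbed-to-reference
range and documented here rather than tuned.

Vegetation: species richness interpolates along the same latent curve
over a ranked species pool (geometric rank-abundance profile, ratio
0.75; common species enter first as richness grows), and plot abundances
are Dirichlet-multinomial with tunable overdispersion — diversity indices
only need realistic aggregate structure, and DM gives controllable
plot-to-plot variation. What the generator does **not** emulate: spatial
autocorrelation among plots, topographic or soil-type covariates,
multi-year resurveys, observer error in species identification, and any
vegetation–soil feedback (plant and soil trajectories share the latent
curve but their noise is independent). Passing end-to-end tests
therefore show that the pipeline recovers the structure it assumes, not
that real refuse dumps obey that structure.

## Numerical and design conventions

- **Simpson variant**: the Gini–Simpson complement $1 - \sum p_i^2$ by
  default, so all indices point in the diversity direction; the raw
  dominance form is a flag.
- **Logarithms**: natural throughout; configurable base for H′ and J.
- **Pielou at S = 1** is defined as 0 (rather than 0/0) so site means
  never fail; Margalef is 0 at S = 1 or N = 1.
- **Aggregation**: indices per plot, then averaged per site (matching
  mean ± letter reporting); pooling abundances per site is a flag.
- **Tukey**: unequal plot counts (2 vs 3) use the Tukey–Kramer
  correction; the letter display uses the insert-and-absorb algorithm
  with ties broken by label order, so output is deterministic.
- **Degenerate inputs**: zero within- and between-group variance flags
  the ANOVA as degenerate (NaN F); constant indicator columns
  standardize to 0.5 with a warning; both-zero composites give C = 0
  with a warning.
- **Problem sizes in the test suite** (chosen to make the checks sharp
  at interactive scale): diversity oracle on 1,000 random censuses; RDA
  oracle on 100 random 12×6/12×5 instances; permutation type-I error
  over 1,000 simulated null datasets at 199 permutations each (the
  permutation count per test is the package's choice; the conventional
  499 is used for reported analyses); logistic recovery over 200 seeded
  chronosequences; stability-vs-age trend over 100 seeded runs.

The `pipeline_cli` surface is the pair `run_all()` / `validate_inputs()`
plus the repository's scripts: this package's users drive analyses from
R, so no shell subcommand layer is shipped. `run_all()` writes every
stage's CSV and a JSON manifest recording the configuration, seed,
package version and every gap-filling decision actually exercised
(entropy ε, coordination variant, cost-indicator set, truncation rate),
so a run is reconstructible from its manifest.

## Limitations

- Entropy weights depend on the site set: adding or dropping a site
  changes standardization ranges and weights, so D values are
  comparable within a mine's site set, not across studies.
- With 5–6 sites per mine the entropy weights are estimated from very
  few rows; they are objective but not stable under resampling. An
  uncertainty treatment (bootstrap over plots) is deliberately out of
  scope.
- The RDA permutes plots as exchangeable units; plots nested in sites
  are mildly pseudo-replicated under the global null. Restricted
  permutation schemes are not implemented.
- The succession fit extrapolates K beyond the oldest observed age;
  confidence in K degrades quickly if the chronosequence ends before
  the inflection.
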