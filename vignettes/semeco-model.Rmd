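---
title: "Modelling self-establishing metabolically cooperating yeast communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling self-establishing metabolically cooperating yeast communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semeco)
```

## The system

A prototrophic yeast cell that carries its biosynthetic genes (here *HIS3*,
*LEU2*, *URA3*, *MET15*, complementing the his3/leu2/ura3/met15 deletion
background) on episomal plasmids loses each plasmid occasionally at cell
division — segregation, at a per-division rate `m` of a few percent per
plasmid. A colony founded by one four-plasmid cell therefore turns, over
tens of doublings, into a mixture of up to `2^k = 16` *metabotypes*: cell
types defined by which subset of the k markers they retain. On minimal
media every lost marker is a lethal deficiency for a cell on its own, so a
growing colony of mostly-auxotrophic cells is direct evidence that cells
cooperate by exchanging the missing metabolites — a self-establishing
metabolically cooperating community (SeMeCo).

`semeco` implements the quantitative machinery around that experiment: the
metabotype state space, the segregation dynamics that predict colony
composition, estimation of `m` from replica plating, descriptive
composition statistics, spatial proximity analysis of fluorescence colony
images, and Richards growth-curve fitting, plus seeded generators of
synthetic inputs for all of them.

## Metabotype space

Metabotypes are encoded as k-bit retention masks in marker-set bit order
(`"1101"` = lost the third marker only); the canonical four-marker order is
H, L, U, M. `enumerate_metabotypes()` lists all `2^k` states, ordered by
descending retained-plasmid count and then descending mask value, so the
full prototroph is always first and the plasmid-free type last. This order
is the tie-break used wherever a deterministic ordering is needed
(`rank_metabotypes()`).

Supplementation is modelled per metabolite, not per marker: a uracil
auxotroph on uracil-supplemented media has no *external* requirement in the
nutritional sense (`classify_metabotype()`), which is exactly what matters
for the growth regimes below.

## Segregation dynamics

A daughter of a cell with retained set `s` keeps each plasmid `i` in `s`
independently with probability `1 - m_i`, so the per-generation transition
probability to retained set `s' ⊆ s` is

    T(s, s') = prod_{i in s'} (1 - m_i) * prod_{i in s \ s'} m_i.

Loss applies symmetrically to both daughters at division; mass never flows
back to higher retention (the matrix is triangular in loss-count order).

`step_population()` combines `T` with a per-metabotype division weight
`w(s)` given by the growth scenario:

* **neutral / cooperation** — `w = 1` for every type. In the cooperating
  colony auxotrophs are fed by their neighbours, so at the level of
  composition frequencies cooperation is the neutral model.
* **no_cooperation** — `w = 1` only for types with no unmet external
  requirement; arrested cells stay in the census but do not divide.
* **fitness_weighted** — user weights, rescaled so the fastest type has
  `w = 1` and interpreted per generation (in the stochastic model, the
  probability that a cell divides in that generation).

One generation maps frequencies `f` to the renormalisation of

    mass(s') = sum_s f(s) [ (1 - w(s)) 1{s' = s} + 2 w(s) T(s, s') ],

which reduces exactly to `f' = f T` under the neutral regime. If no
frequency mass sits on a dividing type the colony cannot grow;
`simulate_deterministic()` reports this as trajectory status `"collapsed"`
(a legitimate biological outcome, not an error) and freezes the
composition.

The deterministic recursion is the infinite-population expectation.
`simulate_stochastic()` is the corresponding branching process on absolute
cell counts — every dividing cell yields two daughters whose metabotypes
are drawn from `T` — with optional bottlenecks implemented as multivariate
hypergeometric subsampling (re-spotting a colony changes counts, not
expected frequencies, which is also why the deterministic model skips
bottlenecks). Extinction after a bottleneck is reported as status
`"extinct"`.

### Parameter choices

The only free parameter of the headline simulation is the segregation
rate. The community's measured *total* rate — the per-division probability
of losing at least one of the four plasmids — is 11%, i.e. a probability
0.89 of retaining all four through one division. Per-plasmid measured
rates are not printed in a reusable form, so the default derives equal
per-plasmid rates from the total: `equal_rates_from_total(0.11, 4)` =
0.0287 per plasmid per division, squarely inside the 2–4% per-division
range reported for both common replication types. Under the neutral regime
the prototroph frequency is then exactly `0.89^g`, which reproduces every
printed checkpoint: 91.3% of cells have lost a plasmid by `g = 21`
doublings (>90%), 99.87% by `g = 57` (>99%, and 99.9% to one decimal).

```{r checkpoints}
r <- equal_rates_from_total(0.11, 4)
traj <- simulate_deterministic(semeco_markers(), rep(r, 4), generations = 57)
100 * (1 - traj$freq[c("21", "57"), "1111"])
```

### Numerical choices

Counts in the branching process are tracked as doubles; binomial draws
whose trial count exceeds the 32-bit integer range (a 10^5-cell founder
doubling for 20 generations passes 10^11 cells) use a rounded normal
approximation, whose error at that scale is far below a single cell in
frequency terms. All stochastic entry points take an explicit seed,
restore the caller's RNG state, and record the seed in their outputs.

## Rate estimation

Replica plating scores, per replicate, how many of `n` colony-forming
units still retain a marker after `g` doublings. Under per-division loss
`m` the retention fraction is `F_g = F_0 (1 - m)^g`, inverted per
replicate as `m_hat = 1 - (F_g / F_0)^(1/g)` with `F_0 = 1` by default
(cultures start under selection). Replicates are pooled by arithmetic
mean; uncertainty comes from a seeded bootstrap (resampling CFUs
binomially within replicates, percentile interval, 1000 resamples by
default). Zero retaining CFUs would put the estimator at the `m = 1`
boundary on a log-degenerate path, so they receive a continuity correction
`(r + 0.5)/(n + 1)` with a warning. `doublings_from_counts()` supplies `g`
from biomass gain as `log2(final/initial)`.

## Composition analysis

`summarize_composition()` reduces genotyping counts to the community
descriptors: the auxotroph fraction, loss bins (how many cells lost 0..k
markers), per-marker auxotrophy both as a proportion of cells
(`marker_auxotrophy_abs`) and as a share of all auxotrophy *instances*
(`marker_auxotrophy_share`, a cell lacking two markers counts twice — this
is the normalisation under which the four shares sum to 100%), and the
cumulative weight of the `n` most frequent metabotypes.
`compare_compositions()` reports the squared Pearson correlation of raw
frequency pairs over the full metabotype space together with the
least-squares line and residuals; zero variance on either side is flagged
as a degenerate comparison rather than propagating `NaN`. No inferential
statistics are attached — these are descriptive summaries.

## Spatial proximity

For each marker channel of a colony image, intensities are min–max
normalised over the colony mask (the standard cut-offs 0.1–0.4
presuppose a normalised scale; the mask defaults to pixels whose
across-channel maximum exceeds the 5% quantile, and a user mask
overrides). Pixels at or above the cut-off are metabolite-producing
(prototrophic), the rest requiring (auxotrophic). Every auxotrophic
pixel's Euclidean distance to the nearest prototrophic pixel — exact
distance transform, distances between pixel centres, converted to µm by
the pixel size — is summarised as min, mean, max and the 90th percentile
(linear interpolation between order statistics). Distances are per pixel
by default because the underlying procedure operates on pixels; a per-cell
mode (connected-component centroids) is available. `proximity_sweep()`
tabulates all markers at all cut-offs; markers with no producer or no
auxotroph pixels at a cut-off are flagged rather than dropped.

## Growth kinetics

Growth curves are fitted with the Richards model in its growth-analysis
parameterisation

    y(t) = A [1 + nu e^(1+nu) exp((mu_max/A) (1+nu)^(1+1/nu) (lambda - t))]^(-1/nu),

with asymptote `A` (OD595), maximum slope `mu_max` (OD595/hr — reported on
the instrument scale, not per capita), lag `lambda` (hr) and shape `nu`
(logistic at `nu = 1`). Fitting is Levenberg–Marquardt least squares with
deterministic initialisation (`A` = max value, `mu_max` = max
finite-difference slope, `lambda` = first time above 5% of range, `nu` =
1), so a fit is reproducible from the data alone; non-convergence returns
a flagged result carrying the initialisation. An optional additive
baseline makes `mu_max` invariant to a constant offset.

Nutrient uptake is estimated from the falling extracellular concentration
curve by reflecting it and fitting **both** the Richards family and a
straight line, reporting the maximum slope of whichever has the lower
residual sum of squares. The dual fit is deliberate: a purely linear
depletion is the correct limit but sits on the boundary of the Richards
family (`A` unbounded, `nu` at its floor), where nonlinear least squares
is ill-conditioned; the line recovers that limit exactly while the
sigmoid wins whenever saturation is visible. Flat series return rate 0;
rising series are flagged and return 0.

## Synthetic data

The generators produce every input the analysis stages consume, with
ground truth alongside:

* `gen_genotyping_counts()` — one multinomial draw of `n` genotyped cells
  from true metabotype frequencies (the study genotyped 542 cells per
  colony; tests use that size).
* `gen_replica_plating()` — per replicate, retaining CFUs are
  `Binomial(n_cfu, (1 - m)^g)`.
* `gen_colony_image()` — cells as filled disks, positions uniform over a
  circular footprint; each cell's metabotype is drawn from the supplied
  frequencies, optionally re-weighted per marker by a von Mises kernel
  `exp(kappa cos(phi - phi_marker))` on the cell's angular position to
  mimic the sectored regions of real colonies (`kappa = 0` is spatially
  uniform; the sector pattern is a phenomenological stand-in — the real
  colony gives no generative model). Channels take `intensity_high` on
  pixels covered by a retaining cell, `intensity_low` on other colony
  pixels, plus Gaussian noise clipped at zero.
* `gen_growth_curve()` — Richards values plus Gaussian noise, clipped at
  zero; the default test regime mirrors a plate reader sampling every
  20 min for 40 hr at `mu_max = 0.2` OD/hr and sigma = 0.01 OD.

What the generators do **not** emulate — metabolite diffusion fields,
realistic cell shapes and point-spread functions, plasmid copy-number
variation, fitness differences between metabotypes — bounds what passing
tests show: they validate the computational pipeline against its own
statistical assumptions, not the biology of real colonies. In particular
the observed community composition is known *not* to follow the neutral
segregation prediction (that discrepancy is the biological finding), so
the package never claims to predict real compositions, only to compute
the model's prediction and compare it with data.

## Problem sizes and test design

The test suite runs the deterministic recursion to 57 generations on the
16-state space, the branching process from a 10^5-cell founder for 20
generations, 100 random 50x50 labelings against an all-pairs
nearest-neighbour oracle, 100-replicate rate-recovery loops at 1000 CFUs,
and 50 seeded noisy growth-curve fits — sizes at which every check is
exact or tightly bounded while the whole suite stays fast. Brute-force
oracles (daughter-pattern enumeration for the recursion, sum-formula
Pearson, all-pairs distances) are implemented independently in the test
helpers, never by calling the code they check.

## Known limitations

* Equal per-plasmid rates are a modelling default, not a measurement;
  per-marker estimates from `estimate_segregation_rate()` slot straight
  into every simulator when available.
* The deterministic no-cooperation model keeps arrested cells in the
  census forever (no death term).
* The colony mask heuristic assumes background is dimmer than colony in
  at least one channel; segmentation of real micrographs is out of scope.
* Cut-offs live on the per-channel min–max scale; images with saturated
  hot pixels should be masked or pre-clipped, or the normalisation will
  compress the informative range.
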