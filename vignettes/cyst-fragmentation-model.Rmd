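---
title: "Modeling germline cyst fragmentation, fusome inheritance and nurse-cell transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling germline cyst fragmentation, fusome inheritance and nurse-cell transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cystkit)
```

## The biological question

Mouse female primordial germ cells build germline cysts by five rounds of
synchronous mitotic divisions with incomplete cytokinesis: each division
leaves the daughters joined by a stable intercellular bridge, so a cyst is a
tree of up to 32 cells. The cyst later fragments, and each fragment matures
at most one oocyte while its other cells serve as nurse cells. Whether
fragmentation is random — any bridge equally likely to break — or programmed
toward uniform 6-cell derivatives is a quantitative question about the
bridge network, and this package provides the combinatorics, the exact
statistics and the stochastic simulators needed to pose it.

## Cyst topology

`divide_round()` implements the inheritance rule that at division **all
pre-existing bridges remain with one daughter**. This single rule fixes the
cyst's shape: after $r$ full rounds the canonical cyst has $2^r$ cells,
maximum degree $r$, and $2^{r-1}$ single-bridge (peripheral) cells for
$r \ge 2$. It is the only inheritance rule consistent with the observed
8-cell breakage arithmetic: enumerating the seven single-bridge removals of
the canonical 8-cell cyst gives fragment-size pairs
$\{(1,7)\times 4,\ (2,6)\times 2,\ (4,4)\}$, i.e. exactly 2 of 7 bridges
release a 6-cell derivative. Had old bridges been distributed between
daughters, the degree distribution — and that count — would differ.

```{r}
enumerate_break_outcomes(canonical_cyst(3))
```

Cysts of 7, 9 or 10 cells are modeled as a canonical cyst caught partway
through its next round (`partial_cyst()`). Which cells lead the division
wave is not known; the default `leaf_first` policy (lowest-degree cells
divide first, ties to the lowest id) is deterministic and reproducible, and
a seeded `random_subset` policy is the alternative. This choice has real
consequences: under `leaf_first` the 7-cell topology has a 6-cell cut at
3 of its 6 bridges, while the 9- and 10-cell topologies have none, so a
programmed 6-cell prediction is impossible for them under this policy. We
treat that as a property of the modeled topology, report it openly
(`analysis/01_build_cysts.R` tabulates per-size 6-cut fractions), and note
that no partial-round policy we examined yields a 6-cut at every observed
size — the in vivo topologies of non-power-of-two cysts are simply not
constrained by the available data.

## The breakage null test

The pooled test reproduces the published procedure: every observed cyst,
whatever its size, is a Bernoulli trial with success probability
$p_6 = 2/7$, the canonical 8-cell value, and the observed 13 successes in 15
trials are scored against $X \sim \mathrm{Bin}(15, 2/7)$. The package
reports both the point mass $P(X = k)$ and the upper tail $P(X \ge k)$; the
published $4.53\times10^{-6}$ corresponds numerically to the **point**
probability at $k = 13$ (the tail is $4.80\times10^{-6}$), and we label it
as such rather than asserting which was intended — at these magnitudes the
scientific conclusion is unchanged.

```{r}
breakage_null_test(reference_breakage_sample())
```

The exact mode replaces the pooled $2/7$ with each record's own
$p_6(\text{partial\_cyst}(\text{size}))$ and evaluates the Poisson-binomial
distribution by iterative convolution ($O(n^2)$, exact to machine
precision; checked in the tests against complete $2^n$ enumeration). Under
`leaf_first` topologies the 9- and 10-cell records have $p_6 = 0$, so 13
successes are unreachable and the exact test returns an exact zero — an
even stronger rejection than the pooled figure, and a reminder that the
pooled simplification is the *conservative* choice here.

Binomial masses are computed in log space
($\exp[\log C(n,k) + k\log p + (n-k)\log(1-p)]$) so the far tail at
$k = 13$–$15$ is stable; normalization holds to $10^{-12}$ up to $n = 64$.

## Programmed fragmentation and the clone model

The microtubule gap that predicts breakage isolates a 6-cell group. Among
6-yielding bridges, `programmed_break()` removes the one whose 6-cell side
contains the most-branched cell, because the multi-bridge cells are the
fusome-enriched pro-oocytes; remaining ties break deterministically by
creation round then cell id. Whether the *other* 6-yielding bridge is ever
the in vivo break site cannot be distinguished from the available
observations; the tie rule is a documented convention, not a claim.

The quartet scheme (`quartet_fragmentation()`) models the clone-level
outcome: cut the three oldest bridges (rounds 1–2), producing four 8-cell
subtrees, then apply the programmed break to each — exactly four 6-cell and
four 2-cell cysts, hence four future oocytes. The greedy alternative
(`eight_cell` schedule: break any fragment of ≥ 7 cells as soon as it has a
6-cut) is also provided; a single run is frozen in the tests as a
regression fixture and produces fragments of 24, 6 and 2 cells, because a
6-cell fragment that keeps dividing has no 6-cut at 12 or 24 cells. Only
the single late wave reproduces uniform sixes, which is the reason it is
the default.

## Fusome inheritance

The fusome is modeled as a per-cell scalar volume — the quantity actually
measured in granule quantifications — rather than a per-bridge field. At
each division the parent's volume $V$ splits $f : (1-f)$ with the
bridge-retaining daughter receiving $f$; both daughters gain $\delta/2$ of
newly deposited material; multiplicative lognormal noise
($\mathrm{LN}(0,\sigma)$) models biological and measurement scatter while
keeping volumes positive (the reason noise is multiplicative, not
additive). Without noise the totals obey
$\sum V_{\text{daughters}} = V_{\text{parent}} + \delta$ exactly, and each
cell's volume is $V_0$ times the product of $f$/$(1-f)$ factors on its
retention path, so for $f > 0.5$ the most-branched cell always holds the
most fusome.

Defaults, chosen once as the study conditions: $f = 0.7$ (a consistent
$\approx 2.3{:}1$ sister ratio, matching the reproducible inequality of
sister granule volumes in 2-cell cysts), $\delta = 0.2\,V_0$ (fresh
material appears at each furrow but the inherited pool dominates),
$\sigma = 0.25$ (a realistic spread for organelle-volume scatter, matched
qualitatively, not fitted). Volumes scale linearly in $V_0$, which is
therefore left at 1 µm³.

```{r}
st <- simulate_fusome(canonical_cyst(3), fusome_params(f = 0.7, delta = 0, sigma = 0))
enrichment_report(canonical_cyst(3), st)$table
```

When every cell has the same volume (e.g. $f = 0.5$, $\sigma = 0$) the rank
correlation is undefined; it is reported as 0 with `degenerate = TRUE`
rather than `NA`, so downstream tabulations need no special-casing.

## Nurse-cell transfer

Within a fragment the oocyte is the most-branched cell (ties to the
smallest id). Cells activate as nurse cells on an exponential clock at
`rate` = 0.5/day — one activation per 2 days on average — so an $n$-cell
fragment breaks down in $(n-1)/\mathrm{rate}$ days in expectation (10 days
for a 6-cell cyst). A donor must be a current leaf of the shrinking tree
(removing an interior cell would disconnect it); it sends a fraction
$\varepsilon$ of its **current** content to its unique neighbor — one hop
along the path toward the oocyte — and the remainder is logged as the dying
nurse cell's remnant. Because transfer is hop-wise, losses compound with
distance: at $\varepsilon = 0.9$ a 6-cell fragment yields a 5.32-fold
oocyte enrichment, below the 6-fold conservation bound and in the ~5-fold
range reported for organelle enrichment, without any fitting. At
$\varepsilon = 1$ conservation is exact: fold = fragment size.

Whether activation is strictly peripheral-first in vivo is unknown; both a
deterministic `leaf_first` order and a uniform `random` order over current
leaves are provided.

## Synthetic data and the voxel oracle

The generators exist so every statistical claim can be exercised on data
whose ground truth is known. `make_measurement_table()` produces per-cell
tables (bridge count, fusome volume, a Pard3 stained area that tracks
volume^(2/3), nucleus diameter) whose couplings are *inherited from the
generative models*, not painted onto the table. `make_mt_gap_dataset()`
places a microtubule gap per cyst — at a 6-yielding bridge with probability
$1-\eta$ under programmed truth, uniformly under random truth — and always
derives `six_predicted` from the graph, never stores it independently. The
10 µm gap criterion is metadata: gaps are topological (a designated
bridge), with no spatial geometry simulated. Fixed seeds reproduce every
dataset byte-for-byte.

What these generators deliberately do not emulate: imaging noise,
segmentation error, spatial cell arrangement, or the movement-driven
transient separations seen in live imaging. Tests passing on synthetic data
therefore validate the statistical machinery and the model's internal
consistency, not the imaging pipeline.

`voxelize_granules()` / `measure_volume()` give volume quantification an
analytic oracle: spheres are rasterized by voxel-center inclusion on a
lattice anchored at integer multiples of the voxel size (so a fixed scene
refines consistently as the voxel shrinks, independent of the bounding
box), and measured volume is count × voxel³. At 0.2 µm voxels a 5 µm-radius
sphere measures within 2% of $\frac{4}{3}\pi r^3 = 523.6$ µm³, with error
decreasing through 0.4/0.2/0.1 µm.

## Numerical and design notes

* All tie-breaks (divider order, daughter numbering, programmed-break
  candidates, oocyte choice) resolve by smallest creation round then
  smallest cell id, making every deterministic code path exactly
  reproducible.
* Every stochastic function takes an explicit `seed`; the power study and
  Monte-Carlo checks fix seeds so reruns are bit-identical.
* `power_curve()` defaults to samples of canonical 8-cell cysts — the
  topology whose $p_6 = 2/7$ calibrates the pooled test — so its size under
  random truth reads off the test's exact conservativeness; mixed-size
  studies pass `size_mix`. Significance levels default to 0.05 and
  $10^{-4}$.
* Problem sizes used in the shipped tests and scripts: topologies to
  32 cells, Poisson-binomial brute-force cross-checks to $n = 12$
  ($2^{12}$ enumeration), $10^5$ random-break draws for the Monte-Carlo
  frequency check, 1000 replicates × 15 cysts for the power study.
* Known limitations: no spatial embedding or cell movement; male cyst
  topology differences not modeled; timing within a cell cycle (the
  late-telophase onset of fusome asymmetry) collapsed into the division
  event; empirical fold-enrichment values and the literature's "average of
  4.8 smaller cysts" are context, not targets, and are not fitted.
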