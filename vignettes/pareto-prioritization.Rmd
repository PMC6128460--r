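---
title: "Pareto ranking for spatial conservation prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pareto ranking for spatial conservation prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paretoprior)
```

## The problem

Conservation planners in fire-prone, fragmented landscapes — Mediterranean-type
ecosystems being the archetype — must decide where to spend limited monitoring
and management resources. Each raster grid cell of the landscape carries
several attributes describing threats (wildfire history and potential, roads,
urban and agricultural development, habitat fragmentation) and biodiversity
value (stacked species-distribution-model richness per taxon, genetic
diversity and divergence). This is a multi-criteria decision analysis (MCDA)
problem: the alternatives are the grid cells, and the criteria disagree about
which cells matter most.

Classical MCDA methods (additive multi-attribute value theory, AHP) collapse
the criteria into a single score using subjective weights. `paretoprior`
implements the alternative this package exists for: **Pareto ranking**, which
needs no weights and no common scale, only the comparative order of values
within each criterion.

## Criteria and value functions

Write $a_{k,m}$ for the $m$-th attribute of cell $k$ ($k = 1,\dots,K$,
$m = 1,\dots,M$). Ranking is posed as minimization, so each attribute column
$\mathbf a_m$ is transformed into a criterion $\mathbf x_m \in [0,1]^K$ with
one of two linear min–max value functions:

* order-preserving, for attributes whose **low** values warrant attention
  (`value_fn_f`): $x_{k,m} = \dfrac{a_{k,m} - \min(\mathbf a_m)}{\max(\mathbf a_m) - \min(\mathbf a_m)}$
* order-reversing, for attributes whose **high** values warrant attention
  (`value_fn_g`): $x_{k,m} = \dfrac{\max(\mathbf a_m) - a_{k,m}}{\max(\mathbf a_m) - \min(\mathbf a_m)}$

For any non-constant column the two satisfy $f + g = 1$ elementwise. Because
Pareto ranking only uses the comparative values $<, =, >$ within each column,
any strictly monotone transform would serve equally well; the linear form is
kept for interpretability, and the package's tests verify that ranks are
invariant to strictly increasing transforms and positive per-column weights.

Normalization minima and maxima are computed over in-mask, non-missing cells
only. Two degenerate cases need a rule:

* **Constant column** ($\max = \min$): division by zero. The column is mapped
  to all zeros with a warning — a constant criterion expresses no preference,
  and this keeps ranking well-defined.
* **Missing values** stay missing through the transform; a cell with any
  missing criterion in a given decision matrix is excluded from that ranking
  (it gets no rank, and nodata in the output raster).

The standard twelve attributes and their directions ship as a registry:
the order-reversing `g` for fire counts (`nfires`), ignition probability
(`pr_ign`), road density (`road`), development density (`dev`), the four
taxon richness indices (`plant`, `herp`, `bird`, `mamm`), and the genetic
layers (`divers`, `diverg`); the order-preserving `f` for fire return
interval departure (`frid`, where more-negative departure means fires are
more frequent than the reference regime) and fragment area (`patch`, where
small patches indicate fragmentation). Six preset decision matrices combine
the fire block F′, fragmentation block H′, species block S′, and genetic
block G′ as [F′|S′], [H′|S′], [F′|G′], [H′|G′], [F′|S′|G′], [H′|S′|G′].

## Pareto ranking

Criteria vector $\mathbf x_k$ **weakly dominates** $\mathbf x_l$ when
$x_{k,m} \le x_{l,m}$ for every $m$ and $x_{k,m} < x_{l,m}$ for at least one
$m$. Identical vectors do not dominate each other. Ranking proceeds by front
peeling: the non-dominated set of all valid cells gets rank 1, the
non-dominated set of the remainder rank 2, and so on until every valid cell
is ranked. Consequences the package tests as invariants:

* dominance implies strictly lower rank;
* assigned ranks are contiguous from 1, and the first front is never empty;
* identical criteria vectors always share a rank;
* the result is deterministic and independent of row order;
* for $M = 1$ ranking reduces to dense sorting; for two perfectly
  anticorrelated distinct criteria every cell is rank 1.

### Algorithm

The definitional algorithm — scan all pairs, peel, repeat — is quadratic per
front and impractical for grids with 10^5–10^6 cells. The implementation
first collapses identical criteria vectors (they provably co-rank, which also
settles tie handling exactly), then ranks the unique vectors with an
efficient non-dominated sort in C++: rows are processed in lexicographic
order, so any dominator of a row precedes it, and each row binary-searches
the first front none of whose members dominates it (the front a row belongs
to is monotone in this test because dominance is transitive). The brute-force
all-pairs peeling algorithm is retained in the test suite as an independent
oracle, and the two agree exactly on hundreds of randomized instances up to
$K = 500$, $M = 6$, with and without duplicate rows.

### Composite ranking

With many criteria, dominance becomes rare and most cells land on the first
few fronts, which blunts the prioritization. Composite Pareto ranking widens
the range: rank two component matrices separately, treat the two resulting
ranks as a new 2-criterion matrix (lower better), and rank again. The three
standard pairings combine the fire-based and fragmentation-based matrices
sharing a biodiversity block: r[r(F′|S′) | r(H′|S′)], r[r(F′|G′) | r(H′|G′)],
r[r(F′|S′|G′) | r(H′|S′|G′)]. A cell unranked in any component is unranked in
the composite, consistent with ranking only cells with complete criteria.

### Why weights are irrelevant

For any strictly positive weights $w_m$, $\mathbf x_k \prec \mathbf x_l$
implies $\sum_m w_m x_{k,m} \le \sum_m w_m x_{l,m}$: weighted-sum screening
can never prefer a dominated cell to its dominator.
`check_weighted_consistency()` verifies this pairwise-dominance statement
directly. Note the implemented and tested claim is deliberately the pairwise
one; the stronger claim that *every* lower-ranked alternative beats every
higher-ranked one under any weighted sum does not follow from pairwise
dominance (two cells on adjacent fronts need not be comparable), so the
package does not assert it.

## Attribute derivation

The derivations and their tunable parameters (defaults chosen for a 50 m
grid, i.e. 0.25 ha cells):

| Layer | Derivation | Parameters |
|---|---|---|
| `nfires` | per-cell sum of binary fire-perimeter rasters | — |
| `road` | proportion of cells with road within a circular window | `radius = 500` m |
| `dev` | `(n_urban + 0.3 * n_ag) / n_total` over the same window | `radius = 500` m, `ag_weight = 0.3` |
| `patch` | area (ha) of the connected open patch containing the cell | `connectivity = 4`, urban blocks by default |
| `plant` | sum of thresholded presence maps | one threshold per species |
| `herp`, `bird`, `mamm` | sum of continuous suitabilities in [0,1] | — |
| `pr_ign`, `frid`, `divers`, `diverg` | consumed as provided (external model outputs) | — |

Discretization choices that the sources of such layers rarely state, fixed
here as follows:

* **Circular window membership**: a cell belongs to the window iff its
  *center* lies within `radius` of the focal cell's center. At grid borders
  the denominator counts only in-grid cells, so densities remain proportions
  in [0, 1].
* **Patch connectivity**: 4-connectivity by default. Rasterized road lines
  are frequently only diagonally contiguous; with 8-connectivity a patch
  would "leak" through such a road, defeating the point of roads as
  barriers. 8-connectivity is available as an option.
* **What blocks a patch**: roads and urban cover both block by default
  (patches are road-free, non-urban areas); blocking by roads alone is a
  caller choice since the blocking layer is an explicit input.
* Urban and agriculture layers must be disjoint; overlap is an error rather
  than silently double-counted.

## Percentile classification and summaries

Cells are classified top-priority when their rank is at or below the
25th-percentile rank (configurable `q`). Pareto ranks are small integers with
massive ties, so an interpolating quantile estimator could return a
non-attained threshold; the nearest-rank rule on the empirical CDF is used
instead: the smallest rank $t$ with $\Pr(\text{rank} \le t) \ge q$. The
threshold is computed per decision matrix by default (each matrix defines its
own rank scale); `zonal_summary(threshold = )` supports an explicit global
threshold where comparability across matrices is wanted. Summaries report,
per zone × conservation status stratum, the number and percentage of
classified cells; `median_rank_profile()` gives per-row (or per-column)
median ranks for gradient descriptions such as west-to-east trends.

## Simulation module

`simulate_criteria()` draws criteria from an equicorrelated multivariate
Gaussian (pairwise correlation `rho`, feasible for
$\rho \in (-1/(M-1), 1]$) mapped to [0,1] by the order-preserving value
function, and `rank_range_experiment()` records the maximum assigned rank
over replicates. The equicorrelated Gaussian copula is the simplest structure
expressing "correlation among criteria", and only qualitative trends are
asserted: the rank range grows with `rho` and shrinks with the number of
criteria. The analytic limits anchor the ends: a strictly decreasing function
of a single criterion (the $\rho = -1$ limit) gives one all-rank-1 front; a
duplicated column (the $\rho = +1$ limit) gives one rank per distinct value.
All randomness flows from one explicit seed; replicate $r$ of configuration
$g$ uses seed $+ (g-1) n_{\text{rep}} + r$, so runs are reproducible and
replicates never reuse a seed.

## Synthetic data

Two generators provide fully in-code fixtures:

* `synthetic_stack()` emulates the *structure* of a real attribute stack:
  equicorrelated, lightly smoothed Gaussian layers; a rectangular mask hole;
  a controllable fraction of in-mask cells missing in one layer; contiguous
  vertical zone bands (real climate zones run roughly parallel to the
  coast); and a spatially blocky conservation layer.
* `synthetic_landscape()` generates the *primitive* inputs upstream of
  derivation — blob-shaped fire perimeters, drifting road transects, disjoint
  urban/agriculture blobs, smooth suitability fields — so the derivation
  functions are exercised end to end.

What these do **not** emulate: realistic fire-size distributions, road
network topology, species co-occurrence structure, or any spatial
autocorrelation model beyond box smoothing. Passing tests on these fixtures
demonstrates the correctness of the transformations, ranking, and summaries —
not that any particular landscape's priorities are ecologically right, which
depends entirely on the quality of the input layers.

## Problem sizes and numerical choices

The test suite validates ranking against the brute-force oracle on matrices
up to $K = 500$, $M = 6$ (200 randomized instances), and runs the full
pipeline on a 100×100 stack with 12 layers, 10% missing cells, and 4 zones —
sizes chosen so the whole suite completes in well under a minute while still
crossing every code path; the ranking core itself handles $10^5$ unique
vectors in seconds. Raster I/O uses the ESRI ASCII grid text format with an
explicit nodata value (0 for rank rasters, since ranks start at 1; −9999
otherwise). Grid alignment checks compare shape, origin, and cell size with a
10⁻⁶ m tolerance. No randomness exists anywhere in ranking or summarization;
only the simulation and fixture generators consume seeds.

## Known limitations

* No secondary prioritization within ranks: cells sharing a rank are left
  tied by design (downstream screening or expert judgment can break ties
  without ever preferring a dominated cell).
* Ranking ignores spatial relationships between cells (no connectivity or
  compactness objectives, unlike reserve-design tools such as Marxan or
  Zonation); space enters only through attribute derivation and reporting.
* Species distribution models, ignition-probability models, fire return
  interval estimates, and genetic surfaces are inputs, not products, of this
  package.
* Min–max normalization is sensitive to single extreme cells; since ranks
  are invariant to monotone transforms this affects interpretation of the
  criterion values, never the ranks.
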