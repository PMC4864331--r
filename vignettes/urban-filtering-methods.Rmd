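---
title: "Methods: nonrandom species filtering along urbanization gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nonrandom species filtering along urbanization gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbfilter)
```

## The question and the data model

Urbanization replaces vegetated habitat with built-up surfaces, and bird
communities inside city limits are usually a subset of those in the
surrounding landscape. The question this package addresses is whether
that subsetting is *random* — the thinning one expects when a smaller
number of individuals is sampled from the regional pool — or *nonrandom
filtering*, in which particular species (habitat and diet specialists)
are excluded while a few exploiters, often exotic synanthropes, are
promoted.

The data model is a point-count design: a city is covered by grid cells,
a fixed-radius point count is performed in each sampled cell, and every
cell carries metadata (city, habitat class `urban`/`periurban`,
vegetation-cover fraction). The canonical containers are a cells x
species integer count matrix, a per-cell metadata table, and a
per-species trait table assigning each species one of seven diet guilds
and one of four preferred-habitat guilds (mutually exclusive within each
resource group), plus native/exotic origin.

## The resampling null model

For each city separately, let the *pool* be the per-species proportions
of all individuals recorded in the periurban cells, and let $N$ be the
total number of individuals recorded in the urban cells. The null model
draws 999 random urban communities, each a multinomial sample of $N$
individuals (drawing with replacement) from the pool, so random
communities have exactly the observed urban community size — community
size and dispersal chance are thereby disentangled.

For a species absent from the urban habitat, the *mode* of its 999
simulated abundances decides its fate: modal abundance zero means the
absence is compatible with random dispersal (*chance-absent*); a nonzero
mode means random assembly would almost always have included it, so it
is classified an *urban avoider*. Ties in the mode (e.g. counts split
evenly between 0 and 1) are broken toward the smaller value by default,
which is conservative: it favours chance-absent over avoider. The
tie-break is configurable.

Three per-city loss metrics summarise the result:

* **observed loss** — the percentage of periurban species absent from
  the urban habitat;
* **random loss** — $100 (S_P - \bar S_{sim}) / S_P$, where $S_P$ is
  periurban richness and $\bar S_{sim}$ the mean simulated urban
  richness: the loss expected from random dispersal alone;
* **tolerance richness** — total recorded species minus the avoiders:
  the richness expected if only nonrandom exclusions are removed.

Species recorded in neither habitat of a city are excluded from that
city's pool and metrics. Each city consumes its own random generator,
seeded from the master seed and a hash of the city name, so adding or
dropping a city never perturbs the other cities' simulations.

### Known bias of the plug-in pool

The null model is a *plug-in* procedure: the simulated absence
probability of species $i$ is approximately $(1-\hat p_i)^N$ with
$\hat p_i$ the empirical periurban proportion. For species recorded
only once or twice in the periurban sample, $\hat p_i$ is bounded below
by $1/T$ ($T$ = periurban total count), while the species' true
proportion, under a realistic abundance distribution with few genuinely
vanishing-rare species, tends to sit above that bound. The convexity of
$(1-p)^N$ then makes the simulated absence probability of such species
an overestimate, so the *random loss* is slightly overpredicted. In our
synthetic no-filtering experiments (100 replicates at the default
design) this bias is about $-0.6$ percentage points of
observed-minus-random loss, and a t-test across replicates detects it
reliably; the avoider false-positive rate among well-sampled species
(expected urban count $\ge 3$) nevertheless stays below 1%. The bias is
conservative for the headline claim — it can only shrink an apparent
filtering signal, never inflate it — and it depends on the assumed
species-abundance distribution. We report it rather than correct it,
because the plug-in form *is* the method under study.

## PERMANCOVA on dissimilarity matrices

Responses are compared through distance-based linear models in the
McArdle–Anderson framework: the distance matrix $D$ is Gower-centered,
$G = -\tfrac12 J D^2 J$, whose trace is the total sum of squares, and
sequential (Type I) sums of squares are obtained by projecting $G$ onto
the orthonormalized design columns of each term, in the fixed order

covariate, city, habitat, cov x city, cov x habitat, city x habitat,
cov x city x habitat.

The covariate (vegetation cover) enters first. Five responses are
standard: richness and evenness on Euclidean distances of the per-cell
index, and community, diet-guild and habitat-guild structure on
Bray–Curtis dissimilarities of fourth-root-transformed counts. Evenness
is Pielou's $J' = H'/\ln S$ with natural logarithms — the package's
reading of a generic "log-evenness index"; it is undefined for cells
with $S \le 1$, and such cells are dropped from the evenness analysis
only. Shannon's $H'$ is available as an alternative.

**Denominators.** With habitat fixed and city random, the pseudo-F for
habitat uses the city x habitat mean square as denominator; every other
term is tested over the residual. The expected-mean-square bookkeeping
of mixed distance-based models is software-convention territory, so the
full denominator map is user-overridable and echoed in the output.

**Permutation p-values** use Freedman–Lane permutation of residuals
under the reduced model (the terms preceding the tested term in the
sequential order): residuals of the reduced fit are permuted, the
response reconstructed and the full table recomputed, which gives the
statistic's null distribution while holding earlier terms fixed. A raw
row/column permutation scheme is available as a cheaper alternative.
P-values include the observed statistic, $(b+1)/(m+1)$, and therefore
lie in $(0, 1]$. Internally the permuted statistic is evaluated through
quadratic forms of the permuted basis vectors plus an $O(n)$ trace
correction, never by rebuilding $n \times n$ matrices, so 2,000
permutations of a 480-cell, 7-term model take well under a minute.

**Monte-Carlo p-values.** The habitat term's denominator has 2 degrees
of freedom, so only $(2!)^3 = 8$ distinguishable permutations exist at
the 3-city design and the permutation p-value is uselessly coarse. For
any term whose count of distinguishable permutations falls below 1,000,
the null pseudo-F is instead drawn (10,000 draws) from ratios of
chi-square sums weighted by the eigenvalues of the residual-projected
$G$ — the asymptotic form of the permutation distribution. Negative
eigenvalues of semi-metric inputs are kept with their sign.

**Components of variation** are method-of-moments estimates: for term
$t$ with denominator $d$, $(MS_t - MS_d) / m_t$ with multiplier $m_t =
n / (\text{level combinations of } t)$, the balanced-design
expected-mean-square coefficient; the residual component is $MS_{res}$.
Negative estimates are truncated to zero and the set rescaled to
percentages summing to 100.

## SIMPER

For every between-habitat pair of cells $(j,k)$, species $i$ takes the
share $|y_{ij}-y_{ik}| / \sum_s (y_{sj}+y_{sk})$; shares sum exactly to
the pair's Bray–Curtis dissimilarity, and averaging over all pairs
gives per-species contributions that sum exactly to the average
between-habitat dissimilarity. The table is sorted by contribution and
truncated at the first item whose cumulative percentage reaches the 90%
cutoff (so totals slightly exceed 90). Average abundances per group are
reported on the same (fourth-root) scale as the decomposition by
default, with a raw-scale option, since either convention is found in
published tables.

## Ordination

PCoA is the eigendecomposition of $G$; coordinates are eigenvectors
scaled by $\sqrt{\lambda}$ for positive eigenvalues. Bray–Curtis is a
semi-metric, so negative eigenvalues occur: they are reported, their
axes are not embedded, and percentages explained are computed over the
positive spectrum only. No Lingoes/Cailliez correction is applied by
default (an option applies Lingoes). Group-centroid distance matrices
are computed directly from $G$-block means — equivalent to centroid
distances in the full principal-coordinate space including
negative-eigenvalue components with sign; a negative squared centroid
distance (possible for semi-metrics) is clamped to zero with a warning.
Correlation vectors are Pearson correlations (Spearman selectable) of
each item with the plotted axes; an item is displayed only when its
maximum absolute correlation strictly exceeds 0.75.

Whether ordination should show cells or city x habitat centroids is a
presentation choice; both are possible, and the bundled workflow uses
the 6 centroids, which is what "centroidal dissimilarity matrices"
produce.

## The synthetic-data generator

No field data ship with the package; the generator produces surveys
with the statistical structure the analyses assume, plus ground truth
for validation. Defaults mirror the target design: 3 cities, 110 urban
and 50 periurban cells per city, 54 species, 3 exotics.

* **Regional pools.** Per-city species scores are lognormal (sdlog 1 by
  default; a log-series option exists), normalized to proportions. One
  independent pool per city reflects pooling by city; a shared-pool
  switch supports cross-city homogenization experiments.
* **Fate classes.** Avoider/exploiter/tolerant fractions (defaults
  0.30/0.15) are converted to exact counts by floor +
  largest-remainder. Avoiders get urban multiplier
  $1 - \text{filter\_strength}$ (default filter 0.8), native exploiters
  2, exotics `exotic_boost` (default 20). Avoider status is never
  assigned to the ~5 regionally dominant species: empirically, urban
  avoiders are habitat specialists while regionally superabundant
  open-country species persist in cities, and a generator that lets a
  20%-share species be an avoider produces loss tables no field study
  shows.
* **Exotics** are a subset of the exploiters with regional shares near
  the typical species share (lognormal, sdlog 0.3 around the median
  score): synanthropes are moderately common everywhere and owe their
  urban dominance to the boost, not to regional rarity or abundance.
  With the default boost, the exotics dominate urban communities and
  top the species SIMPER table in every city, the qualitative pattern
  the package is designed to detect.
* **Cells.** Vegetation cover is Beta-distributed (urban mean 0.25,
  periurban 0.60 — only the ordering matters to the analyses); per-cell
  totals are Poisson with log-linear vegetation effect
  $\lambda = \bar N \exp(0.6\,(v - 0.45))$, $\bar N = 12$ birds per
  count, a typical 6-minute fixed-radius point-count figure; species
  counts are multinomial over the city pool, urban cells re-weighted by
  the multipliers and renormalized.

What the generator does *not* emulate: spatial autocorrelation among
cells, detectability differences among species and habitats,
phylogenetic or trait-correlated abundance structure, and temporal
replication. Passing tests therefore demonstrate correctness of the
machinery and calibration under idealized sampling, not robustness of
the field inference to those complications.

## Numerical choices

* Sequential orthonormalization uses double Gram–Schmidt against all
  earlier terms with a $10^{-9}$ rank tolerance; a term that loses all
  rank raises an error naming it (singular/confounded designs are
  refused, as are designs with empty or single-observation cells for
  the slope interactions).
* All-zero cell pairs get Bray–Curtis distance 0 with a warning.
* The residual sum of squares is obtained from the trace identity
  rather than a residual projector, so the SS partition is exact to
  machine precision on every run.
* Permutation tie handling compares $F^* \ge F - 10^{-12}|F|$.
* Problem sizes in the bundled workflow: 999 null-model simulations,
  1,999 permutations per PERMANCOVA response at 480 cells, 10,000
  Monte-Carlo draws; the full five-response pipeline runs in about a
  minute on one core.

## Limitations

The denominator map and permutation scheme reproduce one defensible
convention for mixed distance-based models; other software may choose
differently, and the package makes the choice explicit and overridable.
The Monte-Carlo p-value is an asymptotic approximation whose accuracy
degrades for very small designs. The plug-in bias of the null model
described above is inherent to resampling from an estimated pool at
finite periurban sample size. Components of variation assume a balanced
design for their multipliers; with mild imbalance they remain useful
descriptively.
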