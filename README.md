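# urbfilter

Tests whether the loss of bird species from urban habitat is random.
Given point-count surveys of urban and periurban grid cells in one or
more cities, the package asks two questions:

1. **Is each urban absence explainable by chance?** A resampling null
   model draws 999 random urban communities from the periurban species
   pool — multinomial draws of the same total number of individuals
   as the observed urban community. A species absent from urban habitat
   whose simulated abundances have modal value zero is *chance-absent*;
   a nonzero mode marks an *urban avoider*, a nonrandom exclusion. Per
   city, the observed loss (% of periurban species absent from urban
   habitat), the random loss (% expected from random dispersal alone)
   and the tolerance richness (total species minus avoiders) summarize
   the filter.
2. **Do urban and periurban communities differ in structure?**
   Distance-based PERMANCOVA (sequential sums of squares of the
   Gower-centered dissimilarity matrix, pseudo-F with mixed-model
   denominators: habitat fixed, city random, vegetation cover as
   covariate), with permutation and Monte-Carlo p-values and components
   of variation; SIMPER decomposition of the average between-habitat
   Bray–Curtis dissimilarity over species or guilds (90% cumulative
   cutoff); and PCoA of city-by-habitat centroid distance matrices with
   correlation-vector overlays (|r| > 0.75).

A synthetic survey generator with known ground-truth filtering
(`generate_study()`) stands in for field data, so the whole pipeline is
testable end to end: 3 cities, 110 urban + 50 periurban cells per city,
54 species with diet and habitat guilds, 3 exotic urban exploiters.

It is aimed at community ecologists analysing urbanization gradients
(or any two-habitat filter) from site-by-species count matrices.

## Worked example

```r
library(urbfilter)

study <- generate_study(generator_config(seed = 1))
nm <- null_model(study, null_model_config(n_sims = 999, seed = 1))
nm$summary
#>    city S_total S_periurban S_urban observed_loss_pct random_loss_pct
#> 1 city1      53          53      49             7.547          1.2635
#> 2 city2      53          53      48             9.434          0.3381
#> 3 city3      54          52      49             9.615          2.0097
#>   tolerance_richness n_avoiders n_chance_absent
#> 1                 49          4               0
#> 2                 48          5               0
#> 3                 49          5               0
```

Observed losses (7.5–9.6% of periurban species) far exceed the losses
expected from random dispersal (0.3–2.0%): the urban habitat filters
nonrandomly. The 4–5 avoiders per city are the species whose absence
random draws cannot explain.

```r
rd <- response_distance(study, "community")   # fourth-root, Bray-Curtis
permancova(rd$D, rd$data, covariate = "veg_cover",
           factor_random = "city", factor_fixed = "habitat",
           n_perms = 1999, seed = 1)
#>                    term  df      SS pseudo_F p_perm     p_MC CV_pct  denominator
#>               veg_cover   1  9.4456  47.3735 0.0005       NA   6.15     Residual
#>                    city   2 19.0238  47.7059 0.0005       NA  18.57     Residual
#>                 habitat   1  8.5510  48.7155 0.0005  0.00010  11.14 city:habitat
#>   ...
#>                Residual 468 93.3130                            63.63
```

The habitat term is tested over the city × habitat interaction; with 3
cities and 2 habitats only 8 distinguishable permutations exist, so its
Monte-Carlo p-value (p_MC ≈ 1e-4) is the one to read — urban and
periurban community structure differ strongly and consistently across
cities. SIMPER attributes the dissimilarity:

```r
sel <- study$cells$city == "city1"
simper_bc(fourth_root(study$abund)[sel, ], study$cells$habitat[sel])
#> SIMPER: average between-group Bray-Curtis dissimilarity = 0.7682 (cutoff 90%)
#>  item avg_periurban avg_urban contribution contribution_pct cumulative_pct
#>  sp48       0.14378   1.04928     0.049454           6.4377          6.438
#>  sp16       0.14000   0.84159     0.040390           5.2579         11.696
#>  sp23       0.06378   0.75524     0.037942           4.9391         16.635
#>  ...
```

The top three contributors are the three exotic exploiters (`sp16`,
`sp23`, `sp48`): rare in periurban cells, dominant in urban ones — the
classic signature of urbanization-driven biotic homogenization.

## The analysis workflow

The numbered scripts under `analysis/` run the full study on synthetic
data and write every table under `results/`:

```sh
Rscript analysis/01_simulate.R   --seed 1   # survey + ground truth
Rscript analysis/02_null_model.R --seed 1   # loss metrics + fates
Rscript analysis/03_permancova.R --seed 1   # 5 responses
Rscript analysis/04_simper.R                # species + guild tables
Rscript analysis/05_ordination.R            # centroid PCoA + vectors
```

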