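# Synthetic survey generator: determinism, design geometry, ground truth.

test_that("generator is deterministic and mirrors the study design", {
  cfg <- small_config()
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$abund, s2$abund)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$truth, s2$truth)

  # default design: 3 cities x (110 urban + 50 periurban) = 480 cells
  def <- generator_config()
  expect_equal(def$n_cities * (def$n_urban_cells + def$n_periurban_cells),
               480)
  expect_equal(def$n_species, 54)
  expect_equal(def$n_exotic, 3)

  tab <- table(s1$cells$city, s1$cells$habitat)
  expect_true(all(tab[, "urban"] == cfg$n_urban_cells))
  expect_true(all(tab[, "periurban"] == cfg$n_periurban_cells))
})

test_that("pool proportions normalize and fates follow largest remainder", {
  cfg <- generator_config(n_species = 10, avoider_fraction = 0.3,
                          exploiter_fraction = 0.2, seed = 4)
  po <- generate_pool(cfg)
  expect_equal(unname(rowSums(po$pool)), rep(1, cfg$n_cities))
  expect_equal(sum(po$truth$fate_class == "avoider"), 3)
  expect_equal(sum(po$truth$fate_class == "exploiter"), 2)
  # multiplier invariants
  av <- po$truth$urban_multiplier[po$truth$fate_class == "avoider"]
  ex <- po$truth$urban_multiplier[po$truth$fate_class == "exploiter"]
  to <- po$truth$urban_multiplier[po$truth$fate_class == "tolerant"]
  expect_true(all(av == 1 - cfg$filter_strength))
  expect_true(all(ex >= 1))
  expect_true(all(to == 1))
  # exotics are a subset of exploiters, capped at the exploiter count
  exo <- po$traits$origin == "exotic"
  expect_true(all(po$truth$fate_class[exo] == "exploiter"))
  expect_equal(sum(exo), min(cfg$n_exotic, sum(ex >= 1)))
})

test_that("complete filtering removes avoiders from every urban cell", {
  cfg <- small_config(filter_strength = 1)
  st <- generate_study(cfg)
  avoiders <- st$truth$species_id[st$truth$fate_class == "avoider"]
  urban <- st$cells$habitat == "urban"
  expect_true(all(st$abund[urban, avoiders] == 0))
  # but avoiders do occur in periurban cells somewhere
  expect_true(sum(st$abund[!urban, avoiders]) > 0)
})

test_that("urban cells have stochastically lower vegetation cover", {
  st <- generate_study(small_config(seed = 21))
  mu <- tapply(st$cells$veg_cover, st$cells$habitat, mean)
  expect_lt(mu[["urban"]], mu[["periurban"]])
})

test_that("expected urban/periurban abundance ratio tracks the multiplier", {
  # one large city so that per-species means are well estimated
  cfg <- generator_config(n_cities = 1, n_urban_cells = 3000,
                          n_periurban_cells = 3000, n_species = 12,
                          filter_strength = 0.5, veg_effect = 0,
                          mean_count_per_cell = 30, seed = 9)
  st <- generate_study(cfg)
  urban <- st$cells$habitat == "urban"
  mu_u <- colMeans(st$abund[urban, ])
  mu_p <- colMeans(st$abund[!urban, ])
  mult <- st$truth$urban_multiplier
  # ratio of urban to periurban per-species means, corrected for the
  # urban renormalization constant, should equal the multiplier
  po <- generate_pool(cfg)
  norm <- sum(po$pool[1, ] * mult)
  ratio <- (mu_u / mu_p) * norm
  se <- sqrt(apply(st$abund[urban, ], 2, var) / sum(urban)) / mu_p * norm +
    mult * sqrt(apply(st$abund[!urban, ], 2, var) / sum(!urban)) / mu_p
  expect_true(all(abs(ratio - mult) <= 3 * se + 0.02))
})

test_that("richness per cell grows stochastically with sampling effort", {
  rich_at <- function(mean_count) {
    st <- generate_study(small_config(mean_count_per_cell = mean_count,
                                      seed = 33))
    mean(rowSums(st$abund > 0))
  }
  r <- vapply(c(2, 10, 40), rich_at, 0)
  expect_true(all(diff(r) > 0))
  expect_true(all(r <= small_config()$n_species))
})

test_that("config validation rejects impossible settings", {
  expect_error(generator_config(n_species = 1), "n_species")
  expect_error(generator_config(avoider_fraction = 0.7,
                                exploiter_fraction = 0.5), "fraction")
  expect_error(generator_config(filter_strength = 1.2), "filter_strength")
  expect_error(generator_config(mean_count_per_cell = 0),
               "mean_count_per_cell")
})
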