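# Resampling null model: pools, simulations, fate classes, loss metrics.

test_that("build_pool normalizes periurban counts and sizes the community", {
  st <- tiny_study()
  po <- build_pool(st$abund, st$cells, "cityA")
  # periurban totals: sp1 = 3, sp2 = 12, sp3 = 3, sp4 = 4 -> sum 22
  expect_equal(unname(po$pool),
               c(3, 12, 3, 4) / 22)
  expect_equal(sum(po$pool), 1)
  # urban community size = all individuals over urban cells
  expect_equal(po$N, sum(st$abund[1:3, ]))
  expect_error(build_pool(st$abund, st$cells, "nowhere"), "unknown city")
})

test_that("pools are built independently per city", {
  cfg <- small_config(seed = 5)
  st <- generate_study(cfg)
  p1 <- build_pool(st$abund, st$cells, "city1")
  p2 <- build_pool(st$abund, st$cells, "city2")
  per1 <- st$cells$habitat == "periurban" & st$cells$city == "city1"
  expect_equal(unname(p1$pool),
               unname(colSums(st$abund[per1, names(p1$pool)]) /
                        sum(st$abund[per1, names(p1$pool)])))
  expect_false(identical(p1$pool, p2$pool))
})

test_that("simulated communities are multinomial draws of fixed size", {
  pool <- c(a = 0.5, b = 0.3, c = 0.2)
  set.seed(1)
  sims <- simulate_random_communities(pool, N = 200, n_sims = 999)
  expect_equal(dim(sims), c(999, 3))
  expect_true(all(rowSums(sims) == 200))
  # single-species pool is degenerate
  expect_true(all(simulate_random_communities(c(x = 1), 7, 50) == 7))
  # binomial moments: mean count ~ N p within 3 SE
  se <- sqrt(200 * pool * (1 - pool) / 999)
  expect_true(all(abs(colMeans(sims) - 200 * pool) <= 3 * se))
  expect_error(simulate_random_communities(c(0.5, 0.4), 10, 5), "sum to 1")
})

test_that("fate classification follows the mode-zero rule", {
  sims <- cbind(a = c(0, 0, 0, 1, 2),
                b = c(3, 2, 3, 3, 1),
                c = c(1, 1, 0, 0, 2))
  urban <- c(a = 0L, b = 0L, c = 5L)
  pool <- c(a = 0.2, b = 0.5, c = 0.3)
  f <- classify_fates(sims, urban, pool)
  expect_equal(f$fate, c("chance_absent", "avoider", "present"))
  # column c counts {0:2, 1:2, 2:1}: tie broken toward the smallest value
  expect_equal(f$sim_mode, c(0L, 3L, 0L))
  # tie {0,1} broken toward the smallest by default, largest on request
  tied <- cbind(t = c(0L, 1L, 0L, 1L))
  expect_equal(classify_fates(tied, c(t = 0L), c(t = 1))$fate,
               "chance_absent")
  expect_equal(classify_fates(tied, c(t = 0L), c(t = 1),
                              mode_tiebreak = "largest")$fate, "avoider")
})

test_that("loss metrics implement the observed/random/tolerance arithmetic", {
  # 20 periurban species, 8 absent from urban; simulated richness fixed 18
  nsp <- 25
  fates <- data.frame(species_id = paste0("s", 1:nsp),
                      pool_proportion = rep(1 / nsp, nsp),
                      urban_abundance = c(rep(0L, 8), rep(2L, 17)),
                      sim_mode = c(rep(1L, 4), rep(0L, 4), rep(1L, 17)),
                      fate = c(rep("avoider", 4), rep("chance_absent", 4),
                               rep("present", 17)))
  peri <- stats::setNames(c(rep(1, 20), rep(0, 5)), paste0("s", 1:nsp))
  sims <- matrix(0L, 10, nsp)
  sims[, 1:18] <- 1L
  lm <- loss_metrics(fates, sims, peri)
  expect_equal(lm$S_periurban, 20)
  expect_equal(lm$observed_loss_pct, 100 * 8 / 20)
  expect_equal(lm$random_loss_pct, 100 * (20 - 18) / 20)
  expect_equal(lm$tolerance_richness, 25 - 4)
  expect_error(loss_metrics(fates, sims, peri * 0), "periurban")
})

test_that("null model is deterministic and per-city seeds are stable", {
  st <- generate_study(small_config(seed = 8))
  cfg <- null_model_config(n_sims = 99, seed = 3)
  r1 <- null_model(st, cfg)
  r2 <- null_model(st, cfg)
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$fates, r2$fates)
  # dropping a city leaves the other cities' results untouched
  keep <- st$cells$city != "city3"
  st2 <- st
  st2$abund <- st$abund[keep, ]
  st2$cells <- st$cells[keep, ]
  r3 <- null_model(st2, cfg)
  expect_equal(r3$summary,
               r1$summary[r1$summary$city != "city3", ],
               ignore_attr = TRUE)
})

test_that("random loss decreases as the urban community size grows", {
  set.seed(2)
  pool <- as.numeric(rmultinom(1, 400, rep(1 / 20, 20))[, 1])
  pool <- pool / sum(pool)
  names(pool) <- paste0("s", 1:20)
  rl <- vapply(c(50, 200, 1000), function(N) {
    set.seed(10)
    sims <- simulate_random_communities(pool, N, 499)
    S_peri <- sum(pool > 0)
    100 * (S_peri - mean(rowSums(sims > 0))) / S_peri
  }, 0)
  expect_true(all(diff(rl) < 0))
})
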