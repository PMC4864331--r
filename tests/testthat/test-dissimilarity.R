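# Bray-Curtis, Gower centering and the PERMANCOVA engine.

test_that("bray_curtis matches the direct formula and handles zeros", {
  x <- rbind(a = c(2, 0, 1), b = c(0, 2, 1), c = c(2, 0, 1))
  D <- as.matrix(bray_curtis(x))
  expect_equal(D["a", "b"], 4 / 6, tolerance = 1e-12)
  expect_equal(D["a", "c"], 0)
  # disjoint rows
  y <- rbind(p = c(2, 0), q = c(0, 3))
  expect_equal(as.numeric(bray_curtis(y)), 1)
  # all-zero pair: distance 0 with a warning
  z <- rbind(u = c(0, 0), v = c(0, 0), w = c(1, 2))
  expect_warning(Dz <- as.matrix(bray_curtis(z)), "all-zero")
  expect_equal(Dz["u", "v"], 0)
  expect_error(bray_curtis(rbind(c(-1, 2), c(0, 1))), "negative")
  # agrees with vegan on random data
  set.seed(5)
  m <- matrix(rpois(60, 3), 10)
  expect_equal(as.matrix(bray_curtis(m)),
               as.matrix(vegan::vegdist(m, "bray")), tolerance = 1e-12)
})

test_that("gower_center yields the total sum of squares and centered rows", {
  D <- dist(c(0, 1, 2))
  G <- gower_center(D)
  expect_equal(sum(diag(G)), 2, tolerance = 1e-12)  # sum sq dev from mean
  expect_equal(unname(rowSums(G)), rep(0, 3), tolerance = 1e-12)
  # Euclidean input -> positive semidefinite G
  set.seed(3)
  pts <- matrix(rnorm(40), 20, 2)
  ev <- eigen(gower_center(dist(pts)), symmetric = TRUE,
              only.values = TRUE)$values
  expect_true(min(ev) > -1e-10 * max(ev))
})

test_that("one fixed factor with Euclidean distances reproduces ANOVA F", {
  set.seed(14)
  for (rep in 1:3) {
    y <- rnorm(24) + rep(c(0, 0.5, 1), each = 8)
    g <- rep(letters[1:3], each = 8)
    tab <- permancova(dist(y), data.frame(g = g), factor_fixed = "g",
                      n_perms = 0)
    expect_equal(tab$pseudo_F[1], oneway_F(y, g), tolerance = 1e-8)
    expect_equal(tab$df[1:2], c(2L, 21L))
  }
})

test_that("sequential SS always partition the trace of G", {
  set.seed(7)
  for (rep in 1:10) {
    n <- 30
    dat <- data.frame(v = runif(n), A = factor(sample(1:3, n, TRUE)),
                      B = factor(rep(c("u", "p"), n / 2)))
    m <- matrix(rpois(n * 8, 4), n)
    tab <- permancova(bray_curtis(m), dat, covariate = "v",
                      factor_random = "A", factor_fixed = "B",
                      n_perms = 0)
    tot <- tab$SS[tab$term == "Total"]
    expect_equal(sum(tab$SS[!(tab$term %in% "Total")]), tot,
                 tolerance = 1e-8 * tot)
  }
})

test_that("freedman-lane and raw permutation agree on a simple design", {
  set.seed(31)
  y <- rnorm(30) + rep(c(0, 0.8), 15)
  dat <- data.frame(g = factor(rep(c("a", "b"), 15)))
  D <- dist(y)
  p_fl <- permancova(D, dat, factor_fixed = "g", n_perms = 1999,
                     seed = 2, scheme = "freedman_lane")$p_perm[1]
  p_raw <- permancova(D, dat, factor_fixed = "g", n_perms = 1999,
                      seed = 3, scheme = "raw")$p_perm[1]
  se <- sqrt(p_raw * (1 - p_raw) / 1999)
  expect_lt(abs(p_fl - p_raw), 4 * se + 0.01)
})

test_that("sampled permutation p matches full enumeration on 6 cells", {
  set.seed(77)
  y <- c(1.1, 0.3, 0.8, 2.4, 2.0, 3.1)
  g <- rep(c("a", "b"), each = 3)
  p_exact <- exact_perm_p(y, g)
  tab <- permancova(dist(y), data.frame(g = g), factor_fixed = "g",
                    n_perms = 10000, seed = 4, scheme = "raw")
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(tab$p_perm[1] - p_exact), 3 * se + 2e-4)
})

test_that("type-I error of permutation p is nominal under the null", {
  set.seed(55)
  n <- 24
  dat <- data.frame(g = factor(rep(1:3, each = 8)))
  rej <- 0
  nrep <- 200
  for (i in seq_len(nrep)) {
    y <- rnorm(n)
    p <- permancova(dist(y), dat, factor_fixed = "g", n_perms = 199,
                    seed = i, scheme = "raw")$p_perm[1]
    rej <- rej + (p <= 0.05)
  }
  # binomial 99% bounds around 0.05
  bnd <- qbinom(c(0.005, 0.995), nrep, 0.05)
  expect_gte(rej, bnd[1])
  expect_lte(rej, bnd[2])
})

test_that("mixed design reports the habitat test over the interaction", {
  st <- generate_study(small_config(seed = 13))
  rd <- response_distance(st, "community")
  tab <- permancova(rd$D, rd$data, covariate = "veg_cover",
                    factor_random = "city", factor_fixed = "habitat",
                    n_perms = 99, seed = 1)
  expect_equal(tab$denominator[tab$term == "habitat"], "city:habitat")
  # few distinguishable permutations -> Monte-Carlo p always reported
  expect_equal(unname(attr(tab, "n_distinct")["habitat"]), 8)
  expect_false(is.na(tab$p_MC[tab$term == "habitat"]))
  expect_true(tab$p_MC[tab$term == "habitat"] > 0 &&
                tab$p_MC[tab$term == "habitat"] <= 1)
  # permutation p-values lie in (0, 1]
  pp <- tab$p_perm[!is.na(tab$p_perm)]
  expect_true(all(pp > 0 & pp <= 1))
  # CV percentages: nonnegative, sum to 100
  cv <- tab$CV_pct[!is.na(tab$CV_pct)]
  expect_true(all(cv >= 0))
  expect_equal(sum(cv), 100, tolerance = 1e-8)
  # denominator override is honoured
  tab2 <- permancova(rd$D, rd$data, covariate = "veg_cover",
                     factor_random = "city", factor_fixed = "habitat",
                     n_perms = 0, denom_map = list(habitat = "Residual"))
  expect_equal(tab2$denominator[tab2$term == "habitat"], "Residual")
  expect_gt(tab2$pseudo_F[tab2$term == "habitat"], 0)
})

test_that("confounded designs fail with the term named", {
  y <- rnorm(12)
  dat <- data.frame(A = factor(rep(1:2, each = 6)),
                    B = factor(rep(1:2, each = 6)))  # B aliases A
  expect_error(permancova(dist(y), dat, factor_random = "A",
                          factor_fixed = "B", n_perms = 0),
               "confounded")
})

test_that("pseudo-F is invariant to rigid translation of the point cloud", {
  set.seed(9)
  pts <- matrix(rnorm(40), 20, 2)
  dat <- data.frame(g = factor(rep(1:2, 10)))
  f1 <- permancova(dist(pts), dat, factor_fixed = "g",
                   n_perms = 0)$pseudo_F[1]
  f2 <- permancova(dist(pts + 100), dat, factor_fixed = "g",
                   n_perms = 0)$pseudo_F[1]
  expect_equal(f1, f2, tolerance = 1e-10)
})
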