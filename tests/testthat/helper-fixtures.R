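# Small in-code fixtures shared across test files.

# A minimal 6-cell, 4-species study spanning 1 city and both habitats.
tiny_study <- function() {
  abund <- matrix(c(
    5, 0, 1, 0,
    3, 1, 0, 0,
    4, 0, 2, 0,
    2, 3, 1, 1,
    1, 4, 0, 2,
    0, 5, 2, 1), nrow = 6, byrow = TRUE,
    dimnames = list(paste0("c", 1:6), paste0("sp", 1:4)))
  cells <- data.frame(cell_id = paste0("c", 1:6),
                      city = "cityA",
                      habitat = rep(c("urban", "periurban"), each = 3),
                      veg_cover = c(0.1, 0.2, 0.15, 0.5, 0.6, 0.7),
                      stringsAsFactors = FALSE)
  traits <- data.frame(species_id = paste0("sp", 1:4),
                       diet_guild = c("granivore", "insectivore",
                                      "granivore", "omnivore"),
                       habitat_guild = c("generalist", "open",
                                         "forest", "open"),
                       origin = c("exotic", "native", "native", "native"),
                       stringsAsFactors = FALSE)
  as_urb_study(abund, cells, traits)
}

# Small synthetic-study config for fast pipeline tests.
small_config <- function(..., seed = 11L) {
  generator_config(n_cities = 3L, n_urban_cells = 15L,
                   n_periurban_cells = 8L, n_species = 20L,
                   seed = seed, ...)
}

# One-way pseudo-F on a univariate Euclidean response, via classical
# ANOVA identities (independent oracle for permutation enumeration).
oneway_F <- function(y, g) {
  g <- factor(g)
  summary(stats::aov(y ~ g))[[1]][1, "F value"]
}

# Exact permutation p-value for a one-way design by full enumeration of
# all n! relabelings (n small).
exact_perm_p <- function(y, g) {
  n <- length(y)
  perms <- gtools_permutations(n)
  F0 <- oneway_F(y, g)
  Fs <- apply(perms, 1L, function(ix) oneway_F(y[ix], g))
  mean(Fs >= F0 - 1e-12)
}

# All permutations of 1..n (tiny n), without external packages.
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
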