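# Resampling null model for urban species absences.  For each city, random
# urban communities are assembled by drawing individuals (with replacement)
# from a pool whose species proportions match the periurban community, at
# the same total community size as the observed urban community.  A species
# absent from urban habitat is "chance-absent" when the mode of its
# simulated abundances is zero, and an "urban avoider" otherwise.

#' Configuration for the null model
#'
#' @param n_sims Number of random communities per city (default 999).
#' @param seed Master seed.  Each city uses its own generator seeded from
#'   the master seed and a hash of the city name, so adding or removing a
#'   city does not perturb the other cities' simulations.
#' @param mode_tiebreak Tie rule for the modal simulated abundance:
#'   `"smallest"` (default; conservative, favours chance-absent) or
#'   `"largest"`.
#' @param natives_only If `TRUE`, exotic species (per the trait table) are
#'   excluded from the periurban pool and from the metrics.
#' @return List of class `urb_null_config`.
#' @export
null_model_config <- function(n_sims = 999L, seed = 1L,
                              mode_tiebreak = c("smallest", "largest"),
                              natives_only = FALSE) {
  mode_tiebreak <- match.arg(mode_tiebreak)
  n_sims <- as.integer(n_sims)
  if (n_sims < 1L) stop("null_model_config: n_sims must be >= 1")
  structure(list(n_sims = n_sims, seed = as.integer(seed),
                 mode_tiebreak = mode_tiebreak,
                 natives_only = isTRUE(natives_only)),
            class = "urb_null_config")
}

# Deterministic 31-bit polynomial hash of a string, for per-city seeds.
.string_hash <- function(s) {
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Build a city's periurban species pool
#'
#' The pool proportions are the per-species periurban counts summed over
#' the city's periurban cells, normalized; the target community size N is
#' the total number of individuals over the city's urban cells.  Species
#' recorded in neither habitat of the city are excluded.
#'
#' @param abund Counts matrix, cells x species.
#' @param cells Cell metadata with `city` and `habitat`.
#' @param city City identifier.
#' @param natives_only,traits If `natives_only`, drop species whose
#'   `origin` is `"exotic"` in `traits` before building the pool.
#' @return List with `pool` (named proportions over recorded species,
#'   summing to 1), `N` (urban community size), `urban` and `periurban`
#'   per-species totals.
#' @export
build_pool <- function(abund, cells, city, natives_only = FALSE,
                       traits = NULL) {
  sel <- cells$city == city
  if (!any(sel)) stop("build_pool: unknown city '", city, "'")
  urb <- sel & cells$habitat == "urban"
  per <- sel & cells$habitat == "periurban"
  if (!any(urb) || !any(per))
    stop("build_pool: city '", city,
         "' needs at least one urban and one periurban cell")
  x <- abund
  if (natives_only) {
    if (is.null(traits)) stop("build_pool: natives_only requires traits")
    keep <- traits$species_id[tolower(traits$origin) != "exotic"]
    x <- x[, colnames(x) %in% keep, drop = FALSE]
  }
  urban_tot <- colSums(x[urb, , drop = FALSE])
  peri_tot <- colSums(x[per, , drop = FALSE])
  recorded <- urban_tot > 0 | peri_tot > 0
  urban_tot <- urban_tot[recorded]
  peri_tot <- peri_tot[recorded]
  if (sum(peri_tot) == 0)
    stop("build_pool: no periurban individuals recorded in city '",
         city, "'")
  list(pool = peri_tot / sum(peri_tot), N = sum(urban_tot),
       urban = urban_tot, periurban = peri_tot)
}

#' Simulate random urban communities
#'
#' Each simulated community is one multinomial draw of N individuals from
#' the pool proportions; all rows sum to N.
#'
#' @param pool Named proportion vector summing to 1.
#' @param N Community size (total individuals, >= 1).
#' @param n_sims Number of simulated communities.
#' @return Integer matrix, `n_sims` x species.
#' @export
simulate_random_communities <- function(pool, N, n_sims = 999L) {
  if (abs(sum(pool) - 1) > 1e-8)
    stop("simulate_random_communities: pool must sum to 1")
  if (N < 1) stop("simulate_random_communities: N must be >= 1")
  sims <- t(stats::rmultinom(n_sims, N, pool))
  colnames(sims) <- names(pool)
  sims
}

# Modal value of a vector of nonnegative integer counts.
.int_mode <- function(v, tiebreak = "smallest") {
  tab <- tabulate(v + 1L)
  hits <- which(tab == max(tab)) - 1L
  if (tiebreak == "smallest") min(hits) else max(hits)
}

#' Classify species fates from the simulated communities
#'
#' A species present in the urban habitat is `present`.  An absent species
#' is `chance_absent` when the mode of its simulated abundances is zero
#' (its absence is compatible with random draws from the periurban pool),
#' and `avoider` otherwise.
#'
#' @param sims Simulation matrix from [simulate_random_communities()].
#' @param urban_abund Named observed urban totals, aligned with `sims`
#'   columns.
#' @param pool Pool proportions (reported alongside the fates).
#' @param mode_tiebreak Tie rule for the mode, see [null_model_config()].
#' @return Data frame with `species_id`, `pool_proportion`,
#'   `urban_abundance`, `sim_mode`, `fate`.
#' @export
classify_fates <- function(sims, urban_abund, pool,
                           mode_tiebreak = "smallest") {
  stopifnot(identical(colnames(sims), names(urban_abund)))
  mode <- apply(sims, 2L, .int_mode, tiebreak = mode_tiebreak)
  fate <- ifelse(urban_abund > 0, "present",
                 ifelse(mode == 0L, "chance_absent", "avoider"))
  data.frame(species_id = colnames(sims),
             pool_proportion = as.numeric(pool),
             urban_abundance = as.integer(urban_abund),
             sim_mode = as.integer(mode),
             fate = fate, row.names = NULL, stringsAsFactors = FALSE)
}

#' Richness-loss metrics for one city
#'
#' * observed loss: percentage of periurban species absent from the urban
#'   habitat;
#' * random loss: percentage difference between the mean simulated urban
#'   richness and the periurban richness — the loss expected from random
#'   dispersal alone;
#' * tolerance richness: total recorded species minus the avoiders.
#'
#' @param fates Fate table from [classify_fates()].
#' @param sims Simulation matrix.
#' @param periurban_tot Named periurban per-species totals.
#' @return One-row data frame with `S_total`, `S_periurban`,
#'   `S_urban`, `observed_loss_pct`, `random_loss_pct`,
#'   `tolerance_richness`, `n_avoiders`, `n_chance_absent`.
#' @export
loss_metrics <- function(fates, sims, periurban_tot) {
  peri_pres <- periurban_tot > 0
  S_peri <- sum(peri_pres)
  if (S_peri == 0) stop("loss_metrics: no periurban species")
  S_total <- nrow(fates)
  S_urban <- sum(fates$urban_abundance > 0)
  obs_absent <- sum(peri_pres & fates$urban_abundance == 0)
  sim_rich <- rowSums(sims > 0)
  n_avoid <- sum(fates$fate == "avoider")
  data.frame(S_total = S_total, S_periurban = S_peri, S_urban = S_urban,
             observed_loss_pct = 100 * obs_absent / S_peri,
             random_loss_pct = 100 * (S_peri - mean(sim_rich)) / S_peri,
             tolerance_richness = S_total - n_avoid,
             n_avoiders = n_avoid,
             n_chance_absent = sum(fates$fate == "chance_absent"),
             row.names = NULL)
}

#' Run the null model for every city of a study
#'
#' @param study An `urb_study` list (or anything with `abund`, `cells`,
#'   optionally `traits`).
#' @param config An [null_model_config()] object.
#' @return List of class `urb_null_model` with `summary` (one row per
#'   city, see [loss_metrics()]) and `fates` (per-species records, all
#'   cities stacked with a `city` column).
#' @export
null_model <- function(study, config = null_model_config()) {
  stopifnot(inherits(config, "urb_null_config"))
  cities <- unique(study$cells$city)
  fates_all <- list()
  summ_all <- list()
  for (city in cities) {
    po <- build_pool(study$abund, study$cells, city,
                     natives_only = config$natives_only,
                     traits = study$traits)
    set.seed((config$seed + .string_hash(city)) %% 2147483647L)
    sims <- simulate_random_communities(po$pool, po$N, config$n_sims)
    fates <- classify_fates(sims, po$urban, po$pool,
                            mode_tiebreak = config$mode_tiebreak)
    summ <- cbind(city = city, loss_metrics(fates, sims, po$periurban))
    fates_all[[city]] <- cbind(city = city, fates)
    summ_all[[city]] <- summ
  }
  structure(list(summary = do.call(rbind, c(summ_all,
                                            make.row.names = FALSE)),
                 fates = do.call(rbind, c(fates_all,
                                          make.row.names = FALSE)),
                 config = config),
            class = "urb_null_model")
}

#' @export
print.urb_null_model <- function(x, ...) {
  cat("Urban-absence null model (", x$config$n_sims, " simulations)\n",
      sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}
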