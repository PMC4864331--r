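# End-to-end orchestration: simulate (or load) a study, run the null
# model, the five PERMANCOVA analyses, SIMPER per city and for guilds,
# and the centroid ordinations, writing every derived table as CSV plus
# a JSON manifest.  Deterministic given the seed.

#' Configuration for a full pipeline run
#'
#' All thresholds default to the standard settings of the analysis: 999
#' null-model simulations, 10,000 permutations, 90% SIMPER cutoff, 0.75
#' correlation-vector threshold.
#'
#' @param generator An [generator_config()] for synthetic data, or `NULL`
#'   when a study is supplied to [run_all()] directly.
#' @param seed Master seed for every stage.
#' @param n_sims Null-model simulations per city.
#' @param n_perms PERMANCOVA permutations.
#' @param cutoff SIMPER cumulative cutoff (fraction).
#' @param vector_threshold Correlation-vector display threshold.
#' @param responses PERMANCOVA responses to run.
#' @return List of class `urb_run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       seed = 1L,
                       n_sims = 999L,
                       n_perms = 10000L,
                       cutoff = 0.90,
                       vector_threshold = 0.75,
                       responses = c("richness", "evenness", "community",
                                     "diet_guilds", "habitat_guilds")) {
  structure(list(generator = generator, seed = as.integer(seed),
                 n_sims = as.integer(n_sims),
                 n_perms = as.integer(n_perms),
                 cutoff = cutoff, vector_threshold = vector_threshold,
                 responses = responses),
            class = "urb_run_config")
}

#' Run the complete analysis pipeline
#'
#' Stages: (1) generate or accept a study; (2) null model per city;
#' (3) PERMANCOVA for each configured response; (4) SIMPER between
#' habitats, per city at the species level and pooled at the guild
#' level; (5) PCoA of the city-by-habitat centroid distance matrices
#' with correlation vectors.  Every table is written under `out_dir`;
#' a `manifest.json` records the configuration and seeds.  A stage
#' failure aborts with the stage name; tables already written are kept.
#'
#' @param config An [run_config()] object.
#' @param out_dir Output directory.
#' @param study Optional `urb_study`; when `NULL`, one is generated from
#'   `config$generator`.
#' @return Invisibly, a list with all result objects.
#' @export
run_all <- function(config = run_config(), out_dir, study = NULL) {
  stopifnot(inherits(config, "urb_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)

  if (is.null(study)) {
    if (is.null(config$generator))
      stop("run_all: no study supplied and no generator configured")
    study <- stage("simulate", generate_study(config$generator))
    wcsv(data.frame(cell_id = rownames(study$abund), study$abund,
                    check.names = FALSE), "survey.csv")
    wcsv(study$cells, "cells.csv")
    wcsv(study$traits, "traits.csv")
    wcsv(study$truth, "ground_truth.csv")
  }
  guilds_needed <- any(config$responses %in% c("diet_guilds",
                                               "habitat_guilds"))
  if (guilds_needed && is.null(study$traits))
    stop("run_all: guild responses requested but the study has no ",
         "trait table")

  nm <- stage("nullmodel",
              null_model(study, null_model_config(n_sims = config$n_sims,
                                                  seed = config$seed)))
  wcsv(nm$summary, "loss_summary.csv")
  wcsv(nm$fates, "species_fates.csv")

  perm <- list()
  for (resp in config$responses) {
    rd <- stage(paste0("permancova_", resp), response_distance(study, resp))
    tab <- stage(paste0("permancova_", resp),
                 permancova(rd$D, rd$data, covariate = "veg_cover",
                            factor_random = "city",
                            factor_fixed = "habitat",
                            n_perms = config$n_perms,
                            seed = config$seed))
    perm[[resp]] <- tab
    wcsv(as.data.frame(tab), paste0("permancova_", resp, ".csv"))
  }

  simp <- list()
  y4 <- fourth_root(study$abund)
  for (city in unique(study$cells$city)) {
    sel <- study$cells$city == city
    st <- stage(paste0("simper_", city),
                simper_bc(y4[sel, , drop = FALSE],
                          study$cells$habitat[sel],
                          cutoff = config$cutoff))
    simp[[city]] <- st
    wcsv(as.data.frame(st), paste0("simper_species_", city, ".csv"))
  }
  if (guilds_needed) {
    for (rg in c("diet", "habitat")) {
      gm <- fourth_root(aggregate_guilds(study$abund, study$traits, rg))
      st <- stage(paste0("simper_", rg, "_guilds"),
                  simper_bc(gm, study$cells$habitat,
                            cutoff = config$cutoff))
      simp[[paste0(rg, "_guilds")]] <- st
      wcsv(as.data.frame(st), paste0("simper_", rg, "_guilds.csv"))
    }
  }

  ords <- list()
  grp <- interaction(study$cells$city, study$cells$habitat, drop = TRUE,
                     sep = "_")
  ord_levels <- c("community",
                  if (guilds_needed) c("diet_guilds", "habitat_guilds"))
  for (lvl in ord_levels) {
    mat <- switch(lvl,
                  community = y4,
                  diet_guilds = fourth_root(
                    aggregate_guilds(study$abund, study$traits, "diet")),
                  habitat_guilds = fourth_root(
                    aggregate_guilds(study$abund, study$traits, "habitat")))
    Dc <- stage(paste0("pcoa_", lvl),
                suppressWarnings(centroid_distances(bray_curtis(mat), grp)))
    ord <- stage(paste0("pcoa_", lvl), pcoa_ord(Dc, n_axes = 2L))
    means <- rowsum(mat, grp) / as.vector(table(grp))
    means <- means[rownames(as.matrix(Dc)), , drop = FALSE]
    vf <- stage(paste0("pcoa_", lvl),
                vector_fit(ord, means,
                           threshold = config$vector_threshold))
    ords[[lvl]] <- list(ordination = ord, vectors = vf)
    wcsv(data.frame(group = rownames(ord$coordinates), ord$coordinates,
                    check.names = FALSE),
         paste0("pcoa_", lvl, "_coordinates.csv"))
    wcsv(data.frame(axis = seq_along(ord$eigenvalues),
                    eigenvalue = ord$eigenvalues),
         paste0("pcoa_", lvl, "_eigenvalues.csv"))
    wcsv(vf, paste0("pcoa_", lvl, "_vectors.csv"))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("urbfilter")),
    seed = config$seed, n_sims = config$n_sims, n_perms = config$n_perms,
    cutoff = config$cutoff, vector_threshold = config$vector_threshold,
    responses = config$responses,
    generator = if (!is.null(config$generator))
      unclass(config$generator))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(study = study, null_model = nm, permancova = perm,
                 simper = simp, ordinations = ords))
}

#' Bar chart of observed, random and tolerance richness loss per city
#'
#' @param summary The `summary` table of an [null_model()] result.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_loss <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_loss requires ggplot2")
  long <- rbind(
    data.frame(city = summary$city, metric = "observed loss (%)",
               value = summary$observed_loss_pct),
    data.frame(city = summary$city, metric = "random loss (%)",
               value = summary$random_loss_pct))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$city, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = "% of periurban species lost", x = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Centroid ordination plot with correlation vectors
#'
#' @param ord An `urb_pcoa` object over group centroids.
#' @param vectors Optional [vector_fit()] table; only `shown` items are
#'   drawn.
#' @param scale_vectors Multiplier applied to the unit-correlation
#'   vectors for display.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_ordination <- function(ord, vectors = NULL, scale_vectors = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_ordination requires ggplot2")
  co <- as.data.frame(ord$coordinates)
  co$group <- rownames(ord$coordinates)
  p <- ggplot2::ggplot(co, ggplot2::aes(x = .data$PCoA1, y = .data$PCoA2,
                                        label = .data$group)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(vjust = -1) +
    ggplot2::labs(
      x = sprintf("PCoA1 (%.1f%%)", ord$pct_explained[1]),
      y = sprintf("PCoA2 (%.1f%%)", ord$pct_explained[2])) +
    ggplot2::theme_minimal()
  if (!is.null(vectors)) {
    sh <- vectors[vectors$shown, , drop = FALSE]
    if (nrow(sh)) {
      sc <- if (is.null(scale_vectors))
        0.8 * max(abs(as.matrix(co[, 1:2]))) else scale_vectors
      sh$x <- sc * sh[[2L]]
      sh$y <- sc * sh[[3L]]
      p <- p +
        ggplot2::geom_segment(data = sh,
                              ggplot2::aes(x = 0, y = 0, xend = .data$x,
                                           yend = .data$y),
                              inherit.aes = FALSE,
                              arrow = grid::arrow(length =
                                                    grid::unit(2, "mm"))) +
        ggplot2::geom_text(data = sh,
                           ggplot2::aes(x = .data$x, y = .data$y,
                                        label = .data$item),
                           inherit.aes = FALSE, vjust = 1.5, size = 3)
    }
  }
  p
}
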