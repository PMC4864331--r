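# Shared domain types and transforms: site-by-species abundance matrices,
# per-cell metadata, per-species traits, diversity indices and guild
# aggregation.  The canonical container is a plain integer matrix with
# cells in rows and species in columns, as in vegan.

#' Canonical guild labels
#'
#' The two mutually exclusive resource groups used to classify species:
#' seven diet guilds and four preferred-habitat guilds.  Guild matching
#' throughout the package is case-insensitive against these labels.
#'
#' @format Character vectors.
#' @name guild_labels
NULL

#' @rdname guild_labels
#' @export
DIET_GUILDS <- c("carnivore", "carrion", "frugivore", "granivore",
                 "insectivore", "nectarivore", "omnivore")

#' @rdname guild_labels
#' @export
HABITAT_GUILDS <- c("forest", "open", "water_wetland", "generalist")

#' Read a point-count survey from delimited text
#'
#' Reads the three tables of a survey: the cells-by-species count matrix,
#' the per-cell metadata (city, habitat, vegetation cover) and, optionally,
#' the per-species trait table (diet guild, preferred-habitat guild,
#' origin).  All files are UTF-8 CSV with a mandatory header; the first
#' column of each file is the row identifier (`cell_id` or `species_id`).
#'
#' @param survey_path Path to the cells-by-species count CSV.
#' @param cells_path Path to the per-cell metadata CSV with columns
#'   `cell_id`, `city`, `habitat` (`urban`/`periurban`) and `veg_cover`.
#' @param traits_path Optional path to the per-species trait CSV with
#'   columns `species_id`, `diet_guild`, `habitat_guild`, `origin`.
#' @return A list of class `urb_study` with elements `abund` (integer
#'   matrix, cells x species), `cells` (data frame) and `traits` (data
#'   frame or `NULL`).  Species present in the survey but missing from the
#'   trait table are reported with a warning.
#' @export
read_survey <- function(survey_path, cells_path, traits_path = NULL) {
  surv <- utils::read.csv(survey_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(surv) < 2L)
    stop("survey file needs a cell_id column plus at least one species")
  cell_id <- as.character(surv[[1L]])
  abund <- as.matrix(surv[, -1L, drop = FALSE])
  storage.mode(abund) <- "double"
  rownames(abund) <- cell_id

  cells <- utils::read.csv(cells_path, stringsAsFactors = FALSE)
  need <- c("cell_id", "city", "habitat", "veg_cover")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cells file is missing column(s): ", paste(miss, collapse = ", "))

  traits <- NULL
  if (!is.null(traits_path)) {
    traits <- utils::read.csv(traits_path, stringsAsFactors = FALSE)
    tneed <- c("species_id", "diet_guild", "habitat_guild", "origin")
    tmiss <- setdiff(tneed, names(traits))
    if (length(tmiss))
      stop("traits file is missing column(s): ",
           paste(tmiss, collapse = ", "))
  }
  as_urb_study(abund, cells, traits)
}

#' Assemble and validate a study object
#'
#' Validates a cells-by-species count matrix against its metadata: counts
#' must be nonnegative integers, identifiers unique, and every survey row
#' must have exactly one metadata row.  Rows of `abund` are reordered to
#' match `cells$cell_id`.
#'
#' @param abund Numeric matrix of counts, cells in rows, species in
#'   columns, with row and column names.
#' @param cells Data frame with `cell_id`, `city`, `habitat`, `veg_cover`.
#' @param traits Optional data frame with `species_id`, `diet_guild`,
#'   `habitat_guild`, `origin`.
#' @return A validated list of class `urb_study`.
#' @export
as_urb_study <- function(abund, cells, traits = NULL) {
  abund <- as.matrix(abund)
  if (is.null(rownames(abund)) || is.null(colnames(abund)))
    stop("abundance matrix needs cell row names and species column names")
  if (anyDuplicated(rownames(abund)))
    stop("duplicate cell_id in survey: ",
         paste(unique(rownames(abund)[duplicated(rownames(abund))]),
               collapse = ", "))
  if (anyDuplicated(colnames(abund)))
    stop("duplicate species_id in survey")
  bad <- which(abund < 0 | abund != round(abund), arr.ind = TRUE)
  if (nrow(bad))
    stop("negative or non-integer abundance at cell '",
         rownames(abund)[bad[1L, 1L]], "', species '",
         colnames(abund)[bad[1L, 2L]], "'")

  cells$cell_id <- as.character(cells$cell_id)
  if (anyDuplicated(cells$cell_id))
    stop("duplicate cell_id in cell metadata")
  if (!setequal(rownames(abund), cells$cell_id))
    stop("cell_id sets of survey and cell metadata differ")
  if (any(cells$veg_cover < 0 | cells$veg_cover > 1, na.rm = TRUE))
    stop("veg_cover must lie in [0, 1]")
  hab <- tolower(as.character(cells$habitat))
  if (!all(hab %in% c("urban", "periurban")))
    stop("habitat must be 'urban' or 'periurban'")
  cells$habitat <- hab
  abund <- abund[match(cells$cell_id, rownames(abund)), , drop = FALSE]

  if (!is.null(traits)) {
    traits$species_id <- as.character(traits$species_id)
    if (anyDuplicated(traits$species_id))
      stop("duplicate species_id in trait table")
    missing_sp <- setdiff(colnames(abund), traits$species_id)
    if (length(missing_sp))
      warning("species without trait records: ",
              paste(missing_sp, collapse = ", "))
  }
  structure(list(abund = abund, cells = cells, traits = traits),
            class = "urb_study")
}

#' @export
print.urb_study <- function(x, ...) {
  cat("Point-count study: ", nrow(x$abund), " cells x ", ncol(x$abund),
      " species\n", sep = "")
  tab <- table(x$cells$city, x$cells$habitat)
  print(tab)
  invisible(x)
}

#' Write the tables of a study to CSV files
#'
#' @param study An `urb_study` list.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(dir, "survey.csv")
  surv <- data.frame(cell_id = rownames(study$abund), study$abund,
                     check.names = FALSE)
  utils::write.csv(surv, sp, row.names = FALSE)
  cp <- file.path(dir, "cells.csv")
  utils::write.csv(study$cells, cp, row.names = FALSE)
  paths <- c(sp, cp)
  if (!is.null(study$traits)) {
    tp <- file.path(dir, "traits.csv")
    utils::write.csv(study$traits, tp, row.names = FALSE)
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' Fourth-root transform of an abundance matrix
#'
#' The standard severe down-weighting of dominant species before
#' Bray-Curtis community-structure analyses: every entry y is replaced by
#' y^(1/4).  Zeros are preserved; presence/absence (0/1) matrices are
#' fixed points.
#'
#' @param x Nonnegative numeric matrix (cells x species).
#' @return Matrix of the same shape with transformed entries.
#' @export
fourth_root <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("fourth_root: negative abundances")
  x^0.25
}

#' Per-cell richness and evenness
#'
#' Species richness is the count of species with nonzero abundance in the
#' cell.  Evenness is Pielou's J' = H'/ln(S), with H' the Shannon index
#' (natural logarithm) of the within-cell relative abundances; it is
#' undefined (NA) for cells with S <= 1.  Shannon diversity is computed
#' with [vegan::diversity()].
#'
#' @param x Matrix of raw (untransformed) counts, cells x species.
#' @param index Evenness index: `"pielou"` (default) or `"shannon"`
#'   (returns raw H' instead of J').
#' @return Data frame with columns `cell_id`, `richness`, `evenness`.
#' @export
richness_evenness <- function(x, index = c("pielou", "shannon")) {
  index <- match.arg(index)
  x <- as.matrix(x)
  if (any(x < 0)) stop("richness_evenness: negative abundances")
  S <- rowSums(x > 0)
  H <- vegan::diversity(x, index = "shannon")
  ev <- switch(index,
               pielou = ifelse(S > 1, H / log(S), NA_real_),
               shannon = ifelse(S > 1, H, NA_real_))
  data.frame(cell_id = rownames(x), richness = as.integer(S),
             evenness = as.numeric(ev), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Aggregate species columns into guilds
#'
#' Sums member-species abundances per cell within each guild of the chosen
#' resource group (diet or preferred habitat).  Column order follows the
#' canonical guild list ([DIET_GUILDS], [HABITAT_GUILDS]); guilds with no
#' member species are dropped.  Per-cell totals are conserved.
#'
#' @param x Abundance matrix, cells x species.
#' @param traits Trait data frame with `species_id` and the guild column.
#' @param resource_group `"diet"` or `"habitat"`.
#' @return Matrix, cells x guilds.
#' @export
aggregate_guilds <- function(x, traits, resource_group = c("diet", "habitat")) {
  resource_group <- match.arg(resource_group)
  x <- as.matrix(x)
  col <- paste0(switch(resource_group, diet = "diet", habitat = "habitat"),
                "_guild")
  canonical <- switch(resource_group, diet = DIET_GUILDS,
                      habitat = HABITAT_GUILDS)
  g <- tolower(as.character(traits[[col]][match(colnames(x),
                                                traits$species_id)]))
  unmapped <- colnames(x)[is.na(g) | !(g %in% canonical)]
  if (length(unmapped))
    stop("species not mapped to a ", resource_group, " guild: ",
         paste(unmapped, collapse = ", "))
  agg <- t(rowsum(t(x), group = g))
  agg[, intersect(canonical, colnames(agg)), drop = FALSE]
}
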