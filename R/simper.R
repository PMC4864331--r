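# Similarity percentages: exact decomposition of the average between-group
# Bray-Curtis dissimilarity over species (or guilds).  For every
# between-group pair of cells (j, k), species i takes the share
# |y_ij - y_ik| / sum_s (y_sj + y_sk); shares sum to the pair's
# Bray-Curtis value, and contributions averaged over all pairs sum to the
# average between-group dissimilarity.

#' SIMPER decomposition of between-group Bray-Curtis dissimilarity
#'
#' @param x Nonnegative matrix (cells x species or cells x guilds),
#'   already transformed if desired (fourth-root for community structure).
#' @param groups Two-level factor (or character) over the rows of `x`.
#' @param cutoff Cumulative-contribution cutoff as a fraction: the table
#'   is truncated at the first item whose cumulative percentage reaches
#'   the cutoff, so totals slightly exceed it.  Default 0.90.
#' @param raw_scale_means If `TRUE`, report group average abundances on
#'   the raw scale of `x` regardless of transformation applied by the
#'   caller (the default reports means of `x` as supplied).
#' @param x_raw Raw matrix used only when `raw_scale_means = TRUE`.
#' @return Data frame of class `urb_simper`, items sorted by decreasing
#'   contribution and truncated at the cutoff, with columns `item`,
#'   `avg_<group1>`, `avg_<group2>`, `contribution`, `contribution_pct`,
#'   `cumulative_pct`.  Attributes: `average_dissimilarity`, `full`
#'   (untruncated table, percentages summing to 100), `cutoff`.
#' @export
simper_bc <- function(x, groups, cutoff = 0.90, raw_scale_means = FALSE,
                      x_raw = NULL) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("simper_bc: negative abundances")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("item", seq_len(ncol(x)))
  g <- factor(groups)
  if (nlevels(g) != 2L)
    stop("simper_bc: 'groups' must have exactly two levels")
  i1 <- which(g == levels(g)[1L])
  i2 <- which(g == levels(g)[2L])
  if (!length(i1) || !length(i2))
    stop("simper_bc: empty group")

  tot <- rowSums(x)
  contrib <- numeric(ncol(x))
  n_pairs <- length(i1) * length(i2)
  avg_d <- 0
  X2 <- t(x[i2, , drop = FALSE])          # species x n2
  for (j in i1) {
    den <- tot[j] + tot[i2]               # length n2
    if (any(den == 0))
      stop("simper_bc: pair of all-zero cells; contributions undefined")
    shares <- abs(x[j, ] - X2) / rep(den, each = ncol(x))
    contrib <- contrib + rowSums(shares)
    avg_d <- avg_d + sum(shares)
  }
  contrib <- contrib / n_pairs
  avg_d <- avg_d / n_pairs
  if (avg_d == 0)
    stop("simper_bc: all between-group dissimilarities are zero")

  m1 <- colMeans(if (raw_scale_means) as.matrix(x_raw)[i1, , drop = FALSE]
                 else x[i1, , drop = FALSE])
  m2 <- colMeans(if (raw_scale_means) as.matrix(x_raw)[i2, , drop = FALSE]
                 else x[i2, , drop = FALSE])
  ord <- order(contrib, decreasing = TRUE)
  full <- data.frame(item = colnames(x)[ord],
                     avg_1 = m1[ord], avg_2 = m2[ord],
                     contribution = contrib[ord],
                     contribution_pct = 100 * contrib[ord] / sum(contrib),
                     stringsAsFactors = FALSE, row.names = NULL)
  names(full)[2:3] <- paste0("avg_", levels(g))
  full$cumulative_pct <- cumsum(full$contribution_pct)
  keep <- seq_len(which(full$cumulative_pct >= 100 * cutoff)[1L])
  out <- full[keep, , drop = FALSE]
  attr(out, "average_dissimilarity") <- avg_d
  attr(out, "full") <- full
  attr(out, "cutoff") <- cutoff
  attr(out, "groups") <- levels(g)
  class(out) <- c("urb_simper", "data.frame")
  out
}

#' @export
print.urb_simper <- function(x, ...) {
  cat("SIMPER: average between-group Bray-Curtis dissimilarity = ",
      format(attr(x, "average_dissimilarity"), digits = 4),
      " (cutoff ", 100 * attr(x, "cutoff"), "%)\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
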