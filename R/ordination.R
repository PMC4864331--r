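# Principal coordinates analysis and centroid-level distance matrices.
# Both operate on the Gower-centered inner-product matrix, so semi-metric
# inputs (Bray-Curtis) are handled: negative eigenvalues are reported but
# not embedded, and negative squared centroid distances are clamped to 0.

#' Principal coordinates analysis
#'
#' Eigendecomposition of the Gower-centered matrix of `D`; coordinates
#' are eigenvectors scaled by the square root of their (positive)
#' eigenvalues.  Negative eigenvalues (possible for semi-metrics such as
#' Bray-Curtis) are listed but their axes are not embedded; percentages
#' of variation explained are computed over the positive eigenvalues
#' only.  No Lingoes/Cailliez correction is applied by default.
#'
#' @param D Distance matrix (`dist` or square matrix).
#' @param n_axes Number of axes to return (default 2); reduced with a
#'   warning if fewer positive eigenvalues exist.
#' @param correction `"none"` (default) or `"lingoes"` (adds the constant
#'   2|min eigenvalue| to all off-diagonal squared distances).
#' @return List of class `urb_pcoa` with `coordinates` (n x k matrix),
#'   `eigenvalues` (all, decreasing), `pct_explained` (per returned
#'   axis), `n_negative`.
#' @export
pcoa_ord <- function(D, n_axes = 2L, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  Dm <- as.matrix(D)
  if (correction == "lingoes") {
    ev0 <- eigen(gower_center(Dm), symmetric = TRUE,
                 only.values = TRUE)$values
    cmin <- min(ev0)
    if (cmin < 0) {
      D2 <- Dm^2 + 2 * abs(cmin)
      diag(D2) <- 0
      Dm <- sqrt(D2)
    }
  }
  G <- gower_center(Dm)
  e <- eigen(G, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values), 1e-300)
  pos <- which(e$values > tol)
  k <- min(n_axes, length(pos))
  if (k < n_axes)
    warning("pcoa_ord: only ", length(pos),
            " positive eigenvalues; returning ", k, " axes")
  coords <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(k)]]), k)
  rownames(coords) <- rownames(Dm)
  colnames(coords) <- paste0("PCoA", seq_len(k))
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 pct_explained = 100 * e$values[pos[seq_len(k)]] /
                   sum(e$values[pos]),
                 n_negative = sum(e$values < -tol)),
            class = "urb_pcoa")
}

#' @export
print.urb_pcoa <- function(x, ...) {
  cat("PCoA: ", ncol(x$coordinates), " axes explaining ",
      format(sum(x$pct_explained), digits = 4),
      "% of the positive-eigenvalue variation; ",
      x$n_negative, " negative eigenvalue(s)\n", sep = "")
  invisible(x)
}

#' Distance matrix among group centroids
#'
#' Squared distances between group centroids are computed in the full
#' principal-coordinate space directly from the Gower-centered matrix,
#' including negative-eigenvalue components with their sign:
#' d^2(g, h) = mean(G[g, g]) + mean(G[h, h]) - 2 mean(G[g, h]).  For
#' semi-metric inputs a squared centroid distance can be negative; it is
#' clamped to zero with a warning.  Singleton groups recover the original
#' distances.
#'
#' @param D Distance matrix over cells.
#' @param groups Group labels over the rows of `D`.
#' @return A `dist` over the group levels.
#' @export
centroid_distances <- function(D, groups) {
  G <- gower_center(D)
  g <- factor(groups)
  if (length(g) != nrow(G))
    stop("centroid_distances: group labels do not match the matrix")
  lv <- levels(g)
  m <- length(lv)
  idx <- split(seq_along(g), g)
  S <- matrix(0, m, m, dimnames = list(lv, lv))
  for (a in seq_len(m)) for (b in seq_len(m))
    S[a, b] <- mean(G[idx[[a]], idx[[b]], drop = FALSE])
  d2 <- outer(diag(S), diag(S), "+") - 2 * S
  if (any(d2 < -1e-10)) {
    warning("centroid_distances: negative squared centroid distance",
            " clamped to 0 (semi-metric input)")
  }
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  stats::as.dist(sqrt(d2))
}

#' Correlation vectors of items with ordination axes
#'
#' Pearson (or Spearman) correlation of each item's abundance with each
#' plotted axis; an item is flagged `shown` when its maximum absolute
#' correlation strictly exceeds the threshold.  Items with zero variance
#' get missing correlations and are never shown.
#'
#' @param ord An `urb_pcoa` object (or a numeric coordinate matrix).
#' @param x Abundance matrix whose rows align with the ordination rows
#'   (cells, or group means for a centroid-level ordination).
#' @param threshold Display threshold on max |r| (strict `>`), default
#'   0.75.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data frame with `item`, one `r_<axis>` column per axis,
#'   `max_abs_r`, `shown`.
#' @export
vector_fit <- function(ord, x, threshold = 0.75,
                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  coords <- if (inherits(ord, "urb_pcoa")) ord$coordinates else
    as.matrix(ord)
  x <- as.matrix(x)
  if (nrow(x) != nrow(coords))
    stop("vector_fit: rows of 'x' do not align with the ordination")
  r <- suppressWarnings(stats::cor(x, coords, method = method))
  r[!is.finite(r)] <- NA_real_
  max_abs <- apply(abs(r), 1L, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  out <- data.frame(item = colnames(x), r,
                    max_abs_r = max_abs,
                    shown = !is.na(max_abs) & max_abs > threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[seq_len(ncol(r)) + 1L] <- paste0("r_", colnames(coords))
  out
}
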