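# Distance-based linear models on Gower-centered inner-product matrices
# (McArdle-Anderson machinery): sequential sums of squares via projection
# onto an orthonormalized design, mixed-model pseudo-F denominators,
# permutation p-values (Freedman-Lane residual permutation under the
# reduced model, or raw permutation), Monte-Carlo p-values from weighted
# chi-square mixtures, and method-of-moments components of variation.

#' Bray-Curtis dissimilarity matrix
#'
#' D[j,k] = sum_i |y_ij - y_ik| / sum_i (y_ij + y_ik), computed with
#' [vegan::vegdist()].  A pair of all-zero cells, for which the quotient
#' is undefined, is assigned distance 0 with a warning.
#'
#' @param x Nonnegative matrix (cells x species), already transformed if
#'   desired (e.g. [fourth_root()]).
#' @return A `dist` object.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("bray_curtis: negative abundances")
  D <- suppressWarnings(as.matrix(vegan::vegdist(x, method = "bray")))
  if (any(!is.finite(D))) {
    warning("bray_curtis: all-zero cell pair(s); distance set to 0")
    D[!is.finite(D)] <- 0
  }
  stats::as.dist(D)
}

#' Gower-center a distance matrix
#'
#' Transforms a distance matrix into the centered inner-product matrix
#' G = J A J, where A = -D^2/2 and J = I - 11'/n.  The trace of G is the
#' total sum of squares of the implied point configuration; row sums are
#' zero; for Euclidean D, G is positive semidefinite.
#'
#' @param D A `dist` object or square symmetric matrix.
#' @return Symmetric n x n matrix.
#' @export
gower_center <- function(D) {
  D <- as.matrix(D)
  if (any(!is.finite(D))) stop("gower_center: non-finite distances")
  A <- -0.5 * D^2
  rm <- rowMeans(A)
  G <- A - outer(rm, rep(1, nrow(A))) - outer(rep(1, nrow(A)), rm) + mean(A)
  (G + t(G)) / 2
}

# ---- internal design machinery -------------------------------------------

# Build the ordered term list for the cov + random A + fixed B design.
# Each element: label, a column matrix spanning the term's raw space, and
# the categorical factors involved (for CV multipliers / MC perm counts).
.build_terms <- function(data, covariate, factor_random, factor_fixed) {
  n <- nrow(data)
  terms <- list()
  add <- function(label, cols, cat_levels) {
    terms[[length(terms) + 1L]] <<- list(label = label, cols = cols,
                                         cat_levels = cat_levels)
  }
  xc <- NULL
  if (!is.null(covariate)) {
    xc <- as.numeric(data[[covariate]])
    if (anyNA(xc)) stop("permancova: missing covariate values")
    xc <- xc - mean(xc)
    add(covariate, matrix(xc, ncol = 1L), integer(0))
  }
  MA <- NULL
  if (!is.null(factor_random)) {
    fA <- factor(data[[factor_random]])
    if (nlevels(fA) < 2) stop("permancova: '", factor_random,
                              "' needs >= 2 levels")
    MA <- stats::model.matrix(~fA)[, -1L, drop = FALSE]
    add(factor_random, MA, stats::setNames(nlevels(fA), factor_random))
  }
  MB <- NULL
  if (!is.null(factor_fixed)) {
    fB <- factor(data[[factor_fixed]])
    if (nlevels(fB) < 2) stop("permancova: '", factor_fixed,
                              "' needs >= 2 levels")
    MB <- stats::model.matrix(~fB)[, -1L, drop = FALSE]
    add(factor_fixed, MB, stats::setNames(nlevels(fB), factor_fixed))
  }
  cross <- function(U, V) {
    out <- matrix(0, n, ncol(U) * ncol(V))
    k <- 0L
    for (i in seq_len(ncol(U))) for (j in seq_len(ncol(V))) {
      k <- k + 1L
      out[, k] <- U[, i] * V[, j]
    }
    out
  }
  if (!is.null(xc) && !is.null(MA))
    add(paste(covariate, factor_random, sep = ":"), xc * MA,
        stats::setNames(nlevels(factor(data[[factor_random]])),
                        factor_random))
  if (!is.null(xc) && !is.null(MB))
    add(paste(covariate, factor_fixed, sep = ":"), xc * MB,
        stats::setNames(nlevels(factor(data[[factor_fixed]])),
                        factor_fixed))
  AB <- NULL
  if (!is.null(MA) && !is.null(MB)) {
    AB <- cross(MA, MB)
    lv <- c(nlevels(factor(data[[factor_random]])),
            nlevels(factor(data[[factor_fixed]])))
    names(lv) <- c(factor_random, factor_fixed)
    add(paste(factor_random, factor_fixed, sep = ":"), AB, lv)
    if (!is.null(xc))
      add(paste(covariate, factor_random, factor_fixed, sep = ":"),
          xc * AB, lv)
  }
  terms
}

# Sequentially orthonormalize the term spaces against the intercept and
# all earlier terms; returns per-term orthonormal bases and dfs.
.orthonormal_bases <- function(terms, n, tol = 1e-9) {
  Q <- matrix(1 / sqrt(n), n, 1L)
  bases <- vector("list", length(terms))
  for (i in seq_along(terms)) {
    Z <- terms[[i]]$cols
    nrm <- sqrt(colSums(Z^2))
    nrm[nrm == 0] <- 1
    Z <- sweep(Z, 2L, nrm, "/")
    for (pass in 1:2)  # double Gram-Schmidt for numerical stability
      Z <- Z - Q %*% crossprod(Q, Z)
    qz <- qr(Z)
    r <- sum(abs(diag(qz$qr)[seq_len(min(dim(Z)))]) > tol)
    if (r == 0L)
      stop("permancova: term '", terms[[i]]$label,
           "' is completely confounded with earlier terms")
    V <- qr.Q(qz)[, seq_len(r), drop = FALSE]
    bases[[i]] <- V
    Q <- cbind(Q, V)
  }
  list(bases = bases, Qfull = Q)
}

# Quadratic-form sums v'Gv over the columns of V.
.qf_sum <- function(V, G) colSums(V * (G %*% V))

# ---- main engine ---------------------------------------------------------

#' Permutational multivariate analysis of covariance on a distance matrix
#'
#' Partitions the total sum of squares of a Gower-centered distance matrix
#' sequentially (Type I) over the terms of the design
#' `covariate + random + fixed + covariate:random + covariate:fixed +
#' random:fixed + covariate:random:fixed` (terms whose constituents are
#' absent are dropped).  Pseudo-F ratios use a mixed-model denominator
#' table: by default every term is tested over the residual, except the
#' fixed factor, which is tested over its interaction with the random
#' factor when that interaction is in the model.  P-values come from
#' permutation (Freedman-Lane residual permutation under the reduced
#' model, or raw row/column permutation of the distance matrix) and,
#' for terms with fewer distinguishable permutations than `mc_threshold`,
#' from a Monte-Carlo approximation that draws the null pseudo-F from
#' ratios of chi-square mixtures weighted by the eigenvalues of the
#' residual-projected G.  Components of variation are method-of-moments
#' estimates from the expected mean squares of the balanced design,
#' negatives truncated to zero and rescaled to percentages.
#'
#' @param D Distance matrix (`dist` or square matrix) over cells.
#' @param data Data frame of cell metadata, rows aligned with `D`.
#' @param covariate Optional name of a numeric covariate column.
#' @param factor_random Optional name of the random factor column (city).
#' @param factor_fixed Optional name of the fixed factor column (habitat).
#' @param n_perms Number of permutations (0 skips permutation p-values).
#' @param seed RNG seed for permutations and Monte-Carlo draws.
#' @param scheme Permutation scheme, `"freedman_lane"` (default) or
#'   `"raw"`.
#' @param denom_map Optional named list overriding the denominator of any
#'   term (values are term labels or `"Residual"`).
#' @param mc_draws Monte-Carlo draws for the chi-square-mixture p-value.
#' @param mc_threshold Report the Monte-Carlo p-value for a term when its
#'   number of distinguishable permutations is below this threshold.
#' @param mc_all If `TRUE`, report the Monte-Carlo p-value for every term.
#' @return Data frame of class `permancova`: one row per term plus
#'   `Residual` and `Total`, with columns `term`, `df`, `SS`, `MS`,
#'   `pseudo_F`, `p_perm`, `p_MC`, `CV_pct`, `denominator`.
#' @references McArdle, B.H. & Anderson, M.J. (2001) Ecology 82:290-297;
#'   Anderson, M.J. & Robinson, J. (2003) Aust. N.Z. J. Stat. 45:301-318.
#' @export
permancova <- function(D, data, covariate = NULL, factor_random = NULL,
                       factor_fixed = NULL, n_perms = 10000L, seed = 1L,
                       scheme = c("freedman_lane", "raw"),
                       denom_map = NULL, mc_draws = 10000L,
                       mc_threshold = 1000L, mc_all = FALSE) {
  scheme <- match.arg(scheme)
  G <- gower_center(D)
  n <- nrow(G)
  if (nrow(data) != n)
    stop("permancova: data rows do not match the distance matrix")
  if (is.null(covariate) && is.null(factor_random) &&
      is.null(factor_fixed))
    stop("permancova: no model terms supplied")

  terms <- .build_terms(data, covariate, factor_random, factor_fixed)
  labels <- vapply(terms, `[[`, "", "label")
  ob <- .orthonormal_bases(terms, n)
  bases <- ob$bases
  dfs <- vapply(bases, ncol, 0L)
  K <- length(terms)

  trG <- sum(diag(G))
  SS <- vapply(seq_len(K), function(i) sum(.qf_sum(bases[[i]], G)), 0)
  df_res <- n - 1L - sum(dfs)
  if (df_res < 1L) stop("permancova: no residual degrees of freedom")
  SS_res <- trG - sum(SS)
  MS <- SS / dfs
  MS_res <- SS_res / df_res

  # denominator table
  denom <- stats::setNames(rep("Residual", K), labels)
  if (!is.null(factor_fixed) && !is.null(factor_random)) {
    ab <- paste(factor_random, factor_fixed, sep = ":")
    if (ab %in% labels) denom[factor_fixed] <- ab
  }
  if (!is.null(denom_map)) {
    bad <- setdiff(names(denom_map), labels)
    if (length(bad)) stop("denom_map: unknown term(s) ",
                          paste(bad, collapse = ", "))
    for (nm in names(denom_map)) {
      if (!(denom_map[[nm]] %in% c(labels, "Residual")))
        stop("denom_map: unknown denominator '", denom_map[[nm]], "'")
      denom[nm] <- denom_map[[nm]]
    }
  }
  den_ms <- function(SSv, SSr) {
    vapply(denom, function(d) {
      if (d == "Residual") SSr / df_res else SSv[match(d, labels)] /
        dfs[match(d, labels)]
    }, 0)
  }
  den_df <- vapply(denom, function(d)
    if (d == "Residual") df_res else dfs[match(d, labels)], 0L)
  Fobs <- MS / den_ms(SS, SS_res)

  # distinguishable permutations per term: huge for residual-denominator
  # terms; for a factor tested over its interaction with the other factor,
  # levels can only be rearranged within each level of that other factor.
  n_distinct <- vapply(seq_len(K), function(i) {
    if (denom[i] == "Residual") return(Inf)
    own <- terms[[i]]$cat_levels
    den_lv <- terms[[match(denom[i], labels)]]$cat_levels
    other <- den_lv[setdiff(names(den_lv), names(own))]
    if (length(own) == 1L && length(other) >= 1L)
      factorial(own[[1L]])^prod(other) else Inf
  }, 0)

  set.seed(seed)
  p_perm <- rep(NA_real_, K)
  if (n_perms > 0L) {
    Vall <- do.call(cbind, bases)
    grp <- rep(seq_len(K), dfs)
    exceed <- numeric(K)
    ftol <- 1e-12 * pmax(abs(Fobs), 1)
    if (scheme == "raw") {
      for (b in seq_len(n_perms)) {
        q <- sample.int(n)
        Vp <- Vall[q, , drop = FALSE]
        qf <- .qf_sum(Vp, G)
        SSp <- as.numeric(rowsum(qf, grp))
        SSrp <- trG - sum(SSp)
        Fp <- (SSp / dfs) / den_ms(SSp, SSrp)
        exceed <- exceed + (Fp >= Fobs - ftol)
      }
    } else {
      # Freedman-Lane: per tested term t, residuals of the reduced model
      # (terms before t) are permuted; the full table is recomputed from
      # G* = M G M', M = H_red + P R_red, using only quadratic forms and
      # an O(n) trace correction.
      pre <- vector("list", K)
      for (t in seq_len(K)) {
        p_t <- if (t == 1L) 1L else 1L + sum(dfs[seq_len(t - 1L)])
        Qred <- ob$Qfull[, seq_len(p_t), drop = FALSE]
        HV <- Qred %*% crossprod(Qred, Vall)
        QtG <- crossprod(Qred, G)          # p x n
        HG <- Qred %*% QtG
        Kmat <- HG - (HG %*% Qred) %*% t(Qred)   # H_red G R_red
        pre[[t]] <- list(Qred = Qred, HV = HV, Kmat = Kmat)
      }
      ii <- seq_len(n)
      for (b in seq_len(n_perms)) {
        q <- sample.int(n)
        invq <- integer(n); invq[q] <- ii
        W <- Vall[invq, , drop = FALSE]    # P' Vall
        Fp <- numeric(K)
        for (t in seq_len(K)) {
          pt <- pre[[t]]
          MV <- pt$HV + W - pt$Qred %*% crossprod(pt$Qred, W)
          qf <- .qf_sum(MV, G)
          SSp <- as.numeric(rowsum(qf, grp))
          trGs <- trG + 2 * sum(pt$Kmat[cbind(ii, q)])
          SSrp <- trGs - sum(SSp)
          dms <- if (denom[t] == "Residual") SSrp / df_res else
            SSp[match(denom[t], labels)] / dfs[match(denom[t], labels)]
          Fp[t] <- (SSp[t] / dfs[t]) / dms
        }
        exceed <- exceed + (Fp >= Fobs - ftol)
      }
    }
    p_perm <- (exceed + 1) / (n_perms + 1)
  }

  # Monte-Carlo p from weighted chi-square mixtures
  p_mc <- rep(NA_real_, K)
  want_mc <- mc_all | (n_distinct < mc_threshold)
  if (any(want_mc) && mc_draws > 0L) {
    Rf <- ob$Qfull
    GR <- G - Rf %*% crossprod(Rf, G)
    Gres <- GR - (GR %*% Rf) %*% t(Rf)     # R_full G R_full
    lam <- eigen((Gres + t(Gres)) / 2, symmetric = TRUE,
                 only.values = TRUE)$values
    lam <- lam[abs(lam) > 1e-10 * max(abs(lam), 1e-300)]
    r <- length(lam)
    for (t in which(want_mc)) {
      if (r == 0L) break
      df1 <- dfs[t]; df2 <- den_df[t]
      num <- colSums(lam * matrix(stats::rchisq(r * mc_draws, df1),
                                  r, mc_draws))
      den <- colSums(lam * matrix(stats::rchisq(r * mc_draws, df2),
                                  r, mc_draws))
      Fmc <- (num / df1) / (den / df2)
      p_mc[t] <- (sum(Fmc >= Fobs[t]) + 1) / (mc_draws + 1)
    }
  }

  # components of variation: (MS_t - MS_denominator) / multiplier, with
  # multiplier n / (#level combinations of the term's categorical factors)
  combos <- vapply(terms, function(t)
    if (length(t$cat_levels)) prod(t$cat_levels) else 1, 0)
  comp <- (MS - den_ms(SS, SS_res)) / (n / combos)
  comp <- pmax(comp, 0)
  comp_all <- c(comp, MS_res)
  cv <- 100 * comp_all / sum(comp_all)

  out <- data.frame(
    term = c(labels, "Residual", "Total"),
    df = c(dfs, df_res, n - 1L),
    SS = c(SS, SS_res, trG),
    MS = c(MS, MS_res, NA_real_),
    pseudo_F = c(Fobs, NA_real_, NA_real_),
    p_perm = c(p_perm, NA_real_, NA_real_),
    p_MC = c(p_mc, NA_real_, NA_real_),
    CV_pct = c(cv, NA_real_),
    denominator = c(unname(denom), NA_character_, NA_character_),
    stringsAsFactors = FALSE)
  attr(out, "scheme") <- if (n_perms > 0L) scheme else "none"
  attr(out, "n_perms") <- n_perms
  attr(out, "seed") <- seed
  attr(out, "denom_map") <- denom
  attr(out, "n_distinct") <- stats::setNames(n_distinct, labels)
  class(out) <- c("permancova", "data.frame")
  out
}

#' @export
print.permancova <- function(x, ...) {
  cat("PERMANCOVA (sequential SS; scheme: ", attr(x, "scheme"),
      ", ", attr(x, "n_perms"), " permutations)\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Build the response distance matrix for a standard analysis
#'
#' Maps the five standard responses to their distance matrices: richness
#' and evenness to Euclidean distances on the per-cell index, community
#' structure to Bray-Curtis on fourth-root-transformed counts, and guild
#' structures to Bray-Curtis on fourth-root-transformed guild totals.
#' Cells with undefined evenness (richness <= 1) are dropped from the
#' evenness analysis only.
#'
#' @param study An `urb_study` list.
#' @param response One of `"richness"`, `"evenness"`, `"community"`,
#'   `"diet_guilds"`, `"habitat_guilds"`.
#' @return List with `D` (dist) and `data` (aligned cell metadata).
#' @export
response_distance <- function(study,
                              response = c("richness", "evenness",
                                           "community", "diet_guilds",
                                           "habitat_guilds")) {
  response <- match.arg(response)
  cells <- study$cells
  if (response %in% c("richness", "evenness")) {
    div <- richness_evenness(study$abund)
    y <- if (response == "richness") div$richness else div$evenness
    keep <- !is.na(y)
    return(list(D = stats::dist(y[keep]), data = cells[keep, , drop = FALSE]))
  }
  if (response %in% c("diet_guilds", "habitat_guilds") &&
      is.null(study$traits))
    stop("response_distance: guild responses require a trait table")
  mat <- switch(response,
                community = study$abund,
                diet_guilds = aggregate_guilds(study$abund, study$traits,
                                               "diet"),
                habitat_guilds = aggregate_guilds(study$abund,
                                                  study$traits, "habitat"))
  list(D = bray_curtis(fourth_root(mat)), data = cells)
}
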