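# Two-block partial least squares correlation (PLS-C).
#
# Both blocks are residualized on the covariates and standardized, so the
# cross-block matrix R = t(Xr) %*% Yr / (n - 1) holds correlations and the
# singular values are scale-free. The SVD R = V S t(U) pairs an X-salience
# (column of V, length p) with a Y-salience (column of U, length q) per latent
# variable. Inference: omnibus permutation test on the inertia (sum of all
# singular values), per-LV permutation p-values on the non-rotated k-th
# singular value, and percentile bootstrap CIs for every salience element
# after orthogonal Procrustes alignment of each resample to the point
# estimate.

# Residualize every column of `block` on [1, C] and scale to unit sample
# variance (divisor n - 1). strict = TRUE errors on degenerate columns
# (naming them); strict = FALSE zeroes them (resampling branches).
.std_resid <- function(block, C, strict = TRUE) {
  block <- as.matrix(block)
  qrC <- qr(cbind(1, C))
  res <- qr.resid(qrC, block)
  sds <- apply(res, 2, stats::sd)
  bad <- sds < 1e-10
  if (any(bad)) {
    if (strict) {
      nm <- colnames(block)
      if (is.null(nm)) nm <- paste0("column ", seq_len(ncol(block)))
      stop("zero residual variance after covariate adjustment in: ",
           paste(nm[bad], collapse = ", "))
    }
    sds[bad] <- Inf   # column becomes 0
  }
  sweep(res, 2, sds, "/")
}

#' Residualize and standardize a block
#'
#' Replaces each column by its OLS residual on an intercept plus the
#' covariates, then scales each column to unit sample variance (divisor
#' `n - 1`). With no covariates the block is centered and scaled.
#'
#' @param block Numeric matrix or data frame (subjects in rows).
#' @param covariates Optional data frame / matrix of numeric covariates.
#' @return Numeric matrix of standardized residuals (column names kept).
#' @export
residualize_block <- function(block, covariates = NULL) {
  block <- as.matrix(block)
  if (anyNA(block)) stop("block contains missing values; exclude listwise first")
  n <- nrow(block)
  C <- .cov_matrix(covariates, n)
  if (n <= ncol(C) + 1) stop("too few subjects to residualize on the covariates")
  .std_resid(block, C, strict = TRUE)
}

# core decomposition; assumes residualized/standardized inputs
.plsc_svd <- function(Xr, Yr) {
  n <- nrow(Xr)
  R <- crossprod(Xr, Yr) / (n - 1)
  sv <- svd(R)
  K <- min(ncol(Xr), ncol(Yr))
  list(R = R, d = sv$d[seq_len(K)],
       V = sv$u[, seq_len(K), drop = FALSE],
       U = sv$v[, seq_len(K), drop = FALSE])
}

# deterministic sign convention: largest-|.| element of each Y-salience
# column made positive, X-salience flipped in step
.fix_signs <- function(V, U) {
  for (k in seq_len(ncol(U))) {
    j <- which.max(abs(U[, k]))
    if (U[j, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  list(V = V, U = U)
}

#' Fit a PLS-C decomposition (point estimates)
#'
#' Singular value decomposition of the cross-block correlation matrix
#' `R = t(Xr) %*% Yr / (n - 1)` of two residualized, standardized blocks.
#' Saliences carry a deterministic sign convention: per latent variable, the
#' largest-magnitude Y-salience element is positive. Latent-variable scores
#' are `Lx = Xr V` and `Ly = Yr U`; their sample covariances reproduce the
#' singular values.
#'
#' @param Xr,Yr Residualized, standardized blocks with the same number of
#'   rows (see [residualize_block()]).
#' @return Object of class `plsc_fit`: list with `singular_values`,
#'   `x_saliences` (p x K), `y_saliences` (q x K), `x_scores`, `y_scores`,
#'   `inertia` (sum of singular values), `cov_explained`
#'   (`sigma_k^2 / sum(sigma^2)`), `cross_block` (R), `n`.
#' @export
fit_plsc <- function(Xr, Yr) {
  Xr <- as.matrix(Xr); Yr <- as.matrix(Yr)
  if (nrow(Xr) != nrow(Yr)) stop("Xr and Yr must have the same number of rows")
  if (!all(is.finite(Xr)) || !all(is.finite(Yr)))
    stop("blocks must be finite with no missing entries")
  dec <- .plsc_svd(Xr, Yr)
  sgn <- .fix_signs(dec$V, dec$U)
  V <- sgn$V; U <- sgn$U
  rownames(V) <- colnames(Xr); rownames(U) <- colnames(Yr)
  structure(list(
    singular_values = dec$d,
    x_saliences = V, y_saliences = U,
    x_scores = Xr %*% V, y_scores = Yr %*% U,
    inertia = sum(dec$d),
    cov_explained = if (sum(dec$d^2) > 0) covariance_explained(dec$d)
                    else rep(NA_real_, length(dec$d)),
    cross_block = dec$R, n = nrow(Xr)),
    class = "plsc_fit")
}

#' Covariance-explained fractions
#'
#' Fraction of the cross-block covariance carried by each latent variable:
#' `sigma_k^2 / sum_j sigma_j^2`. The fractions sum to one, and
#' `sum(sigma^2)` equals the squared Frobenius norm of the cross-block matrix.
#'
#' @param sigma Non-negative vector of singular values.
#' @return Numeric vector of fractions summing to 1.
#' @export
covariance_explained <- function(sigma) {
  if (length(sigma) == 0 || any(sigma < 0))
    stop("'sigma' must be a non-empty vector of non-negative singular values")
  tot <- sum(sigma^2)
  if (tot <= 0) stop("all singular values are zero")
  sigma^2 / tot
}

#' Permutation test for PLS-C
#'
#' Non-rotated permutation test: for each permutation the rows of `Yr` are
#' shuffled and the decomposition refit. The omnibus p-value compares the
#' inertia (sum of all singular values); per-LV p-values compare the k-th
#' singular value of each permuted fit with the observed k-th singular value.
#' Both use the add-one estimator `p = (1 + #exceedances) / (1 + n_perm)`,
#' so p is never exactly zero.
#'
#' @inheritParams fit_plsc
#' @param n_perm Number of permutations (at least 100).
#' @param seed Optional integer seed.
#' @return List with `omnibus_p`, `lv_p` (length `min(p, q)`),
#'   `inertia_obs`, `n_perm`.
#' @export
plsc_permutation <- function(Xr, Yr, n_perm = 10000, seed = NULL) {
  Xr <- as.matrix(Xr); Yr <- as.matrix(Yr)
  if (nrow(Xr) != nrow(Yr)) stop("Xr and Yr must have the same number of rows")
  if (n_perm < 100) stop("n_perm must be at least 100 (unstable p otherwise)")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Xr)
  obs <- .plsc_svd(Xr, Yr)
  K <- length(obs$d)
  inertia_obs <- sum(obs$d)
  exceed_omni <- 0L
  exceed_lv <- integer(K)
  Xt <- t(Xr) / (n - 1)    # precompute: R_perm = Xt %*% Yr[perm, ]
  for (b in seq_len(n_perm)) {
    d_perm <- svd(Xt %*% Yr[sample.int(n), , drop = FALSE],
                  nu = 0, nv = 0)$d[seq_len(K)]
    if (sum(d_perm) >= inertia_obs) exceed_omni <- exceed_omni + 1L
    exceed_lv <- exceed_lv + (d_perm >= obs$d)
  }
  list(omnibus_p = (1 + exceed_omni) / (1 + n_perm),
       lv_p = (1 + exceed_lv) / (1 + n_perm),
       inertia_obs = inertia_obs, n_perm = n_perm)
}

# orthogonal Procrustes: rotation Q minimizing || A Q - B ||_F
.procrustes_rotation <- function(A, B) {
  sv <- svd(crossprod(A, B))
  sv$u %*% t(sv$v)
}

#' Bootstrap salience confidence intervals (Procrustes-aligned)
#'
#' Subjects are resampled jointly with replacement; each resample is
#' re-standardized column-wise, refit, and aligned to the point estimate by
#' orthogonal Procrustes rotation (the rotation is solved on the Y-saliences
#' and applied to both blocks). Percentile confidence intervals are computed
#' per salience element; an element is flagged reliable when its interval
#' does not cross zero. Rank-collapsed resamples (a column with zero variance)
#' are redrawn, up to `10 * n_boot` attempts in total.
#'
#' @inheritParams fit_plsc
#' @param n_boot Number of bootstrap resamples (at least 200).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed.
#' @param fit Optional pre-computed [fit_plsc()] result for `(Xr, Yr)`.
#' @return List with arrays `x_ci_lower`, `x_ci_upper`, `y_ci_lower`,
#'   `y_ci_upper` (salience-shaped), logical `x_reliable`, `y_reliable`,
#'   and `n_boot`.
#' @export
plsc_bootstrap <- function(Xr, Yr, n_boot = 10000, conf = 0.95, seed = NULL,
                           fit = NULL) {
  Xr <- as.matrix(Xr); Yr <- as.matrix(Yr)
  if (nrow(Xr) != nrow(Yr)) stop("Xr and Yr must have the same number of rows")
  if (n_boot < 200) stop("n_boot must be at least 200")
  if (is.null(fit)) fit <- fit_plsc(Xr, Yr)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Xr); p <- ncol(Xr); q <- ncol(Yr)
  K <- length(fit$singular_values)
  V0 <- fit$x_saliences; U0 <- fit$y_saliences
  Vb <- array(NA_real_, c(p, K, n_boot))
  Ub <- array(NA_real_, c(q, K, n_boot))
  got <- 0L; tries <- 0L
  while (got < n_boot && tries < 10L * n_boot) {
    tries <- tries + 1L
    idx <- sample.int(n, n, replace = TRUE)
    Xb <- Xr[idx, , drop = FALSE]; Yb <- Yr[idx, , drop = FALSE]
    # re-standardize the resample so R stays a correlation matrix
    Xb <- sweep(Xb, 2, colMeans(Xb), "-")
    Yb <- sweep(Yb, 2, colMeans(Yb), "-")
    sx <- sqrt(colSums(Xb^2) / (n - 1)); sy <- sqrt(colSums(Yb^2) / (n - 1))
    if (any(sx < 1e-10) || any(sy < 1e-10)) next   # rank-collapsed, redraw
    Xb <- sweep(Xb, 2, sx, "/"); Yb <- sweep(Yb, 2, sy, "/")
    dec <- .plsc_svd(Xb, Yb)
    Q <- .procrustes_rotation(dec$U, U0)
    got <- got + 1L
    Ub[, , got] <- dec$U %*% Q
    Vb[, , got] <- dec$V %*% Q
  }
  if (got < n_boot) stop("bootstrap failed: too many rank-collapsed resamples")
  alpha <- (1 - conf) / 2
  qlo <- function(a) apply(a, c(1, 2), stats::quantile, probs = alpha)
  qhi <- function(a) apply(a, c(1, 2), stats::quantile, probs = 1 - alpha)
  x_lo <- qlo(Vb); x_hi <- qhi(Vb)
  y_lo <- qlo(Ub); y_hi <- qhi(Ub)
  dimnames(x_lo) <- dimnames(x_hi) <- dimnames(V0)
  dimnames(y_lo) <- dimnames(y_hi) <- dimnames(U0)
  list(x_ci_lower = x_lo, x_ci_upper = x_hi,
       y_ci_lower = y_lo, y_ci_upper = y_hi,
       x_reliable = x_lo > 0 | x_hi < 0,
       y_reliable = y_lo > 0 | y_hi < 0,
       n_boot = n_boot)
}

#' Full PLS-C analysis
#'
#' Residualizes both blocks on the covariates, fits the cross-block SVD, and
#' runs the inertia permutation test and the Procrustes-aligned bootstrap.
#' A latent variable is marked reportable when it explains more than
#' `report_threshold` of the cross-block covariance and its permutation
#' p-value is below 0.05.
#'
#' @param X Numeric matrix / data frame, subjects x p (e.g. 48 ROI FA values).
#' @param Y Numeric matrix / data frame, subjects x q (e.g. 6 sleep measures).
#' @param covariates Optional data frame / matrix of numeric covariates.
#' @param n_perm,n_boot Iteration counts (defaults 10000).
#' @param conf Bootstrap confidence level (default 0.95).
#' @param seed Optional integer seed covering both resampling stages.
#' @param report_threshold Covariance-explained fraction above which an LV is
#'   reportable (default 0.05).
#' @return Object of class `plsc_result`: the [fit_plsc()] fields plus
#'   `omnibus_p`, `lv_p`, `boot` (see [plsc_bootstrap()]), `reportable`,
#'   `n_perm`, `n_boot`.
#' @export
plsc <- function(X, Y, covariates = NULL, n_perm = 10000, n_boot = 10000,
                 conf = 0.95, seed = NULL, report_threshold = 0.05) {
  Xr <- residualize_block(X, covariates)
  Yr <- residualize_block(Y, covariates)
  fit <- fit_plsc(Xr, Yr)
  if (!is.null(seed)) set.seed(seed)
  perm <- plsc_permutation(Xr, Yr, n_perm = n_perm)
  boot <- plsc_bootstrap(Xr, Yr, n_boot = n_boot, conf = conf, fit = fit)
  out <- unclass(fit)
  out$omnibus_p <- perm$omnibus_p
  out$lv_p <- perm$lv_p
  out$boot <- boot
  out$reportable <- fit$cov_explained > report_threshold & perm$lv_p < 0.05
  out$n_perm <- n_perm
  out$n_boot <- n_boot
  class(out) <- c("plsc_result", "plsc_fit")
  out
}

#' @export
print.plsc_fit <- function(x, ...) {
  K <- length(x$singular_values)
  cat(sprintf("PLS-C fit: n = %d, %d latent variable(s), inertia = %.4f\n",
              x$n, K, x$inertia))
  tab <- data.frame(
    lv = seq_len(K),
    sigma = round(x$singular_values, 4),
    cov_explained = round(100 * x$cov_explained, 2))
  if (inherits(x, "plsc_result")) {
    tab$p_perm <- signif(x$lv_p, 3)
    tab$reportable <- x$reportable
    cat(sprintf("Omnibus (inertia) permutation p = %.4g (n_perm = %d)\n",
                x$omnibus_p, x$n_perm))
  }
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Group-wise PLS-C with a group-contrast permutation test
#'
#' Runs an independent PLS-C per group (covariates fitted within group) and a
#' permutation test of whether the X-Y covariance pattern differs between the
#' two groups. The contrast statistic is the inertia (sum of singular values)
#' of the difference of the two within-group cross-block correlation matrices;
#' its null distribution is obtained by permuting group membership (group
#' sizes fixed) and re-residualizing within the permuted groups.
#'
#' @inheritParams plsc
#' @param groups Two-level factor of group membership, one entry per row.
#' @return Object of class `groupwise_plsc`: list with `within` (named list of
#'   [plsc()] results per group), `contrast_stat`, `contrast_p`, `n_perm`.
#' @export
groupwise_plsc <- function(X, Y, groups, covariates = NULL, n_perm = 10000,
                           n_boot = 10000, conf = 0.95, seed = NULL,
                           report_threshold = 0.05) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("'groups' must have exactly two levels")
  n <- nrow(X)
  if (length(groups) != n || nrow(Y) != n)
    stop("X, Y and groups must agree in length")
  C <- .cov_matrix(covariates, n)
  for (g in levels(groups)) {
    if (sum(groups == g) < ncol(C) + 3)
      stop("group '", g, "' has too few subjects for the covariate model")
  }
  if (!is.null(seed)) set.seed(seed)
  within <- lapply(levels(groups), function(g) {
    sel <- groups == g
    plsc(X[sel, , drop = FALSE], Y[sel, , drop = FALSE],
         covariates = if (ncol(C) > 0) C[sel, , drop = FALSE] else NULL,
         n_perm = n_perm, n_boot = n_boot, conf = conf,
         report_threshold = report_threshold)
  })
  names(within) <- levels(groups)
  # group contrast: inertia of R_1 - R_2 under label permutation
  contrast_stat_for <- function(lab) {
    Rg <- lapply(levels(groups), function(g) {
      sel <- lab == g
      Xr <- .std_resid(X[sel, , drop = FALSE],
                       C[sel, , drop = FALSE], strict = FALSE)
      Yr <- .std_resid(Y[sel, , drop = FALSE],
                       C[sel, , drop = FALSE], strict = FALSE)
      crossprod(Xr, Yr) / (sum(sel) - 1)
    })
    sum(svd(Rg[[1]] - Rg[[2]], nu = 0, nv = 0)$d)
  }
  obs <- contrast_stat_for(groups)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (contrast_stat_for(sample(groups)) >= obs) exceed <- exceed + 1L
  }
  structure(list(within = within, contrast_stat = obs,
                 contrast_p = (1 + exceed) / (1 + n_perm), n_perm = n_perm),
            class = "groupwise_plsc")
}

#' @export
print.groupwise_plsc <- function(x, ...) {
  cat(sprintf("Group-contrast PLS-C: statistic = %.4f, permutation p = %.4g\n",
              x$contrast_stat, x$contrast_p))
  for (g in names(x$within)) {
    cat("\n--- group:", g, "---\n")
    print(x$within[[g]])
  }
  invisible(x)
}
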