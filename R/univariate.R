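# Covariate-adjusted univariate statistics: nested-model GLM group test,
# partial correlations with percentile-bootstrap CIs, Benjamini-Hochberg FDR,
# and percentile-bootstrap simple mediation.

# Validate a covariate table: data.frame (or NULL) with numeric columns and no
# missing values (listwise exclusion happens upstream). Returns a numeric matrix
# (0-column matrix for NULL).
.cov_matrix <- function(cov, n) {
  if (is.null(cov)) return(matrix(numeric(0), nrow = n, ncol = 0))
  if (is.data.frame(cov)) cov <- as.matrix(cov)
  if (!is.matrix(cov)) cov <- matrix(cov, nrow = n)
  storage.mode(cov) <- "double"
  if (nrow(cov) != n) stop("covariates must have one row per subject")
  if (anyNA(cov)) stop("covariates contain missing values; exclude listwise first")
  cov
}

# residuals of y on [1, C] via QR
.resid_on <- function(y, C) {
  qr.resid(qr(cbind(1, C)), y)
}

#' Covariate-adjusted group test (nested-model F)
#'
#' Tests the effect of a two-level group factor on an outcome adjusting for
#' covariates, via the nested-model residual-sum-of-squares comparison of
#' `y ~ covariates` against `y ~ group + covariates`, with the exact
#' F reference distribution (1 numerator df).
#'
#' @param y Numeric outcome vector.
#' @param group Two-level factor (or vector coercible to one).
#' @param covariates Optional data frame / matrix of numeric covariates
#'   (e.g. age, sex, absolute and relative motion).
#' @return Object of class `glm_group_test`: list with `f_stat`, `df_num`,
#'   `df_den`, `p_value`, `adjusted_means` (group means at covariate means),
#'   and `n`.
#' @export
glm_group_test <- function(y, group, covariates = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  group <- factor(group)
  if (nlevels(group) != 2) stop("'group' must have exactly two levels")
  if (length(group) != n) stop("'y' and 'group' lengths differ")
  if (anyNA(y) || anyNA(group)) stop("missing values; exclude listwise first")
  C <- .cov_matrix(covariates, n)
  k <- ncol(C)
  if (n <= k + 2) stop("too few subjects for the model")
  g <- as.numeric(group == levels(group)[2])
  X_full <- cbind(1, g, C)
  qr_full <- qr(X_full)
  if (qr_full$rank < ncol(X_full)) {
    cols <- c("(intercept)", "group", colnames(C))
    drop <- qr_full$pivot[seq(qr_full$rank + 1, ncol(X_full))]
    stop("rank-deficient design; collinear column(s): ",
         paste(cols[drop], collapse = ", "))
  }
  rss_full <- sum(qr.resid(qr_full, y)^2)
  rss_red <- sum(qr.resid(qr(cbind(1, C)), y)^2)
  df_den <- n - ncol(X_full)
  f_stat <- (rss_red - rss_full) / (rss_full / df_den)
  p <- stats::pf(f_stat, 1, df_den, lower.tail = FALSE)
  beta <- qr.coef(qr_full, y)
  cov_means <- if (k > 0) colMeans(C) else numeric(0)
  base <- beta[1] + if (k > 0) sum(beta[-(1:2)] * cov_means) else 0
  adj <- stats::setNames(c(base, base + beta[2]), levels(group))
  structure(list(f_stat = f_stat, df_num = 1, df_den = df_den, p_value = p,
                 adjusted_means = adj, n = n),
            class = "glm_group_test")
}

#' @export
print.glm_group_test <- function(x, ...) {
  cat(sprintf("Group effect: F(%d, %d) = %.3f, p = %.4g (n = %d)\n",
              x$df_num, x$df_den, x$f_stat, x$p_value, x$n))
  cat("Adjusted means:\n")
  print(round(x$adjusted_means, 4))
  invisible(x)
}

#' Partial correlation with bootstrap confidence interval
#'
#' Pearson correlation between the OLS residuals of `x` and `y` on an
#' intercept plus the covariates; with an empty covariate set this reduces to
#' the plain Pearson correlation. The two-tailed p-value uses the t transform
#' with `n - k - 2` degrees of freedom (`k` covariates); the confidence
#' interval is a subject-level nonparametric percentile bootstrap in which each
#' resample is re-residualized. Degenerate resamples (zero residual variance)
#' are redrawn, up to `10 * B` attempts in total.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data frame / matrix of numeric covariates.
#' @param B Number of bootstrap resamples (default 1000); `B = 0` skips the
#'   bootstrap.
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return Object of class `partial_correlation`: list with `r`, `df`,
#'   `p_value`, `ci` (length-2 vector or `NULL`), `conf`, `B`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL, B = 1000,
                                conf = 0.95, seed = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("'x' and 'y' lengths differ")
  if (anyNA(x) || anyNA(y)) stop("missing values; exclude listwise first")
  C <- .cov_matrix(covariates, n)
  k <- ncol(C)
  if (n <= k + 2) stop("too few subjects for the partial correlation")
  pcor <- function(xi, yi, Ci) {
    rx <- .resid_on(xi, Ci); ry <- .resid_on(yi, Ci)
    vx <- sum(rx^2); vy <- sum(ry^2)
    if (vx < 1e-12 || vy < 1e-12) return(NA_real_)
    sum(rx * ry) / sqrt(vx * vy)
  }
  r <- pcor(x, y, C)
  if (is.na(r)) stop("zero residual variance in x or y after adjustment")
  df <- n - k - 2
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  ci <- NULL
  if (B > 0) {
    if (!is.null(seed)) set.seed(seed)
    boots <- numeric(B)
    got <- 0L; tries <- 0L
    while (got < B && tries < 10L * B) {
      tries <- tries + 1L
      idx <- sample.int(n, n, replace = TRUE)
      rb <- pcor(x[idx], y[idx], C[idx, , drop = FALSE])
      if (!is.na(rb)) { got <- got + 1L; boots[got] <- rb }
    }
    if (got < B) stop("bootstrap failed: too many degenerate resamples")
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  }
  structure(list(r = r, df = df, p_value = p, ci = ci, conf = conf,
                 B = B, n = n),
            class = "partial_correlation")
}

#' @export
print.partial_correlation <- function(x, ...) {
  cat(sprintf("Partial correlation: r = %.3f, df = %d, p = %.4g (n = %d)\n",
              x$r, x$df, x$p_value, x$n))
  if (!is.null(x$ci))
    cat(sprintf("  %g%% percentile bootstrap CI (B = %d): [%.3f, %.3f]\n",
                100 * x$conf, x$B, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with p-values sorted ascending,
#' `q(i) = min over j >= i of p(j) * m / j`, capped at 1, returned in the input
#' order (delegates to [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing entries")
  stats::p.adjust(p, method = "BH")
}

#' Percentile-bootstrap simple mediation
#'
#' Simple (single-mediator) mediation by OLS path analysis: `a` from
#' `m ~ x + covariates`; `b` and the direct effect `c'` from
#' `y ~ x + m + covariates`; the total effect `c` from `y ~ x + covariates`.
#' The indirect effect is `a * b`, with a subject-level percentile bootstrap
#' confidence interval. For these linear models without interaction the OLS
#' decomposition `c = c' + a * b` holds exactly.
#'
#' @param x Exposure vector.
#' @param m Mediator vector.
#' @param y Outcome vector.
#' @param covariates Optional data frame / matrix of numeric covariates.
#' @param B Number of bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return Object of class `mediation`: list with paths `a`, `b`, `c`,
#'   `c_prime`, `indirect`, `ci`, `conf`, `B`, `n`.
#' @export
mediate <- function(x, m, y, covariates = NULL, B = 1000, conf = 0.95,
                    seed = NULL) {
  x <- as.numeric(x); m <- as.numeric(m); y <- as.numeric(y)
  n <- length(x)
  if (length(m) != n || length(y) != n) stop("x, m, y lengths differ")
  if (anyNA(x) || anyNA(m) || anyNA(y))
    stop("missing values; exclude listwise first")
  C <- .cov_matrix(covariates, n)
  if (n <= ncol(C) + 3) stop("too few subjects for the mediation models")
  if (abs(stats::cor(.resid_on(x, C), .resid_on(m, C))) > 0.999)
    warning("x and m nearly collinear after adjustment; paths are unstable")
  paths <- function(xi, mi, yi, Ci) {
    qa <- qr(cbind(1, xi, Ci))
    a <- qr.coef(qa, mi)[2]
    cb <- qr.coef(qr(cbind(1, xi, mi, Ci)), yi)
    c_tot <- qr.coef(qa, yi)[2]
    c(a = unname(a), b = unname(cb[3]), c = unname(c_tot),
      c_prime = unname(cb[2]))
  }
  est <- paths(x, m, y, C)
  ci <- NULL
  if (B > 0) {
    if (!is.null(seed)) set.seed(seed)
    boots <- numeric(B)
    got <- 0L; tries <- 0L
    while (got < B && tries < 10L * B) {
      tries <- tries + 1L
      idx <- sample.int(n, n, replace = TRUE)
      pb <- tryCatch(paths(x[idx], m[idx], y[idx], C[idx, , drop = FALSE]),
                     error = function(e) NULL)
      if (!is.null(pb) && all(is.finite(pb))) {
        got <- got + 1L; boots[got] <- pb[["a"]] * pb[["b"]]
      }
    }
    if (got < B) stop("bootstrap failed: too many degenerate resamples")
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  }
  structure(list(a = est[["a"]], b = est[["b"]], c = est[["c"]],
                 c_prime = est[["c_prime"]],
                 indirect = est[["a"]] * est[["b"]],
                 ci = ci, conf = conf, B = B, n = n),
            class = "mediation")
}

#' @export
print.mediation <- function(x, ...) {
  cat(sprintf("Mediation (n = %d): a = %.3f, b = %.3f, c = %.3f, c' = %.3f\n",
              x$n, x$a, x$b, x$c, x$c_prime))
  cat(sprintf("  indirect a*b = %.3f", x$indirect))
  if (!is.null(x$ci))
    cat(sprintf(", %g%% percentile bootstrap CI [%.3f, %.3f] (B = %d)",
                100 * x$conf, x$ci[1], x$ci[2], x$B))
  cat("\n")
  invisible(x)
}
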