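# Logistic association of PRSs with longevity status, Nagelkerke
# pseudo-R2, and multiple-testing control across traits and SNP sets.

#' Logistic regression of a binary outcome on one predictor
#'
#' Maximum-likelihood logistic fit with an optional covariate matrix; the
#' reported p-value for the predictor is the Wald test. When the fit shows
#' signs of complete separation (non-convergence or fitted probabilities at
#' the boundary) the Wald statistic degenerates, so the likelihood-ratio
#' p-value is reported instead, with a warning.
#'
#' @param y Binary 0/1 outcome (non-constant).
#' @param x Numeric predictor (typically a standardized PRS).
#' @param covariates Optional numeric matrix of covariates; the null model
#'   contains the intercept and covariates only.
#' @return A list: `coefficient`, `se`, `p`, `ll_null`, `ll_full`, `n`,
#'   `method` (`"wald"` or `"lrt"`).
#' @export
fit_logistic <- function(y, x, covariates = NULL) {
  ok <- !is.na(y) & !is.na(x)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    ok <- ok & stats::complete.cases(covariates)
    covariates <- covariates[ok, , drop = FALSE]
  }
  y <- y[ok]; x <- x[ok]
  if (length(unique(y)) < 2) stop("outcome is constant")
  if (any(!is.finite(x))) stop("predictor contains non-finite values")

  dat <- data.frame(y = y, x = x)
  form_full <- y ~ x
  form_null <- y ~ 1
  if (!is.null(covariates)) {
    colnames(covariates) <- paste0("c", seq_len(ncol(covariates)))
    dat <- cbind(dat, covariates)
    form_full <- stats::as.formula(
      paste("y ~ x +", paste(colnames(covariates), collapse = " + ")))
    form_null <- stats::as.formula(
      paste("y ~", paste(colnames(covariates), collapse = " + ")))
  }
  ctl <- stats::glm.control(epsilon = 1e-12, maxit = 100)
  full <- suppressWarnings(stats::glm(form_full, stats::binomial(), dat,
                                      control = ctl))
  null <- stats::glm(form_null, stats::binomial(), dat, control = ctl)
  sm <- summary(full)$coefficients
  coef_x <- sm["x", "Estimate"]
  se_x <- sm["x", "Std. Error"]
  p_x <- sm["x", "Pr(>|z|)"]
  ll_full <- as.numeric(stats::logLik(full))
  ll_null <- as.numeric(stats::logLik(null))
  method <- "wald"
  eps <- 1e-8
  separated <- !full$converged ||
    all(full$fitted.values > 1 - eps | full$fitted.values < eps)
  if (separated) {
    warning("possible complete separation; reporting likelihood-ratio p")
    p_x <- stats::pchisq(2 * (ll_full - ll_null), df = 1, lower.tail = FALSE)
    method <- "lrt"
  }
  list(coefficient = coef_x, se = se_x, p = p_x,
       ll_null = ll_null, ll_full = ll_full, n = length(y), method = method)
}

#' Nagelkerke pseudo-R2
#'
#' Cox-Snell R2 rescaled to a maximum of 1:
#' `(1 - exp(2 * (ll_null - ll_full) / n)) / (1 - exp(2 * ll_null / n))`.
#'
#' @param ll_null,ll_full Log-likelihoods of the null and full models
#'   (`ll_full >= ll_null`).
#' @param n Number of observations.
#' @return Pseudo-R2 in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(ll_null, ll_full, n) {
  if (n <= 0) stop("n must be positive")
  if (ll_full < ll_null - 1e-8)
    stop("ll_full must be at least ll_null")
  cox_snell <- 1 - exp(2 * (ll_null - ll_full) / n)
  max_cs <- 1 - exp(2 * ll_null / n)
  if (max_cs <= 0) return(0)
  min(1, max(0, cox_snell / max_cs))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param pvals Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value list")
  if (any(is.na(pvals) | pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

# BH adjustment against a declared family larger than the observed tests:
# the m unobserved tests are treated as occupying the top ranks (p = 1), so
# adjusted_i = min over observed tail of p_(j) * m_total / j. Used for the
# sets-x-traits correction family when only one trait's scan is in hand.
bh_fdr_family <- function(pvals, m_total) {
  if (m_total < length(pvals)) stop("family size smaller than test count")
  ord <- order(pvals)
  k <- length(pvals)
  adj <- pvals[ord] * m_total / seq_len(k)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(k)
  out[ord] <- pmin(1, adj)
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("m must be at least 1")
  alpha / m
}
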