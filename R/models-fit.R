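#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2*logLik + 2k + 2k(k+1)/(n-k-1)`, with `k` counting every
#' estimated parameter including variance components.
#'
#' @param logLik model log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return the AICc value.
#' @export
aicc_value <- function(logLik, k, n) {
  if (n - k - 1 <= 0) {
    stop(sprintf("AICc undefined: n - k - 1 = %d <= 0", n - k - 1))
  }
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc_value
#' @param fit a `slip_fit`.
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "slip_fit"))
  fit$aicc
}

#' Ordinary least squares fit of a design
#'
#' @param design a [design_matrix()] result.
#' @param g unused placeholder for interface symmetry.
#' @return a `slip_fit`: list with `type`, `coefficients` (data.frame
#'   term/estimate/se/t/p), `logLik`, `n`, `k`, `aicc`, `r2`
#'   (adjusted), `sigma`, `fitted`, `residuals`, `spec`.
#' @export
fit_linear <- function(design, g = NULL) {
  y <- design$y
  X <- design$X
  intercept <- design$spec$intercept
  n <- length(y)
  p <- ncol(X) + intercept
  if (n <= p) stop("not enough rows to fit the model")
  if (ncol(X) == 0) return(fit_null(design))
  df <- data.frame(.response = y, X, check.names = FALSE)
  fml <- if (intercept) .response ~ . else .response ~ 0 + .
  fit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  ll <- as.numeric(stats::logLik(fit))
  k <- p + 1  # + residual variance
  aicc <- if (n - k - 1 > 0) aicc_value(ll, k, n) else NA_real_
  out <- list(type = "linear",
              coefficients = data.frame(term = rownames(co),
                                        estimate = co[, 1], se = co[, 2],
                                        t = co[, 3], p = co[, 4],
                                        row.names = NULL,
                                        stringsAsFactors = FALSE),
              logLik = ll, n = n, k = k, aicc = aicc,
              r2 = sm$adj.r.squared, sigma = sm$sigma,
              fitted = stats::fitted(fit), residuals = stats::resid(fit),
              spec = design$spec, lm = fit)
  class(out) <- "slip_fit"
  out
}

# the empty model: intercept-only, or pure-variance for zero-intercept specs
fit_null <- function(design) {
  y <- design$y
  n <- length(y)
  intercept <- design$spec$intercept
  mu <- if (intercept) mean(y) else 0
  s2 <- mean((y - mu)^2)
  ll <- sum(stats::dnorm(y, mu, sqrt(s2), log = TRUE))
  k <- 1 + intercept
  co <- if (intercept) {
    se <- sqrt(s2 / (n - 1)) / sqrt(n) * sqrt(n / (n - 1))
    tt <- mu / (stats::sd(y) / sqrt(n))
    data.frame(term = "(Intercept)", estimate = mu,
               se = stats::sd(y) / sqrt(n), t = tt,
               p = 2 * stats::pt(-abs(tt), n - 1), stringsAsFactors = FALSE)
  } else {
    data.frame(term = character(0), estimate = numeric(0), se = numeric(0),
               t = numeric(0), p = numeric(0), stringsAsFactors = FALSE)
  }
  out <- list(type = "null", coefficients = co, logLik = ll, n = n, k = k,
              aicc = aicc_value(ll, k, n), r2 = 0, sigma = sqrt(s2),
              fitted = rep(mu, n), residuals = y - mu, spec = design$spec)
  class(out) <- "slip_fit"
  out
}

#' Random-intercept mixed model by restricted maximum likelihood
#'
#' Fits a Gaussian linear mixed model with a random intercept for the
#' grouping in the design (moth or trial), estimated by REML. A
#' singular fit (zero group variance) is returned with a `singular`
#' flag rather than an error. The conditional r-squared is the
#' fixed-plus-random variance share of the total; fixed-effect
#' p-values use a t approximation on the residual degrees of freedom.
#'
#' @param design a [design_matrix()] result whose spec carries a
#'   random-intercept grouping.
#' @return a `slip_fit` with additional fields `group_var`,
#'   `resid_var`, `singular`.
#' @export
fit_mixed_random_intercept <- function(design) {
  y <- design$y
  X <- design$X
  grp <- design$groups
  if (is.null(grp)) stop("design has no random-intercept grouping")
  if (nlevels(grp) < 2) stop("need >= 2 groups for a random intercept")
  if (min(table(grp)) < 2) stop("every group needs >= 2 rows")
  intercept <- design$spec$intercept
  df <- data.frame(.response = y, X, .group = grp, check.names = FALSE)
  tn <- colnames(X)
  rhs <- paste(c(if (!intercept) "0", sprintf("`%s`", tn), "(1 | .group)"),
               collapse = " + ")
  fml <- stats::as.formula(paste(".response ~", rhs))
  fit <- suppressMessages(lme4::lmer(fml, data = df, REML = TRUE))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  co <- summary(fit)$coefficients
  n <- length(y)
  p <- nrow(co)
  dof <- n - p - 1
  pvals <- 2 * stats::pt(-abs(co[, 3]), dof)
  vc <- as.data.frame(lme4::VarCorr(fit))
  group_var <- vc$vcov[vc$grp == ".group"]
  resid_var <- vc$vcov[vc$grp == "Residual"]
  fe <- lme4::fixef(fit)
  Xf <- stats::model.matrix(fit)
  var_f <- stats::var(as.numeric(Xf %*% fe))
  r2c <- (var_f + group_var) / (var_f + group_var + resid_var)
  ll <- as.numeric(stats::logLik(fit))  # REML criterion
  k <- p + 2  # fixed effects + group variance + residual variance
  out <- list(type = "mixed",
              coefficients = data.frame(term = rownames(co),
                                        estimate = co[, 1], se = co[, 2],
                                        t = co[, 3], p = pvals,
                                        row.names = NULL,
                                        stringsAsFactors = FALSE),
              logLik = ll, n = n, k = k, aicc = aicc_value(ll, k, n),
              r2 = r2c, sigma = sqrt(resid_var),
              fitted = stats::fitted(fit), residuals = stats::resid(fit),
              group_var = group_var, resid_var = resid_var,
              singular = singular, spec = design$spec, lmer = fit)
  class(out) <- "slip_fit"
  out
}

#' @export
print.slip_fit <- function(x, ...) {
  cat(sprintf("<slip_fit %s> response: %s, n = %d, AICc = %.2f, r2 = %.3f\n",
              x$type, x$spec$response, x$n, x$aicc, x$r2))
  if (nrow(x$coefficients) > 0) {
    print(x$coefficients, digits = 4)
  }
  if (isTRUE(x$singular)) cat("  (singular random-effect variance)\n")
  invisible(x)
}

#' Convenience: fit one model spec on a stroke table
#'
#' Builds the design and dispatches to the linear or mixed fitter
#' according to the spec's random-intercept grouping.
#'
#' @param tab a `stroke_table`.
#' @param spec a [model_spec()].
#' @param g gravitational acceleration (cm/s^2).
#' @return a `slip_fit`.
#' @export
fit_model <- function(tab, spec, g = 980.665) {
  d <- design_matrix(tab, spec, g)
  if (spec$random_intercept == "none") fit_linear(d) else
    fit_mixed_random_intercept(d)
}
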