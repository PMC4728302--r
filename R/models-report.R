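#' Percentage contribution of each model term
#'
#' For each fitted term, the coefficient magnitude times the mean
#' absolute value of its predictor, normalized so the contributions sum
#' to 100 percent.
#'
#' @param fit a `slip_fit` with at least one term.
#' @param tab the `stroke_table` the fit was built from.
#' @param g gravitational acceleration (cm/s^2).
#' @return data.frame with `term`, `K`, `mean_abs_x`,
#'   `contribution_pct`.
#' @export
contribution_table <- function(fit, tab, g = 980.665) {
  stopifnot(inherits(fit, "slip_fit"))
  d <- design_matrix(tab, fit$spec, g)
  co <- fit$coefficients
  co <- co[co$term %in% colnames(d$X), , drop = FALSE]
  if (nrow(co) == 0) stop("fit has no terms to apportion")
  mabs <- vapply(co$term, function(tm) mean(abs(d$X[, tm])), numeric(1))
  w <- abs(co$estimate) * mabs
  if (sum(w) <= 0) stop("all term contributions are zero")
  data.frame(term = co$term, K = co$estimate, mean_abs_x = unname(mabs),
             contribution_pct = unname(100 * w / sum(w)),
             stringsAsFactors = FALSE)
}

#' Damping time constants from fitted velocity coefficients
#'
#' Treats each fitted collinear-velocity damping term (`ydot` on the
#' lateral acceleration, `zdot` on the vertical) as the rate constant
#' of a first-order decay, all other terms at equilibrium: time
#' constant `-1/K` and half-life `ln(2) * (-1/K)`. Non-negative
#' coefficients are flagged and yield non-finite values.
#'
#' @param fit a `slip_fit` for a `yddot` or `zddot` (or `betadot`)
#'   response containing a velocity term.
#' @return data.frame with `term`, `K`, `time_constant_s`,
#'   `half_life_s`, `damped`.
#' @export
damping_time_constants <- function(fit) {
  stopifnot(inherits(fit, "slip_fit"))
  co <- fit$coefficients
  vel <- co[co$term %in% c("ydot", "zdot"), , drop = FALSE]
  if (nrow(vel) == 0) stop("fit contains no velocity-damping coefficient")
  out <- data.frame(term = vel$term, K = vel$estimate,
                    time_constant_s = NA_real_, half_life_s = NA_real_,
                    damped = vel$estimate < 0, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    if (out$damped[i]) {
      out$time_constant_s[i] <- -1 / out$K[i]
      out$half_life_s[i] <- log(2) * out$time_constant_s[i]
    } else {
      warning("non-negative damping coefficient for ", out$term[i])
      out$time_constant_s[i] <- Inf
      out$half_life_s[i] <- Inf
    }
  }
  out
}

#' Roll-velocity percentile-binned t-tests
#'
#' Splits halfstrokes at the 25th percentile of |roll velocity|:
#' the bottom quartile is treated as normal flapping, the rest as
#' high-roll-velocity flapping. For each wing measure (pitch, sweep
#' amplitude, elevation amplitude, midstroke elevation) the
#' roll-ipsilateral and roll-contralateral wing values during high roll
#' velocity are compared against the normal-flapping baseline
#' (one-sample t against the baseline mean) and against one another
#' (unpaired two-sample t).
#'
#' @param tab a `stroke_table` with >= 8 rows in each bin.
#' @return data.frame with `measure`, `comparison`, `mean_a`, `mean_b`,
#'   `diff`, `p`.
#' @export
updown_binned_ttests <- function(tab) {
  bd <- abs(tab$betadot)
  ok <- is.finite(bd)
  q25 <- stats::quantile(bd[ok], 0.25, na.rm = TRUE)
  normal <- ok & bd <= q25
  high <- ok & bd > q25
  if (sum(normal) < 8 || sum(high) < 8) {
    stop("need >= 8 halfstrokes in both the normal and high-roll bins")
  }
  ipsi_side <- ifelse(tab$betadot > 0, "R", "L")  # side toward the roll
  contra_side <- ifelse(tab$betadot > 0, "L", "R")
  pick <- function(meas, side) {
    vapply(seq_len(nrow(tab)), function(i)
      tab[[paste0(meas, "_", side[i])]][i], numeric(1))
  }
  safe_t <- function(a, b = NULL, mu = 0) {
    tryCatch({
      if (is.null(b)) stats::t.test(a, mu = mu)$p.value
      else stats::t.test(a, b)$p.value
    }, error = function(e) {
      warning("degenerate comparison (essentially constant data)")
      1
    })
  }
  out <- list()
  for (meas in c("alpha", "phi_p", "theta_p", "theta")) {
    base_vals <- c(tab[[paste0(meas, "_L")]][normal],
                   tab[[paste0(meas, "_R")]][normal])
    base_mu <- mean(base_vals, na.rm = TRUE)
    iv <- pick(meas, ipsi_side)[high]
    cv <- pick(meas, contra_side)[high]
    out[[length(out) + 1]] <- data.frame(
      measure = meas, comparison = "ipsi_vs_normal",
      mean_a = mean(iv, na.rm = TRUE), mean_b = base_mu,
      diff = mean(iv, na.rm = TRUE) - base_mu,
      p = safe_t(iv[is.finite(iv)], mu = base_mu), stringsAsFactors = FALSE)
    out[[length(out) + 1]] <- data.frame(
      measure = meas, comparison = "contra_vs_normal",
      mean_a = mean(cv, na.rm = TRUE), mean_b = base_mu,
      diff = mean(cv, na.rm = TRUE) - base_mu,
      p = safe_t(cv[is.finite(cv)], mu = base_mu), stringsAsFactors = FALSE)
    out[[length(out) + 1]] <- data.frame(
      measure = meas, comparison = "ipsi_vs_contra",
      mean_a = mean(iv, na.rm = TRUE), mean_b = mean(cv, na.rm = TRUE),
      diff = mean(iv, na.rm = TRUE) - mean(cv, na.rm = TRUE),
      p = safe_t(iv[is.finite(iv)], cv[is.finite(cv)]),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Compare roll-velocity against roll-acceleration models
#'
#' Fits the wing-asymmetry term set against both the first and the
#' second derivative of roll: single-term regressions per asymmetry
#' plus the full set, all without intercepts. In a heavily damped
#' (first-order) roll system the velocity model fits far better and
#' the acceleration regressions show no consistent trends.
#'
#' @param tab a `stroke_table` with a `betaddot` column.
#' @param terms asymmetry term names; defaults to the roll-velocity
#'   set.
#' @param g gravitational acceleration (cm/s^2).
#' @return list with `table` (per-model r2 and minimum coefficient
#'   p-value), `r2_betadot`, `r2_betaddot` (full-model values).
#' @export
roll_acceleration_check <- function(tab, terms = default_terms("betadot"),
                                    g = 980.665) {
  if (!"betaddot" %in% names(tab)) stop("stroke table lacks 'betaddot'")
  rows <- list()
  fulls <- list()
  for (resp in c("betadot", "betaddot")) {
    for (tm in terms) {
      ft <- fit_linear(design_matrix(tab, model_spec(resp, tm), g))
      rows[[length(rows) + 1]] <- data.frame(
        response = resp, model = tm, r2 = ft$r2,
        p_min = min(ft$coefficients$p), stringsAsFactors = FALSE)
    }
    ff <- fit_linear(design_matrix(tab, model_spec(resp, terms), g))
    fulls[[resp]] <- ff
    rows[[length(rows) + 1]] <- data.frame(
      response = resp, model = "full", r2 = ff$r2,
      p_min = min(ff$coefficients$p), stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, rows),
       r2_betadot = fulls$betadot$r2,
       r2_betaddot = fulls$betaddot$r2)
}
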