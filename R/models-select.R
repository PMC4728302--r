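#' AICc cascade model selection
#'
#' Implements the cascade comparison: candidate terms are ordered by
#' their significance in the full-model linear fit (smallest p first,
#' ties broken by larger |t|); the model is grown term by term, a term
#' being accepted only if it decreases AICc against the current model;
#' after each acceptance the cascade recurses one step by re-testing
#' the model with the lone exclusion of the previously confirmed term.
#' Once the linear cascade is complete, random-intercept variants of
#' the surviving specification are evaluated and the minimum-AICc model
#' is returned together with the full decision trace.
#'
#' @param tab a `stroke_table`.
#' @param response the response derivative.
#' @param candidates candidate term names (>= 2); defaults to the full
#'   a priori pool for the response.
#' @param intercept whether the linear models carry an intercept
#'   (ignored, forced FALSE, for roll responses).
#' @param groupings random-intercept groupings to evaluate after the
#'   linear cascade.
#' @param g gravitational acceleration (cm/s^2).
#' @return list with `spec` (best [model_spec()]), `fit` (its
#'   `slip_fit`), `trace` (data.frame of every comparison), and
#'   `full_fit` (the all-candidates linear fit used for ordering and
#'   reported p-values).
#' @export
cascade_select <- function(tab, response, candidates = NULL,
                           intercept = response %in% c("yddot", "zddot"),
                           groupings = c("moth", "trial"), g = 980.665) {
  if (is.null(candidates)) candidates <- default_terms(response, full = TRUE)
  if (length(candidates) < 2) stop("need >= 2 candidate terms")
  if (response %in% c("betadot", "betaddot")) intercept <- FALSE

  mk <- function(terms, grouping = "none") {
    model_spec(response, terms, intercept = intercept,
               random_intercept = grouping)
  }
  full_fit <- fit_linear(design_matrix(tab, mk(candidates), g))
  co <- full_fit$coefficients
  co <- co[co$term %in% candidates, ]
  ord <- co$term[order(co$p, -abs(co$t))]

  trace <- list()
  note <- function(action, terms, aicc, accepted) {
    trace[[length(trace) + 1]] <<- data.frame(
      step = length(trace) + 1L, action = action,
      terms = paste(terms, collapse = "+"), aicc = aicc,
      accepted = accepted, stringsAsFactors = FALSE)
  }

  current <- character(0)
  cur_fit <- fit_linear(design_matrix(tab, mk(current), g))
  note("null", current, cur_fit$aicc, TRUE)
  prev_confirmed <- NULL
  for (tm in ord) {
    trial <- c(current, tm)
    tf <- fit_linear(design_matrix(tab, mk(trial), g))
    if (tf$aicc < cur_fit$aicc) {
      note("add", trial, tf$aicc, TRUE)
      current <- trial
      cur_fit <- tf
      # recurse one step: lone exclusion of the previously confirmed term
      if (!is.null(prev_confirmed) && prev_confirmed %in% current) {
        reduced <- setdiff(current, prev_confirmed)
        rf <- fit_linear(design_matrix(tab, mk(reduced), g))
        if (rf$aicc < cur_fit$aicc) {
          note("drop", reduced, rf$aicc, TRUE)
          current <- reduced
          cur_fit <- rf
        } else {
          note("drop", reduced, rf$aicc, FALSE)
        }
      }
      prev_confirmed <- tm
    } else {
      note("add", trial, tf$aicc, FALSE)
    }
  }

  best_spec <- mk(current)
  best_fit <- cur_fit
  if (length(current) > 0) {
    for (grp in groupings) {
      sp <- mk(current, grp)
      mf <- tryCatch(fit_mixed_random_intercept(design_matrix(tab, sp, g)),
                     error = function(e) NULL)
      if (is.null(mf)) next
      note(paste0("random_intercept:", grp), current, mf$aicc,
           mf$aicc < best_fit$aicc)
      if (mf$aicc < best_fit$aicc) {
        best_spec <- sp
        best_fit <- mf
      }
    }
  }
  list(spec = best_spec, fit = best_fit,
       trace = do.call(rbind, trace), full_fit = full_fit)
}

#' Exhaustive minimum-AICc enumeration (oracle-style reference)
#'
#' Fits every subset of the candidate terms and returns the
#' minimum-AICc specification. Practical only for small candidate
#' sets; used as an independent reference for the cascade.
#'
#' @inheritParams cascade_select
#' @return list with `terms` (best subset) and `aicc_table`.
#' @export
exhaustive_select <- function(tab, response, candidates,
                              intercept = response %in% c("yddot", "zddot"),
                              g = 980.665) {
  if (response %in% c("betadot", "betaddot")) intercept <- FALSE
  nsub <- 2^length(candidates)
  res <- list()
  for (m in 0:(nsub - 1)) {
    terms <- candidates[bitwAnd(m, 2^(seq_along(candidates) - 1)) > 0]
    sp <- model_spec(response, terms, intercept = intercept)
    ft <- fit_linear(design_matrix(tab, sp, g))
    res[[m + 1]] <- data.frame(terms = paste(terms, collapse = "+"),
                               aicc = ft$aicc, stringsAsFactors = FALSE)
  }
  tabres <- do.call(rbind, res)
  best <- tabres$terms[which.min(tabres$aicc)]
  list(terms = if (best == "") character(0) else
    strsplit(best, "+", fixed = TRUE)[[1]], aicc_table = tabres)
}
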