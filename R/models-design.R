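#' Model specification for body-derivative regressions
#'
#' Describes one candidate model: the response (a body orientation or
#' position derivative), an ordered set of predictor terms drawn from
#' the term registry (see [model_terms()]), an intercept flag, an
#' optional random-intercept grouping, and terms for which separate
#' up- and downstroke coefficients are estimated. Roll-velocity and
#' roll-acceleration responses never carry an intercept: a stably
#' hovering moth has no wing asymmetry and no roll damping torque, so
#' a significant intercept would indicate a mis-specified model.
#'
#' @param response one of "yddot", "zddot", "betadot", "betaddot".
#' @param terms character vector of term names.
#' @param intercept logical; forced FALSE for roll responses.
#' @param random_intercept "none", "moth" or "trial".
#' @param updown_terms subset of `terms` fitted with separate up- and
#'   downstroke coefficients.
#' @return a `model_spec`.
#' @export
model_spec <- function(response = c("yddot", "zddot", "betadot", "betaddot"),
                       terms, intercept = FALSE,
                       random_intercept = c("none", "moth", "trial"),
                       updown_terms = character()) {
  response <- match.arg(response)
  random_intercept <- match.arg(random_intercept)
  unknown <- setdiff(terms, names(model_terms()))
  if (length(unknown) > 0) {
    stop("unknown term(s): ", paste(unknown, collapse = ", "),
         "; valid terms are: ", paste(names(model_terms()), collapse = ", "))
  }
  if (response %in% c("betadot", "betaddot") && intercept) {
    stop("roll-derivative models are fitted without an intercept")
  }
  if (!all(updown_terms %in% terms)) {
    stop("'updown_terms' must be a subset of 'terms'")
  }
  structure(list(response = response, terms = terms, intercept = intercept,
                 random_intercept = random_intercept,
                 updown_terms = updown_terms),
            class = "model_spec")
}

#' Predictor term registry
#'
#' Named list of functions building each predictor column from a stroke
#' table. Gravitational terms use `g` in cm/s^2; `sgnb_` prefixes mark
#' multiplication by the sign of the roll angle, which isolates the
#' force-amplification role of bilateral amplitude increases during
#' rolled flight.
#'
#' @param g gravitational acceleration (cm/s^2).
#' @return named list of functions `stroke_table -> numeric`.
#' @export
model_terms <- function(g = 980.665) {
  list(
    g_sin_beta = function(tab) g * sin(deg2rad(tab$beta)),
    g_versine_beta = function(tab) g * (1 - cos(deg2rad(tab$beta))),
    ydot = function(tab) tab$ydot,
    zdot = function(tab) tab$zdot,
    sgnb_phi_pc_bar = function(tab) tab$sgn_beta * tab$phi_pc_bar,
    sgnb_theta_pc_bar = function(tab) tab$sgn_beta * tab$theta_pc_bar,
    phi_pc_bar = function(tab) tab$phi_pc_bar,
    theta_pc_bar = function(tab) tab$theta_pc_bar,
    alpha_LR = function(tab) tab$alpha_LR,
    phi_p_LR = function(tab) tab$phi_p_LR,
    theta_p_LR = function(tab) tab$theta_p_LR,
    phi_LR = function(tab) tab$phi_LR,
    theta_LR = function(tab) tab$theta_LR,
    drag_i = function(tab) tab$drag_i,
    alpha_c_bar = function(tab) tab$alpha_c_bar,
    flap_freq = function(tab) {
      f <- attr(tab, "flap_frequency")
      rep(if (is.null(f)) 26 else f, nrow(tab))
    }
  )
}

#' Default model term sets
#'
#' The a priori term sets for each body derivative: lateral
#' acceleration is modeled by the rolled constant-force term plus
#' lateral velocity damping and sign-adjusted amplitude terms; vertical
#' acceleration by the conjugate versine term, vertical velocity
#' damping and amplitude terms; roll velocity by the wing pitch, sweep
#' amplitude and elevation amplitude asymmetries plus lateral velocity.
#' `full = TRUE` adds the additionally attempted kinematics (the
#' ipsilateral drag proxy, the centered bilateral wing pitch, and
#' instantaneous position asymmetries) used when reporting full-model
#' p-values.
#'
#' @param response one of "yddot", "zddot", "betadot", "betaddot".
#' @param full include the additionally attempted terms.
#' @return character vector of term names.
#' @export
default_terms <- function(response, full = FALSE) {
  base <- switch(response,
    yddot = c("g_sin_beta", "ydot", "sgnb_phi_pc_bar", "sgnb_theta_pc_bar"),
    zddot = c("g_versine_beta", "zdot", "phi_pc_bar", "theta_pc_bar"),
    betadot = c("alpha_LR", "phi_p_LR", "theta_p_LR", "ydot"),
    betaddot = c("alpha_LR", "phi_p_LR", "theta_p_LR", "ydot"),
    stop("unknown response"))
  if (!full) return(base)
  extra <- switch(response,
    yddot = c("drag_i", "alpha_c_bar"),
    zddot = c("drag_i", "alpha_c_bar"),
    betadot = c("phi_LR", "theta_LR", "drag_i"),
    betaddot = c("phi_LR", "theta_LR", "drag_i"))
  c(base, extra)
}

#' Build a response vector and predictor matrix from a stroke table
#'
#' Constructs the design exactly as specified: each term column from
#' the registry (including sign-of-roll multipliers and the
#' gravitational transforms), optional separate up/downstroke columns,
#' and the grouping factor for mixed models. Rows with missing values
#' are dropped and counted.
#'
#' @param tab a `stroke_table`.
#' @param spec a [model_spec()].
#' @param g gravitational acceleration (cm/s^2).
#' @return list with `y`, `X` (matrix, 0 columns allowed), `groups`
#'   (factor or NULL), `stroke`, `keep` (logical row mask over the
#'   input table), `n_dropped`, `spec`.
#' @export
design_matrix <- function(tab, spec, g = 980.665) {
  stopifnot(inherits(spec, "model_spec"))
  reg <- model_terms(g)
  y <- tab[[spec$response]]
  cols <- list()
  for (tm in spec$terms) {
    x <- reg[[tm]](tab)
    if (tm %in% spec$updown_terms) {
      cols[[paste0(tm, "_down")]] <- x * (tab$stroke == "down")
      cols[[paste0(tm, "_up")]] <- x * (tab$stroke == "up")
    } else {
      cols[[tm]] <- x
    }
  }
  X <- if (length(cols) > 0) do.call(cbind, cols) else
    matrix(numeric(0), nrow = nrow(tab), ncol = 0)
  groups <- switch(spec$random_intercept,
                   none = NULL,
                   moth = factor(tab$moth_id),
                   trial = factor(interaction(tab$moth_id, tab$trial_id)))
  keep <- is.finite(y)
  if (ncol(X) > 0) keep <- keep & apply(is.finite(X), 1, all)
  if (!is.null(groups)) keep <- keep & !is.na(groups)
  n_dropped <- sum(!keep)
  list(y = y[keep], X = X[keep, , drop = FALSE],
       groups = if (is.null(groups)) NULL else droplevels(groups[keep]),
       stroke = tab$stroke[keep], keep = keep, n_dropped = n_dropped,
       spec = spec)
}
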