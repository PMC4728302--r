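#' Build report figures and tables from a pipeline run
#'
#' Produces the standard analysis products: observed-versus-model
#' scatter panels with a unit-slope reference line for each body
#' derivative, per-halfstroke contribution traces (coefficient times
#' kinematic measure at midstrokes), a roll-versus-time stair-step
#' panel with endstroke markers, and coefficient/contribution tables.
#'
#' @param run a `sideslip_run` from [run_pipeline()].
#' @param trial trial index used for the time-series panels.
#' @return list with `figures` (named ggplot objects), `tables`
#'   (coefficient and contribution data.frames), and `data` (the
#'   numeric arrays behind each figure, for regeneration checks).
#' @export
make_report <- function(run, trial = 1) {
  stopifnot(inherits(run, "sideslip_run"))
  tab <- run$stroke_table
  g <- 980.665

  panel_data <- list()
  figures <- list()
  for (resp in c("yddot", "zddot", "betadot")) {
    fit <- run$fits[[paste0(resp, "_apriori")]]
    d <- design_matrix(tab, fit$spec, g)
    co <- fit$coefficients
    slope_terms <- co$term[co$term %in% colnames(d$X)]
    pred <- as.numeric(d$X[, slope_terms, drop = FALSE] %*%
                         co$estimate[match(slope_terms, co$term)])
    if ("(Intercept)" %in% co$term) {
      pred <- pred + co$estimate[co$term == "(Intercept)"]
    }
    df <- data.frame(model = pred, observed = d$y)
    panel_data[[resp]] <- df
    figures[[paste0("obs_vs_model_", resp)]] <-
      ggplot2::ggplot(df, ggplot2::aes(x = model, y = observed)) +
      ggplot2::geom_point(alpha = 0.5, size = 1) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linewidth = 1) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           color = "red", linewidth = 0.5) +
      ggplot2::labs(x = "model prediction", y = "observed",
                    title = paste("observed vs model:", resp))
  }

  # contribution traces at midstroke for the roll-velocity model
  bt <- run$fits$betadot_apriori
  db <- design_matrix(tab, bt$spec, g)
  keep_tab <- tab[db$keep, ]
  contrib <- sweep(db$X, 2, bt$coefficients$estimate[
    match(colnames(db$X), bt$coefficients$term)], `*`)
  tr_rows <- keep_tab$trial_id == unique(keep_tab$trial_id)[trial]
  cdf <- data.frame(time_s = rep(keep_tab$time_s[tr_rows], ncol(contrib) + 1),
                    series = rep(c(colnames(contrib), "betadot"),
                                 each = sum(tr_rows)),
                    value = c(as.numeric(contrib[tr_rows, ]),
                              keep_tab$betadot[tr_rows]))
  panel_data$contributions <- cdf
  figures$contributions <-
    ggplot2::ggplot(cdf, ggplot2::aes(x = time_s, y = value,
                                      color = series)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "roll velocity contribution (deg/s)")

  # stair-step roll for one trial
  fr <- run$frames[[trial]]
  kin <- frame_kinematics(fr)
  kdf <- data.frame(time_s = kin$time_s, roll = kin$roll,
                    endstroke = grepl("end", kin$phase))
  panel_data$stairstep <- kdf
  figures$stairstep <-
    ggplot2::ggplot(kdf, ggplot2::aes(x = time_s, y = roll)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = kdf[kdf$endstroke, ], color = "red") +
    ggplot2::labs(x = "time (s)", y = "body roll (deg)",
                  title = "roll advances mainly during downstrokes")

  coef_tables <- lapply(run$fits[c("yddot_apriori", "zddot_apriori",
                                   "yddot_mixed", "zddot_mixed",
                                   "betadot_apriori")],
                        function(f) f$coefficients)
  list(figures = figures,
       tables = c(coef_tables, run$checks$contributions),
       data = panel_data)
}
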