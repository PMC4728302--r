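#' Commanded sideslip maneuver schedule
#'
#' Builds the wing-command schedule of one sideslip trial: symmetric
#' hovering, a roll pulse toward `direction`, a counter-pulse that
#' rolls back, and symmetric recovery. During the pulses the
#' roll-contralateral wing pair flies at higher pitch and sweep
#' amplitude and lower elevation amplitude than the ipsilateral pair
#' (the asymmetry pattern of observed sideslips), with a smaller pitch
#' asymmetry during upstroke than downstroke, and both wings flap with
#' slightly increased sweep amplitude to keep supporting body weight
#' while rolled.
#'
#' @param base trimmed symmetric [wing_command()].
#' @param freq wingbeat frequency (Hz).
#' @param direction +1 for a rightward sideslip, -1 leftward.
#' @param strength scaling of all commanded asymmetries.
#' @param alpha_split_down peak left-right midstroke pitch difference
#'   during downstroke (deg) at `strength = 1`.
#' @param updown_ratio upstroke/downstroke pitch-asymmetry ratio (< 1
#'   reproduces the stair-step roll pattern).
#' @param phi_p_split left-right sweep amplitude difference (deg).
#' @param theta_p_split left-right elevation amplitude difference
#'   (deg); the contralateral wing gets the smaller elevation
#'   amplitude.
#' @param amp_boost fractional bilateral sweep-amplitude increase
#'   during the maneuver.
#' @param amp_jitter length-4 vector of fractional bilateral sweep
#'   amplitude perturbations, one per schedule segment (emulates the
#'   natural wander in flapping vigor, decorrelating amplitude from
#'   roll).
#' @param split_jitter 4 x 3 matrix of multiplicative perturbations of
#'   the pitch, sweep-amplitude and elevation-amplitude asymmetries per
#'   segment, so the three asymmetry channels are not locked in a fixed
#'   ratio within a trial.
#' @param pre_wb,pulse_wb,counter_wb,post_wb segment lengths in
#'   wingbeats.
#' @return list with `schedule` (for [integrate_flight()]) and
#'   `duration` (s).
#' @export
sideslip_schedule <- function(base, freq, direction = 1, strength = 1,
                              alpha_split_down = 4, updown_ratio = 0.64,
                              phi_p_split = 3, theta_p_split = 2,
                              amp_boost = 0.06, amp_jitter = c(0, 0, 0, 0),
                              split_jitter = matrix(1, 4, 3),
                              pre_wb = 2, pulse_wb = 5, counter_wb = 5,
                              post_wb = 3) {
  seg_i <- 0
  seg <- function(dir, scale, jit) {
    seg_i <<- seg_i + 1
    sj <- split_jitter[seg_i, ]
    cm <- base
    da_d <- dir * strength * scale * sj[1] * alpha_split_down / 2
    da_u <- da_d * updown_ratio
    dp <- dir * strength * scale * sj[2] * phi_p_split / 2
    dt <- dir * strength * scale * sj[3] * theta_p_split / 2
    boost <- (1 + amp_boost * scale) * (1 + jit)
    cm$left$alpha_down <- base$left$alpha_down + da_d
    cm$right$alpha_down <- base$right$alpha_down - da_d
    cm$left$alpha_up <- base$left$alpha_up + da_u
    cm$right$alpha_up <- base$right$alpha_up - da_u
    cm$left$Phi_p <- base$left$Phi_p * boost + dp
    cm$right$Phi_p <- base$right$Phi_p * boost - dp
    cm$left$theta_p <- max(0, base$left$theta_p - dt)
    cm$right$theta_p <- max(0, base$right$theta_p + dt)
    cm
  }
  Tw <- 1 / freq
  t1 <- pre_wb * Tw
  t2 <- t1 + pulse_wb * Tw
  t3 <- t2 + counter_wb * Tw
  dur <- t3 + post_wb * Tw
  list(schedule = list(
    list(t_start = -Inf, command = seg(0, 0, amp_jitter[1])),
    list(t_start = t1, command = seg(direction, 1, amp_jitter[2])),
    list(t_start = t2, command = seg(-direction, 0.7, amp_jitter[3])),
    list(t_start = t3, command = seg(0, 0, amp_jitter[4]))),
    duration = dur)
}

#' Pipeline run configuration
#'
#' Study conditions for a seeded end-to-end synthetic experiment:
#' number of moths, sideslip trials per moth, landmark noise and
#' missing-data rate, and whether observations pass through the
#' multi-camera projection/triangulation stage before kinematic
#' analysis.
#'
#' @param n_moths number of simulated moths (each with jittered
#'   morphology and its own hover trim).
#' @param trials_per_moth sideslip trials (one maneuver each) per moth.
#' @param noise_sd landmark noise (cm).
#' @param missing_p5_rate hindwing-tip missingness rate.
#' @param use_cameras route landmarks through synthetic cameras
#'   (project, add pixel noise, retriangulate).
#' @param pixel_noise_sd pixel noise when `use_cameras` is TRUE.
#' @param seed master seed; all stage seeds derive from it.
#' @param flap_frequency wingbeat frequency (Hz).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_moths = 4, trials_per_moth = 3,
                            noise_sd = 0.05, missing_p5_rate = 0.02,
                            use_cameras = FALSE, pixel_noise_sd = 0.15,
                            seed = 1L, flap_frequency = 26) {
  structure(list(n_moths = n_moths, trials_per_moth = trials_per_moth,
                 noise_sd = noise_sd, missing_p5_rate = missing_p5_rate,
                 use_cameras = use_cameras, pixel_noise_sd = pixel_noise_sd,
                 seed = as.integer(seed), flap_frequency = flap_frequency),
            class = "pipeline_config")
}

#' Run the full synthetic sideslip pipeline
#'
#' Simulates sideslip maneuvers for every moth and trial, renders them
#' into noisy digitized landmarks (optionally through the camera
#' stage), extracts kinematics, builds the pooled stroke table, and
#' fits the a priori acceleration and roll-velocity models plus the
#' AICc cascade selections. Deterministic given the configuration.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, stage artifacts
#'   (landmark CSVs, stroke table, coefficient tables, manifest) are
#'   written there.
#' @return a `sideslip_run` list: `config`, `frames` (list per trial),
#'   `stroke_table`, `fits` (a priori and cascade fits), `checks`
#'   (damping constants, roll-acceleration comparison, stroke-plane
#'   correlation, stair-step summary), `trajectories`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  n_tr <- config$n_moths * config$trials_per_moth
  mass_jit <- stats::rnorm(config$n_moths, 0, 0.05)
  inertia_jit <- stats::rnorm(config$n_moths, 0, 0.08)
  strength <- stats::runif(n_tr, 0.7, 1.3)
  # independent per-trial asymmetry mixtures so the commanded wing
  # asymmetries are not collinear across the data set
  alpha_split <- stats::runif(n_tr, 3, 7)
  phi_split <- stats::runif(n_tr, 0, 3)
  theta_split <- stats::runif(n_tr, 0, 2.5)
  ud_ratio <- stats::runif(n_tr, 0.5, 0.8)
  boost <- stats::runif(n_tr, 0.02, 0.10)
  amp_jit <- matrix(stats::rnorm(4 * n_tr, 0, 0.025), ncol = 4)
  split_jit <- array(stats::runif(4 * 3 * n_tr, 0.6, 1.4), c(4, 3, n_tr))

  frames_list <- list()
  traj_list <- list()
  trial_idx <- 0L
  for (m in seq_len(config$n_moths)) {
    cfg <- sim_config(body_mass = 2 * (1 + mass_jit[m]),
                      roll_inertia = 1.0 * (1 + inertia_jit[m]),
                      flap_frequency = config$flap_frequency,
                      seed = config$seed + m)
    trim <- trim_hover(cfg)
    for (tr in seq_len(config$trials_per_moth)) {
      trial_idx <- trial_idx + 1L
      dir <- if (trial_idx %% 2 == 0) -1 else 1
      sch <- sideslip_schedule(trim$command, cfg$flap_frequency,
                               direction = dir,
                               strength = strength[trial_idx],
                               alpha_split_down = alpha_split[trial_idx],
                               phi_p_split = phi_split[trial_idx],
                               theta_p_split = theta_split[trial_idx],
                               updown_ratio = ud_ratio[trial_idx],
                               amp_boost = boost[trial_idx],
                               amp_jitter = amp_jit[trial_idx, ],
                               split_jitter = split_jit[, , trial_idx])
      traj <- integrate_flight(cfg, sch$schedule, sch$duration)
      fr <- landmarks_from_trajectory(
        traj, morphology_template(wing_length = cfg$wing_length),
        noise_sd = config$noise_sd,
        missing_p5_rate = config$missing_p5_rate,
        seed = config$seed * 1000L + trial_idx,
        moth_id = paste0("m", m), trial_id = paste0("t", trial_idx))
      if (config$use_cameras) {
        fr <- through_cameras(fr, config, trial_idx)
      }
      frames_list[[trial_idx]] <- fr
      traj_list[[trial_idx]] <- traj
    }
  }

  tab <- build_stroke_table(frames_list)
  attr(tab, "flap_frequency") <- config$flap_frequency

  fits <- list(
    yddot_apriori = fit_model(tab, model_spec(
      "yddot", default_terms("yddot"), intercept = TRUE)),
    zddot_apriori = fit_model(tab, model_spec(
      "zddot", default_terms("zddot"), intercept = TRUE)),
    betadot_apriori = fit_model(tab, model_spec(
      "betadot", default_terms("betadot"))),
    # per-moth random-intercept variants; a single-moth run falls back
    # to the plain linear fit
    yddot_mixed = fit_mixed_or_linear(tab, "yddot"),
    zddot_mixed = fit_mixed_or_linear(tab, "zddot"),
    yddot_cascade = cascade_select(tab, "yddot"),
    zddot_cascade = cascade_select(tab, "zddot"),
    betadot_cascade = cascade_select(tab, "betadot"))

  checks <- list(
    damping_y = damping_time_constants(fits$yddot_apriori),
    damping_z = damping_time_constants(fits$zddot_apriori),
    roll_accel = roll_acceleration_check(tab),
    sp_roll_cor = strokeplane_roll_correlation(frames_list),
    stairstep = stairstep_summary(frames_list),
    contributions = list(
      yddot = contribution_table(fits$yddot_apriori, tab),
      zddot = contribution_table(fits$zddot_apriori, tab),
      betadot = contribution_table(fits$betadot_apriori, tab)))

  run <- list(config = config, frames = frames_list,
              stroke_table = tab, fits = fits, checks = checks,
              trajectories = traj_list)
  class(run) <- "sideslip_run"
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

fit_mixed_or_linear <- function(tab, response) {
  tryCatch(
    fit_model(tab, model_spec(response, default_terms(response),
                              intercept = TRUE, random_intercept = "moth")),
    error = function(e)
      fit_model(tab, model_spec(response, default_terms(response),
                                intercept = TRUE)))
}

through_cameras <- function(fr, config, trial_idx) {
  cams <- default_camera_rig()
  px <- project_to_cameras(fr, cams,
                           pixel_noise_sd = config$pixel_noise_sd,
                           seed = config$seed * 2000L + trial_idx)
  tri <- triangulate_table(cams, px)
  out <- fr
  for (p in unique(tri$point)) {
    sub <- tri[tri$point == p, ]
    i <- match(sub$frame, fr$frame)
    out[i, paste0(p, "_x")] <- sub$x
    out[i, paste0(p, "_y")] <- sub$y
    out[i, paste0(p, "_z")] <- sub$z
  }
  # retain the original missingness of the hindwing tips
  for (s in c("L", "R")) {
    miss <- !is.finite(fr[[paste0("p5", s, "_x")]])
    out[miss, paste0("p5", s, c("_x", "_y", "_z"))] <- NA_real_
  }
  attr(out, "truth") <- attr(fr, "truth")
  attr(out, "flap_frequency") <- attr(fr, "flap_frequency")
  class(out) <- class(fr)
  out
}

#' Default three-camera rig around the flight volume
#'
#' @return list of three `camera_model`s in general position.
#' @export
default_camera_rig <- function() {
  list(
    make_camera(c(120, 0, -20), c(0, 0, 0), focal_px = 1800, label = "cam1"),
    make_camera(c(-40, 110, -30), c(0, 0, 0), focal_px = 1800, label = "cam2"),
    make_camera(c(-60, -100, -40), c(0, 0, 0), focal_px = 1800, label = "cam3"))
}

#' Correlation of stroke-plane roll with body roll at midstroke
#'
#' @param frames a `landmark_frames` data.frame or list of them.
#' @return Pearson correlation across all midstroke frames.
#' @export
strokeplane_roll_correlation <- function(frames) {
  if (inherits(frames, "landmark_frames")) frames <- list(frames)
  sp <- c(); rl <- c()
  for (fr in frames) {
    kin <- frame_kinematics(fr)
    mid <- kin$phase %in% c("mid_down", "mid_up")
    sp <- c(sp, kin$sp_roll[mid])
    rl <- c(rl, kin$roll[mid])
  }
  ok <- is.finite(sp) & is.finite(rl)
  stats::cor(sp[ok], rl[ok])
}

#' Stair-step roll summary
#'
#' Measures the roll gained per halfstroke (endstroke to endstroke
#' change in body roll, signed by the trial's overall roll direction)
#' separately for down- and upstrokes.
#'
#' @param frames a `landmark_frames` data.frame or list of them.
#' @return list with `down_mean`, `up_mean` (deg per halfstroke,
#'   positive = toward the maneuver direction) and `increments`
#'   (data.frame).
#' @export
stairstep_summary <- function(frames) {
  if (inherits(frames, "landmark_frames")) frames <- list(frames)
  rows <- list()
  for (fr in frames) {
    kin <- frame_kinematics(fr)
    dir <- sign(kin$roll[which.max(abs(kin$roll))])
    if (dir == 0) dir <- 1
    idx <- function(wb, ph) which(kin$wingbeat == wb & kin$phase == ph)
    for (k in sort(unique(kin$wingbeat))) {
      for (stroke in c("up", "down")) {
        if (stroke == "up") {
          i1 <- idx(k, "end_down"); i2 <- idx(k, "end_up")
        } else {
          i1 <- idx(k, "end_up"); i2 <- idx(k + 1, "end_down")
        }
        if (length(i1) != 1 || length(i2) != 1) next
        rows[[length(rows) + 1]] <- data.frame(
          stroke = stroke, dbeta = dir * (kin$roll[i2] - kin$roll[i1]),
          stringsAsFactors = FALSE)
      }
    }
  }
  inc <- do.call(rbind, rows)
  list(down_mean = mean(inc$dbeta[inc$stroke == "down"]),
       up_mean = mean(inc$dbeta[inc$stroke == "up"]),
       increments = inc)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_along(run$frames)) {
    p <- file.path(out_dir, sprintf("landmarks_trial%02d.csv", i))
    write_landmark_csv(run$frames[[i]], p)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "stroke_table.csv")
  write_stroke_table(run$stroke_table, p)
  paths <- c(paths, p)
  co <- do.call(rbind, lapply(names(run$fits)[1:5], function(nm) {
    cbind(model = nm, run$fits[[nm]]$coefficients)
  }))
  p <- file.path(out_dir, "coefficients.csv")
  utils::write.csv(co, p, row.names = FALSE)
  paths <- c(paths, p)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mothslip")),
    seed = run$config$seed,
    config = unclass(run$config),
    files = as.list(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.sideslip_run <- function(x, ...) {
  cat("<sideslip_run>\n")
  cat(sprintf("  %d moths x %d trials, %d halfstrokes\n",
              x$config$n_moths, x$config$trials_per_moth,
              nrow(x$stroke_table)))
  k <- function(fit, term) {
    co <- fit$coefficients
    co$estimate[co$term == term]
  }
  cat(sprintf("  K[yddot~g sin(beta)] = %.3f, K[zddot~g versine] = %.3f\n",
              k(x$fits$yddot_apriori, "g_sin_beta"),
              k(x$fits$zddot_apriori, "g_versine_beta")))
  cat(sprintf("  K[betadot~alpha_LR] = %.3f, K[betadot~ydot] = %.4f\n",
              k(x$fits$betadot_apriori, "alpha_LR"),
              k(x$fits$betadot_apriori, "ydot")))
  cat(sprintf("  stroke-plane/body roll r = %.3f\n", x$checks$sp_roll_cor))
  invisible(x)
}
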