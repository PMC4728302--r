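#' Rigid body landmark template
#'
#' Positions (cm, body frame) of the digitized body points: scutum (p1),
#' abdomen tip (p2) and the two wing bases (p3L, p3R), plus the wing
#' length and the chord length used to place the forewing and hindwing
#' tip landmarks. The template is constructed so that the centroid of
#' p1/p3L/p3R lies on the body x-axis and the abdomen tip lies on the
#' same axis: the body-axis construction used by the kinematics module
#' then recovers the pose exactly.
#'
#' @param wing_length wing length (cm); must match the simulator
#'   configuration when rendering a trajectory.
#' @param chord_length hindwing-tip to forewing-tip distance (cm).
#' @param base_halfwidth half the distance between the wing bases (cm).
#' @return a `morphology` list.
#' @export
morphology_template <- function(wing_length = 5, chord_length = 2.5,
                                base_halfwidth = 0.55) {
  stopifnot_positive(wing_length, "wing_length")
  stopifnot_positive(chord_length, "chord_length")
  stopifnot_positive(base_halfwidth, "base_halfwidth")
  m <- list(
    p1_scutum = c(1.0, 0, -0.2),
    p2_abdomen = c(-2.0, 0, 0),
    p3L_base = c(0.25, -base_halfwidth, 0.1),
    p3R_base = c(0.25, base_halfwidth, 0.1),
    wing_length = wing_length,
    chord_length = chord_length
  )
  class(m) <- "morphology"
  m
}

# chord direction perpendicular to the span whose x/z-plane projection
# makes the pitch-path angle xi (deg, measured from +x, positive above
# horizontal) -- the same convention the kinematics module measures.
chord_direction <- function(s, a_hat, up, xi_deg) {
  xi <- deg2rad(xi_deg)
  A <- a_hat[1] * sin(xi) + a_hat[3] * cos(xi)
  B <- up[1] * sin(xi) + up[3] * cos(xi)
  psi <- atan2(-A, B)
  q <- cos(psi) * a_hat + sin(psi) * up
  # pick the branch whose projection points along (cos xi, sin xi)
  if (q[1] * cos(xi) + (-q[3]) * sin(xi) < 0) q <- -q
  q
}

#' Render a simulated trajectory into digitized landmark frames
#'
#' Samples the trajectory at the four stroke phases of each wingbeat
#' (end-downstroke, mid-upstroke, end-upstroke, mid-downstroke, located
#' at the extrema and mean crossings of the commanded sweep waveform)
#' and places the eight digitized landmarks from the rigid body template
#' posed by (y, z, roll) plus wing vectors from the commanded wing
#' kinematics. Isotropic Gaussian noise is added in the global frame and
#' hindwing tips are dropped at the stated rate.
#'
#' @param traj a trajectory from [integrate_flight()].
#' @param morphology a [morphology_template()]; its wing length must
#'   match the trajectory's configuration.
#' @param noise_sd isotropic landmark noise (cm), >= 0.
#' @param missing_p5_rate per-frame, per-wing probability that the
#'   hindwing tip is missing.
#' @param seed integer seed for noise and missingness.
#' @param moth_id,trial_id identifiers stored with the frames.
#' @return a `landmark_frames` data.frame: `frame`, `time_s`, `phase`,
#'   `wingbeat`, `moth_id`, `trial_id` and `<point>_x/_y/_z` columns for
#'   points p1, p2, p3L, p3R, p4L, p4R, p5L, p5R (NA when missing).
#'   The noiseless rendered truth (body pose and per-wing angles) is
#'   attached as attribute `"truth"`.
#' @export
landmarks_from_trajectory <- function(traj, morphology = morphology_template(),
                                      noise_sd = 0.05, missing_p5_rate = 0.02,
                                      seed = 1L, moth_id = "m1",
                                      trial_id = "t1") {
  cfg <- attr(traj, "config")
  sched <- attr(traj, "schedule")
  if (is.null(cfg) || is.null(sched)) {
    stop("'traj' must carry its config and schedule (from integrate_flight)")
  }
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (abs(morphology$wing_length - cfg$wing_length) > 1e-9) {
    stop("morphology wing_length is inconsistent with the trajectory config")
  }
  f <- cfg$flap_frequency
  t_lo <- min(traj$time_s)
  t_hi <- max(traj$time_s)
  if (t_hi - t_lo < 2 / f - 1e-9) stop("trajectory must cover >= 2 wingbeats")

  # phase offsets within the cycle, from the commanded sweep waveform
  ph_ref <- sched[[1]]$command$right$phase_Phi / 360
  offs <- c(end_down = 0, mid_up = 0.25, end_up = 0.5, mid_down = 0.75)
  k_min <- ceiling((t_lo * f + ph_ref) - 1e-9)
  times <- c()
  phases <- c()
  wingbeats <- c()
  for (k in k_min:floor(t_hi * f + ph_ref)) {
    for (j in seq_along(offs)) {
      tt <- (k + offs[j] - ph_ref) / f
      if (tt >= t_lo - 1e-12 && tt <= t_hi + 1e-12) {
        times <- c(times, tt)
        phases <- c(phases, names(offs)[j])
        wingbeats <- c(wingbeats, k)
      }
    }
  }
  ord <- order(times)
  times <- times[ord]; phases <- phases[ord]; wingbeats <- wingbeats[ord]
  nfr <- length(times)

  interp <- function(col) stats::approx(traj$time_s, traj[[col]], xout = times)$y
  y <- interp("y_cm"); z <- interp("z_cm"); beta <- interp("beta_deg")

  pts <- c("p1", "p2", "p3L", "p3R", "p4L", "p4R", "p5L", "p5R")
  out <- matrix(NA_real_, nrow = nfr, ncol = 3 * length(pts))
  truth <- data.frame(frame = seq_len(nfr), time_s = times, phase = phases,
                      wingbeat = wingbeats, yaw = 0, pitch = 0, beta = beta,
                      y = y, z = z,
                      Phi_L = NA_real_, Phi_R = NA_real_,
                      theta_L = NA_real_, theta_R = NA_real_,
                      alpha_L = NA_real_, alpha_R = NA_real_)

  for (i in seq_len(nfr)) {
    cm <- schedule_lookup(sched, times[i])
    wv <- wing_kinematics_waveform(cm, times[i], f)
    R <- rot_x(deg2rad(beta[i]))
    pos <- c(0, y[i], z[i])
    place <- function(p_brf) pos + as.numeric(R %*% p_brf)
    body <- list(p1 = morphology$p1_scutum, p2 = morphology$p2_abdomen,
                 p3L = morphology$p3L_base, p3R = morphology$p3R_base)
    coords <- list()
    for (nm in names(body)) coords[[nm]] <- place(body[[nm]])
    for (side in c("L", "R")) {
      wvs <- if (side == "L") wv$left else wv$right
      w <- if (side == "L") -1 else 1
      Phi <- deg2rad(wvs$Phi[1]); th <- deg2rad(wvs$theta[1])
      s <- c(cos(th) * sin(Phi), w * cos(th) * cos(Phi), -sin(th))
      a_hat <- c(cos(Phi), -w * sin(Phi), 0)
      up <- w * cross3(s, a_hat)
      q <- chord_direction(s, a_hat, up, wvs$xi[1])
      base <- morphology[[paste0("p3", side, "_base")]]
      p4 <- base + morphology$wing_length * s
      p5 <- p4 - morphology$chord_length * q
      coords[[paste0("p4", side)]] <- place(p4)
      coords[[paste0("p5", side)]] <- place(p5)
      truth[[paste0("Phi_", side)]][i] <- wvs$Phi[1]
      truth[[paste0("theta_", side)]][i] <- wvs$theta[1]
      # pitch recorded in the convention of the frame's phase label
      truth[[paste0("alpha_", side)]][i] <-
        if (grepl("down", phases[i])) wvs$xi[1] else 180 - wvs$xi[1]
    }
    out[i, ] <- unlist(coords[pts])
  }

  set.seed(seed)
  if (noise_sd > 0) {
    out <- out + matrix(stats::rnorm(length(out), 0, noise_sd), nrow = nfr)
  }
  miss_L <- stats::runif(nfr) < missing_p5_rate
  miss_R <- stats::runif(nfr) < missing_p5_rate

  df <- data.frame(frame = seq_len(nfr), time_s = times, phase = phases,
                   wingbeat = wingbeats, moth_id = moth_id, trial_id = trial_id,
                   stringsAsFactors = FALSE)
  cn <- as.vector(t(outer(pts, c("x", "y", "z"), paste, sep = "_")))
  colnames(out) <- cn
  df <- cbind(df, as.data.frame(out))
  df[miss_L, c("p5L_x", "p5L_y", "p5L_z")] <- NA_real_
  df[miss_R, c("p5R_x", "p5R_y", "p5R_z")] <- NA_real_
  attr(df, "truth") <- truth
  attr(df, "flap_frequency") <- f
  class(df) <- c("landmark_frames", "data.frame")
  df
}

#' Write / read a landmark CSV
#'
#' The schema (frame, time_s, phase, wingbeat, moth_id, trial_id, then
#' x/y/z per named point with blank cells for missing values) is shared
#' between synthetic and hand-digitized data.
#'
#' @param frames a `landmark_frames` data.frame.
#' @param path file path.
#' @param flap_frequency wingbeat frequency (Hz) to attach on read.
#' @return `path` invisibly (writer); `landmark_frames` (reader).
#' @export
write_landmark_csv <- function(frames, path) {
  utils::write.csv(as.data.frame(frames), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_landmark_csv
#' @export
read_landmark_csv <- function(path, flap_frequency = 26) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(df, "flap_frequency") <- flap_frequency
  class(df) <- c("landmark_frames", "data.frame")
  df
}
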