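#' Per-frame body pose and wing angle series
#'
#' Runs [body_euler()] and [wing_angles()] over every frame and
#' expresses the body position (centroid of scutum and wing bases) in
#' the MGRF, the yaw-rotated global frame in which +x is forward for
#' the moth, +y is the moth's right and z stays vertical.
#'
#' @param frames a `landmark_frames` data.frame.
#' @return data.frame with one row per frame: pose angles, MGRF
#'   position `y_m`, `z_m`, per-wing `Phi_*`, `theta_*`, `alpha_*`,
#'   `alpha_src_*` and `sp_roll` (stroke-plane roll; NA when a tip is
#'   missing).
#' @export
frame_kinematics <- function(frames) {
  n <- nrow(frames)
  out <- data.frame(frame = frames$frame, time_s = frames$time_s,
                    phase = frames$phase, wingbeat = frames$wingbeat,
                    moth_id = frames$moth_id, trial_id = frames$trial_id,
                    yaw = NA_real_, pitch = NA_real_, roll = NA_real_,
                    y_m = NA_real_, z_m = NA_real_,
                    Phi_L = NA_real_, Phi_R = NA_real_,
                    theta_L = NA_real_, theta_R = NA_real_,
                    alpha_L = NA_real_, alpha_R = NA_real_,
                    alpha_src_L = NA_character_, alpha_src_R = NA_character_,
                    sp_roll = NA_real_,
                    stringsAsFactors = FALSE)
  fwv <- array(NA_real_, dim = c(n, 2, 3),
               dimnames = list(NULL, c("L", "R"), NULL))
  for (i in seq_len(n)) {
    row <- frames[i, ]
    pose <- body_euler(row)
    out$yaw[i] <- pose$yaw; out$pitch[i] <- pose$pitch
    out$roll[i] <- pose$roll
    ctr <- c(mean(c(row$p1_x, row$p3L_x, row$p3R_x)),
             mean(c(row$p1_y, row$p3L_y, row$p3R_y)),
             mean(c(row$p1_z, row$p3L_z, row$p3R_z)))
    pm <- as.numeric(t(pose$yaw_R) %*% ctr)
    out$y_m[i] <- pm[2]; out$z_m[i] <- pm[3]
    wa <- wing_angles(row, pose)
    for (s in c("L", "R")) {
      r <- wa[wa$side == s, ]
      out[[paste0("Phi_", s)]][i] <- r$Phi
      out[[paste0("theta_", s)]][i] <- r$theta
      out[[paste0("alpha_", s)]][i] <- r$alpha
      out[[paste0("alpha_src_", s)]][i] <- r$alpha_src
      base <- as.numeric(row[paste0("p3", s, c("_x", "_y", "_z"))])
      tip <- as.numeric(row[paste0("p4", s, c("_x", "_y", "_z"))])
      fwv[i, s, ] <- as.numeric(t(pose$R_body) %*% (tip - base))
    }
    out$sp_roll[i] <- tryCatch(stroke_plane_roll(row), error = function(e) NA_real_)
  }
  attr(out, "fw_brf") <- fwv
  attr(out, "flap_frequency") <- attr(frames, "flap_frequency") %||% 26
  out
}

#' Build the halfstroke regression table
#'
#' Produces one row per halfstroke combining midstroke wing angles,
#' halfstroke amplitudes inserted at their midstroke points, left-right
#' asymmetries, pair means, and wingbeat-scale body state derivatives.
#' Columns suffixed `_c` are centered by subtracting the mean of the
#' entire (pooled) data set. Body position derivatives are computed in
#' the MGRF, roll absolute to the global horizontal; all wingbeat-scale
#' derivatives use like-phase differencing, and the body state assigned
#' to each halfstroke is the wingbeat-filtered value of its wingbeat.
#'
#' @param frames a `landmark_frames` data.frame, or a list of them
#'   (multiple trials pooled into one dataset before centering).
#' @return a `stroke_table` data.frame; the centering means are
#'   attached as attribute `"centering_means"` and halfstroke pattern
#'   summaries (down/up asymmetry ratios, lag autocorrelation of
#'   `alpha_LR`) as attribute `"annotations"`.
#' @export
build_stroke_table <- function(frames) {
  if (inherits(frames, "landmark_frames")) frames <- list(frames)
  tabs <- lapply(frames, stroke_table_one)
  tab <- do.call(rbind, tabs)
  rownames(tab) <- NULL

  # center across the whole data set
  center_cols <- c(alpha_bar = "alpha_c_bar", phi_p_bar = "phi_pc_bar",
                   theta_p_bar = "theta_pc_bar")
  means <- list()
  for (nm in names(center_cols)) {
    mu <- mean(tab[[nm]], na.rm = TRUE)
    means[[nm]] <- mu
    tab[[center_cols[[nm]]]] <- tab[[nm]] - mu
  }

  ann <- list()
  # pattern summaries over maneuvering halfstrokes (all rows if none
  # are labeled); the pitch asymmetry is aligned with each maneuver's
  # roll direction so that measurement noise averages out instead of
  # inflating the |mean| of the quieter halfstroke
  mrow <- if (any(!is.na(tab$maneuver_id))) !is.na(tab$maneuver_id) else
    rep(TRUE, nrow(tab))
  grp <- interaction(tab$trial_id, tab$maneuver_id, drop = TRUE)
  aligned <- rep(NA_real_, nrow(tab))
  for (gl in levels(grp)) {
    idx <- which(!is.na(grp) & grp == gl & mrow)
    if (length(idx) == 0) next
    dir <- sign(mean(tab$betadot[idx], na.rm = TRUE))
    if (is.na(dir) || dir == 0) dir <- 1
    aligned[idx] <- dir * tab$alpha_LR[idx]
  }
  dn <- tab$stroke == "down" & mrow
  up <- tab$stroke == "up" & mrow
  ann$alpha_LR_down_up_ratio <-
    mean(aligned[dn], na.rm = TRUE) / mean(aligned[up], na.rm = TRUE)
  ann$alpha_down_up_ratio <-
    mean(abs(tab$alpha_bar[dn]), na.rm = TRUE) /
    mean(abs(tab$alpha_bar[up]), na.rm = TRUE)
  x <- tab$alpha_LR[is.finite(tab$alpha_LR)]
  ann$alpha_LR_lag2_autocor <- if (length(x) > 6 && stats::sd(x) > 0) {
    stats::cor(x[-c(length(x) - 1, length(x))], x[-c(1, 2)])
  } else NA_real_

  attr(tab, "centering_means") <- means
  attr(tab, "annotations") <- ann
  class(tab) <- c("stroke_table", "data.frame")
  tab
}

stroke_table_one <- function(fr) {
  kin <- frame_kinematics(fr)
  fwv <- attr(kin, "fw_brf")
  f <- attr(kin, "flap_frequency")
  Tw <- 1 / f

  dy <- wingbeat_derivatives(kin$wingbeat, kin$phase, kin$y_m, Tw)
  dz <- wingbeat_derivatives(kin$wingbeat, kin$phase, kin$z_m, Tw)
  db <- wingbeat_derivatives(kin$wingbeat, kin$phase, kin$roll, Tw)
  wbs <- dy$wb$wingbeat
  beta_wb <- tapply(kin$roll, kin$wingbeat, mean, na.rm = TRUE)
  beta_wb <- as.numeric(beta_wb[match(wbs, as.numeric(names(beta_wb)))])
  t_wb <- tapply(kin$time_s, kin$wingbeat, mean, na.rm = TRUE)
  t_wb <- as.numeric(t_wb[match(wbs, as.numeric(names(t_wb)))])
  wbstate <- data.frame(wingbeat = wbs, time_wb = t_wb, beta = beta_wb,
                        ydot = dy$wb$d1, yddot = dy$wb$d2,
                        zdot = dz$wb$d1, zddot = dz$wb$d2,
                        betadot = db$wb$d1, betaddot = db$wb$d2)

  man <- segment_maneuvers(wbstate$time_wb, wbstate$yddot)
  wbstate$maneuver_id <- NA_integer_
  if (nrow(man) > 0) {
    for (m in seq_len(nrow(man))) {
      inm <- wbstate$time_wb >= man$start[m] - 1e-9 &
        wbstate$time_wb <= man$end[m] + 1e-9
      wbstate$maneuver_id[inm] <- m
    }
  }

  idx <- function(wb, phase) which(kin$wingbeat == wb & kin$phase == phase)
  rows <- list()
  hs <- 0L
  for (k in wbs) {
    for (stroke in c("up", "down")) {
      if (stroke == "up") {
        i_mid <- idx(k, "mid_up")
        i_e1 <- idx(k, "end_down"); i_e2 <- idx(k, "end_up")
      } else {
        i_mid <- idx(k, "mid_down")
        i_e1 <- idx(k, "end_up"); i_e2 <- idx(k + 1, "end_down")
      }
      if (length(i_mid) != 1 || length(i_e1) != 1 || length(i_e2) != 1) next
      hs <- hs + 1L
      amp <- lapply(c(L = "L", R = "R"), function(s) {
        stroke_amplitudes(fwv[i_e1, s, ], fwv[i_e2, s, ],
                          kin$phase[i_e1], kin$phase[i_e2])
      })
      st <- wbstate[wbstate$wingbeat == k, ]
      # fallback wing pitch (hindwing tip missing) is a flagged
      # placeholder, degenerate for a lateral wing at midstroke; keep
      # the row but not the value
      aL <- if (kin$alpha_src_L[i_mid] == "chord") kin$alpha_L[i_mid] else NA_real_
      aR <- if (kin$alpha_src_R[i_mid] == "chord") kin$alpha_R[i_mid] else NA_real_
      pL <- kin$Phi_L[i_mid]; pR <- kin$Phi_R[i_mid]
      tL <- kin$theta_L[i_mid]; tR <- kin$theta_R[i_mid]
      th_i <- if (is.finite(st$ydot) && st$ydot < 0) tL else tR
      vmag <- sqrt(st$ydot^2 + st$zdot^2)
      rows[[hs]] <- data.frame(
        halfstroke = hs, stroke = stroke, wingbeat = k,
        time_s = kin$time_s[i_mid],
        moth_id = kin$moth_id[i_mid], trial_id = kin$trial_id[i_mid],
        maneuver_id = st$maneuver_id,
        alpha_L = aL, alpha_R = aR, alpha_LR = aL - aR,
        alpha_bar = (aL + aR) / 2,
        phi_L = pL, phi_R = pR, phi_LR = pL - pR,
        theta_L = tL, theta_R = tR, theta_LR = tL - tR,
        phi_p_L = amp$L$Phi_p, phi_p_R = amp$R$Phi_p,
        phi_p_LR = amp$L$Phi_p - amp$R$Phi_p,
        phi_p_bar = (amp$L$Phi_p + amp$R$Phi_p) / 2,
        theta_p_L = amp$L$theta_p, theta_p_R = amp$R$theta_p,
        theta_p_LR = amp$L$theta_p - amp$R$theta_p,
        theta_p_bar = (amp$L$theta_p + amp$R$theta_p) / 2,
        psi_p_L = amp$L$Psi_p, psi_p_R = amp$R$Psi_p,
        psi_p_bar = (amp$L$Psi_p + amp$R$Psi_p) / 2,
        theta_i = th_i, drag_i = vmag * sin(deg2rad(th_i)),
        beta = st$beta, sgn_beta = sign(st$beta),
        betadot = st$betadot, betaddot = st$betaddot,
        ydot = st$ydot, yddot = st$yddot,
        zdot = st$zdot, zddot = st$zddot,
        alpha_fallback = kin$alpha_src_L[i_mid] != "chord" |
          kin$alpha_src_R[i_mid] != "chord",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a stroke table CSV with a JSON sidecar of centering means
#'
#' @param tab a `stroke_table`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.means.json`.
#' @return `path`, invisibly.
#' @export
write_stroke_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  means <- attr(tab, "centering_means")
  if (!is.null(means)) {
    jsonlite::write_json(means, paste0(path, ".means.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
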