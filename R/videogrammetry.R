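#' Construct a pinhole camera as an 11-coefficient DLT model
#'
#' Builds the direct linear transformation coefficients of an ideal
#' pinhole camera from its extrinsics and intrinsics. The DLT projection
#' is `u = (L1 X + L2 Y + L3 Z + L4) / (L9 X + L10 Y + L11 Z + 1)` and
#' analogously `v` with L5-L8; the 12th projective parameter is
#' normalized to 1, the convention of common digitization-tool
#' coefficient files.
#'
#' @param position camera center (cm, world/GRF).
#' @param target point the camera looks at (cm).
#' @param focal_px focal length in pixels.
#' @param image_size c(width, height) in pixels.
#' @param up approximate world up direction for the image vertical.
#' @param label camera identifier.
#' @return a `camera_model`: list with `L` (11 coefficients),
#'   `image_size`, `label`.
#' @export
make_camera <- function(position, target, focal_px = 1500,
                        image_size = c(1024, 1024), up = c(0, 0, -1),
                        label = "cam") {
  zc <- unitize(target - position)
  xc <- cross3(zc, unitize(up))
  if (sqrt(sum(xc^2)) < 1e-9) stop("camera 'up' is parallel to the view axis")
  xc <- unitize(xc)
  yc <- cross3(zc, xc)
  R <- rbind(xc, yc, zc)
  K <- matrix(c(focal_px, 0, 0,
                0, focal_px, 0,
                image_size[1] / 2, image_size[2] / 2, 1), nrow = 3)
  P <- K %*% cbind(R, -R %*% position)
  if (abs(P[3, 4]) < 1e-12) {
    stop("degenerate camera: projective normalizer is zero")
  }
  P <- P / P[3, 4]
  cam <- list(L = c(P[1, ], P[2, ], P[3, 1:3]), image_size = image_size,
              label = label)
  class(cam) <- "camera_model"
  cam
}

dlt_coeffs <- function(camera) {
  if (inherits(camera, "camera_model")) camera$L else as.numeric(camera)
}

#' Project 3D points through a DLT camera
#'
#' @param camera a `camera_model` or a length-11 coefficient vector.
#' @param xyz n x 3 matrix of world points (cm).
#' @return n x 2 matrix of pixel coordinates; rows are NA (with a
#'   warning) where the projective denominator is not positive (point at
#'   or behind the camera plane).
#' @export
dlt_project <- function(camera, xyz) {
  L <- dlt_coeffs(camera)
  xyz <- rbind(xyz)
  den <- xyz %*% L[9:11] + 1
  u <- (xyz %*% L[1:3] + L[4]) / den
  v <- (xyz %*% L[5:7] + L[8]) / den
  bad <- is.finite(den) & den <= 1e-12
  if (any(bad)) {
    warning(sum(bad), " point(s) at or behind the camera plane marked missing")
    u[bad] <- NA_real_
    v[bad] <- NA_real_
  }
  cbind(u = as.numeric(u), v = as.numeric(v))
}

#' Calibrate an 11-coefficient DLT camera from control points
#'
#' Solves the linear DLT system by least squares from known 3D control
#' points and their pixel positions, and reports the reprojection root
#' mean squared error.
#'
#' @param xyz n x 3 matrix of control point positions (cm), n >= 6,
#'   non-coplanar.
#' @param uv n x 2 matrix of matching pixel coordinates.
#' @param image_size optional c(width, height) stored with the model.
#' @param label camera identifier.
#' @return list with `camera` (a `camera_model`) and `rmse` (px).
#' @export
calibrate_dlt <- function(xyz, uv, image_size = c(1024, 1024), label = "cam") {
  xyz <- as.matrix(xyz); uv <- as.matrix(uv)
  keep <- stats::complete.cases(xyz) & stats::complete.cases(uv)
  xyz <- xyz[keep, , drop = FALSE]; uv <- uv[keep, , drop = FALSE]
  n <- nrow(xyz)
  if (n < 6) stop("DLT calibration needs >= 6 control points with pixel matches")
  A <- matrix(0, nrow = 2 * n, ncol = 11)
  b <- numeric(2 * n)
  X <- xyz[, 1]; Y <- xyz[, 2]; Z <- xyz[, 3]
  u <- uv[, 1]; v <- uv[, 2]
  odd <- seq(1, 2 * n, by = 2)
  A[odd, 1] <- X; A[odd, 2] <- Y; A[odd, 3] <- Z; A[odd, 4] <- 1
  A[odd, 9] <- -u * X; A[odd, 10] <- -u * Y; A[odd, 11] <- -u * Z
  b[odd] <- u
  A[odd + 1, 5] <- X; A[odd + 1, 6] <- Y; A[odd + 1, 7] <- Z; A[odd + 1, 8] <- 1
  A[odd + 1, 9] <- -v * X; A[odd + 1, 10] <- -v * Y; A[odd + 1, 11] <- -v * Z
  b[odd + 1] <- v
  sv <- svd(A)$d
  if (sv[11] / sv[1] < 1e-10) {
    stop("rank-deficient DLT system: control points are coplanar or otherwise degenerate")
  }
  L <- qr.solve(A, b)
  cam <- structure(list(L = as.numeric(L), image_size = image_size,
                        label = label), class = "camera_model")
  reproj <- dlt_project(cam, xyz)
  rmse <- sqrt(mean((reproj - uv)^2))
  list(camera = cam, rmse = rmse)
}

#' Triangulate a 3D point from multi-camera pixel observations
#'
#' Linear least-squares intersection of the DLT rays. Points observed by
#' fewer than two cameras yield a missing (NA) result rather than an
#' error, matching sparse manual digitization.
#'
#' @param cameras list of `camera_model`s.
#' @param uv k x 2 matrix of pixel observations, one row per camera (NA
#'   rows allowed).
#' @return list with `xyz` (length-3, NA if unreconstructable),
#'   `residual_px` (reprojection RMSE over contributing views), and
#'   `n_views`.
#' @export
triangulate <- function(cameras, uv) {
  uv <- rbind(uv)
  seen <- which(stats::complete.cases(uv))
  if (length(seen) < 2) {
    return(list(xyz = rep(NA_real_, 3), residual_px = NA_real_,
                n_views = length(seen)))
  }
  A <- matrix(0, nrow = 2 * length(seen), ncol = 3)
  b <- numeric(2 * length(seen))
  for (j in seq_along(seen)) {
    L <- dlt_coeffs(cameras[[seen[j]]])
    u <- uv[seen[j], 1]; v <- uv[seen[j], 2]
    A[2 * j - 1, ] <- L[1:3] - u * L[9:11]
    b[2 * j - 1] <- u - L[4]
    A[2 * j, ] <- L[5:7] - v * L[9:11]
    b[2 * j] <- v - L[8]
  }
  xyz <- as.numeric(qr.solve(A, b))
  res <- vapply(seen, function(i) {
    p <- dlt_project(cameras[[i]], xyz)
    sqrt(mean((p - uv[i, ])^2))
  }, numeric(1))
  list(xyz = xyz, residual_px = sqrt(mean(res^2)), n_views = length(seen))
}

#' Triangulate a table of pixel observations
#'
#' @param cameras list of `camera_model`s.
#' @param pixels data.frame with columns `camera`, `frame`, `point`,
#'   `u`, `v` (as produced by [project_to_cameras()]).
#' @return data.frame with one row per (frame, point): `frame`, `point`,
#'   `x`, `y`, `z`, `residual_px`, `n_views`.
#' @export
triangulate_table <- function(cameras, pixels) {
  labs <- vapply(cameras, function(c) c$label, character(1))
  keys <- unique(pixels[, c("frame", "point")])
  out <- keys
  out$x <- NA_real_; out$y <- NA_real_; out$z <- NA_real_
  out$residual_px <- NA_real_; out$n_views <- 0L
  for (i in seq_len(nrow(keys))) {
    sub <- pixels[pixels$frame == keys$frame[i] & pixels$point == keys$point[i], ]
    uv <- matrix(NA_real_, nrow = length(cameras), ncol = 2)
    idx <- match(sub$camera, labs)
    uv[idx, ] <- cbind(sub$u, sub$v)
    tri <- triangulate(cameras, uv)
    out[i, c("x", "y", "z")] <- tri$xyz
    out$residual_px[i] <- tri$residual_px
    out$n_views[i] <- tri$n_views
  }
  out
}

#' Project landmark frames to cameras
#'
#' Applies the DLT projection of each camera to every landmark of every
#' frame and adds isotropic pixel noise.
#'
#' @param frames a `landmark_frames` data.frame.
#' @param cameras list of >= 2 `camera_model`s.
#' @param pixel_noise_sd pixel noise standard deviation.
#' @param seed integer seed.
#' @return data.frame with columns `camera`, `frame`, `point`, `u`, `v`.
#' @export
project_to_cameras <- function(frames, cameras, pixel_noise_sd = 0.15,
                               seed = 1L) {
  if (length(cameras) < 2) stop("need >= 2 cameras")
  pts <- c("p1", "p2", "p3L", "p3R", "p4L", "p4R", "p5L", "p5R")
  set.seed(seed)
  res <- list()
  for (cam in cameras) {
    for (p in pts) {
      xyz <- as.matrix(frames[, paste0(p, "_", c("x", "y", "z"))])
      uv <- dlt_project(cam, xyz)
      if (pixel_noise_sd > 0) {
        uv <- uv + matrix(stats::rnorm(length(uv), 0, pixel_noise_sd),
                          ncol = 2)
      }
      res[[length(res) + 1]] <- data.frame(camera = cam$label,
                                           frame = frames$frame,
                                           point = p, u = uv[, 1], v = uv[, 2],
                                           stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out[order(out$camera, out$frame, out$point), ]
}

#' Generate a synthetic calibration wand track
#'
#' Moves a rigid two-LED wand along a smooth pseudo-random path filling
#' the working volume, with slowly varying orientation, and projects
#' both LEDs into every camera.
#'
#' @param cameras list of `camera_model`s.
#' @param volume list with `center` (cm) and `halfwidth` (cm, length 3).
#' @param n_frames number of frames, >= 40.
#' @param separation_mm true LED separation (mm).
#' @param pixel_noise_sd pixel noise added to the tracks.
#' @param seed integer seed.
#' @return a `wand_track`: list with `led3d` (data.frame frame, ax..bz,
#'   cm), `pixels` (camera, frame, led, u, v), `separation_mm`.
#' @export
generate_wand <- function(cameras, volume = list(center = c(0, 0, 0),
                                                 halfwidth = c(25, 25, 25)),
                          n_frames = 120, separation_mm = 68.5,
                          pixel_noise_sd = 0, seed = 1L) {
  if (n_frames < 40) stop("'n_frames' must be >= 40 to span the working volume")
  if (separation_mm <= 0) stop("'separation_mm' must be > 0")
  # the volume must be visible: its center must project into >= 2 cameras
  ctr_uv <- vapply(cameras, function(cam) {
    uv <- suppressWarnings(dlt_project(cam, rbind(volume$center)))
    all(is.finite(uv)) && uv[1] >= 0 && uv[1] <= cam$image_size[1] &&
      uv[2] >= 0 && uv[2] <= cam$image_size[2]
  }, logical(1))
  if (sum(ctr_uv) < 2) stop("working volume outside all camera frusta")

  set.seed(seed)
  tt <- seq(0, 1, length.out = n_frames)
  smooth_path <- function(half) {
    ph <- stats::runif(3, 0, 2 * pi)
    fr <- sample(2:4, 3, replace = TRUE)
    0.8 * half * (0.6 * sin(2 * pi * fr[1] * tt + ph[1]) +
                    0.4 * sin(2 * pi * fr[2] * tt + ph[2]))
  }
  ctr <- volume$center
  pos <- cbind(ctr[1] + smooth_path(volume$halfwidth[1]),
               ctr[2] + smooth_path(volume$halfwidth[2]),
               ctr[3] + smooth_path(volume$halfwidth[3]))
  az <- 2 * pi * tt * 2 + stats::runif(1, 0, 2 * pi)
  el <- pi / 3 * sin(2 * pi * tt * 1.5 + stats::runif(1, 0, 2 * pi))
  o <- cbind(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  d_cm <- separation_mm / 10
  a <- pos - o * d_cm / 2
  b <- pos + o * d_cm / 2
  led3d <- data.frame(frame = seq_len(n_frames),
                      ax = a[, 1], ay = a[, 2], az = a[, 3],
                      bx = b[, 1], by = b[, 2], bz = b[, 3])
  res <- list()
  for (cam in cameras) {
    for (led in c("a", "b")) {
      xyz <- if (led == "a") a else b
      uv <- dlt_project(cam, xyz)
      if (pixel_noise_sd > 0) {
        uv <- uv + matrix(stats::rnorm(length(uv), 0, pixel_noise_sd), ncol = 2)
      }
      res[[length(res) + 1]] <- data.frame(camera = cam$label,
                                           frame = seq_len(n_frames),
                                           led = led, u = uv[, 1], v = uv[, 2],
                                           stringsAsFactors = FALSE)
    }
  }
  out <- list(led3d = led3d, pixels = do.call(rbind, res),
              separation_mm = separation_mm)
  class(out) <- "wand_track"
  out
}

#' Wand reconstruction diagnostics
#'
#' Triangulates both wand LEDs in every frame and compares the
#' reconstructed separation against the nominal wand length.
#'
#' @param cameras list of calibrated `camera_model`s.
#' @param wand a `wand_track` from [generate_wand()] (or a compatible
#'   list with `pixels` and `separation_mm`).
#' @return list with `separation_mm` (per-frame reconstructed values),
#'   `mean_mm`, `sd_mm`, `rmse_mm` (against nominal), `nominal_mm`.
#' @export
wand_diagnostics <- function(cameras, wand) {
  if (wand$separation_mm <= 0) stop("nominal wand separation must be > 0")
  labs <- vapply(cameras, function(c) c$label, character(1))
  frames <- sort(unique(wand$pixels$frame))
  sep <- rep(NA_real_, length(frames))
  for (i in seq_along(frames)) {
    led_xyz <- lapply(c("a", "b"), function(led) {
      sub <- wand$pixels[wand$pixels$frame == frames[i] &
                           wand$pixels$led == led, ]
      uv <- matrix(NA_real_, nrow = length(cameras), ncol = 2)
      uv[match(sub$camera, labs), ] <- cbind(sub$u, sub$v)
      triangulate(cameras, uv)$xyz
    })
    if (all(is.finite(unlist(led_xyz)))) {
      sep[i] <- sqrt(sum((led_xyz[[1]] - led_xyz[[2]])^2)) * 10
    }
  }
  if (all(is.na(sep))) stop("no wand frame could be reconstructed")
  list(separation_mm = sep, mean_mm = mean(sep, na.rm = TRUE),
       sd_mm = stats::sd(sep, na.rm = TRUE),
       rmse_mm = sqrt(mean((sep - wand$separation_mm)^2, na.rm = TRUE)),
       nominal_mm = wand$separation_mm)
}

#' Write / read a DLT coefficient CSV
#'
#' The file layout is 11 rows with one column per camera, compatible
#' with common digitization-tool coefficient exports.
#'
#' @param cameras list of `camera_model`s.
#' @param path file path.
#' @param image_size image size to attach on read.
#' @return `path` invisibly (writer); list of `camera_model`s (reader).
#' @export
write_dlt_csv <- function(cameras, path) {
  m <- vapply(cameras, dlt_coeffs, numeric(11))
  colnames(m) <- vapply(cameras, function(c) c$label, character(1))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dlt_csv
#' @export
read_dlt_csv <- function(path, image_size = c(1024, 1024)) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) != 11) stop("a DLT coefficient file must have 11 rows")
  lapply(names(df), function(nm) {
    structure(list(L = as.numeric(df[[nm]]), image_size = image_size,
                   label = nm), class = "camera_model")
  })
}
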