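rand_points <- function(n, seed = 1) {
  set.seed(seed)
  cbind(stats::runif(n, -20, 20), stats::runif(n, -20, 20),
        stats::runif(n, -20, 20))
}

test_that("noiseless pinhole calibration recovers the DLT model exactly", {
  cam <- make_camera(c(100, 30, -25), c(0, 0, 0), focal_px = 1600,
                     label = "c1")
  xyz <- rand_points(20, seed = 2)
  uv <- dlt_project(cam, xyz)
  cal <- calibrate_dlt(xyz, uv, label = "c1")
  expect_lt(cal$rmse, 1e-8)
  expect_lt(max(abs(cal$camera$L - cam$L)), 1e-6)
  expect_equal(dlt_project(cal$camera, xyz), uv, tolerance = 1e-8)
})

test_that("deficient calibration geometry is rejected", {
  cam <- make_camera(c(100, 0, 0), c(0, 0, 0))
  xyz <- rand_points(5, seed = 3)
  expect_error(calibrate_dlt(xyz, dlt_project(cam, xyz)), ">= 6")
  coplanar <- cbind(stats::runif(12, -20, 20), stats::runif(12, -20, 20), 0)
  expect_error(calibrate_dlt(coplanar, dlt_project(cam, coplanar)),
               "coplanar|deficient")
})

test_that("projection/triangulation round trip is the identity", {
  cams <- default_camera_rig()
  xyz <- rand_points(50, seed = 4)
  for (i in seq_len(10)) {
    uv <- t(vapply(cams, function(cm) dlt_project(cm, xyz[i, , drop = FALSE])[1, ],
                   numeric(2)))
    tri <- triangulate(cams, uv)
    expect_lt(sqrt(sum((tri$xyz - xyz[i, ])^2)), 1e-6)
    expect_lt(tri$residual_px, 1e-6)
  }
})

test_that("a single view yields a missing triangulation, not an error", {
  cams <- default_camera_rig()
  uv <- rbind(c(512, 512), c(NA, NA), c(NA, NA))
  tri <- triangulate(cams, uv)
  expect_true(all(is.na(tri$xyz)))
  expect_identical(tri$n_views, 1L)
})

test_that("triangulation error under pixel noise is reproducible Monte Carlo", {
  cams <- default_camera_rig()
  run_mc <- function(seed) {
    xyz <- rand_points(300, seed = seed)
    set.seed(seed + 1000)
    errs <- vapply(seq_len(300), function(i) {
      uv <- t(vapply(cams, function(cm)
        dlt_project(cm, xyz[i, , drop = FALSE])[1, ], numeric(2)))
      uv <- uv + matrix(stats::rnorm(6, 0, 0.15), ncol = 2)
      sqrt(sum((triangulate(cams, uv)$xyz - xyz[i, ])^2))
    }, numeric(1))
    mean(errs)
  }
  e1 <- run_mc(11)
  e2 <- run_mc(77)
  expect_equal(e1, e2, tolerance = 0.1)
  # sub-millimeter at these camera distances, same order as calibration
  # residuals of a few hundredths of a pixel-projected centimeter
  expect_lt(e1, 0.1)
  expect_gt(e1, 1e-4)
})

test_that("wand diagnostics return the nominal separation on clean tracks", {
  cams <- default_camera_rig()
  wand <- generate_wand(cams, n_frames = 60, seed = 5)
  d3 <- sqrt((wand$led3d$ax - wand$led3d$bx)^2 +
               (wand$led3d$ay - wand$led3d$by)^2 +
               (wand$led3d$az - wand$led3d$bz)^2) * 10
  expect_equal(d3, rep(68.5, 60), tolerance = 1e-9)
  diag <- wand_diagnostics(cams, wand)
  expect_equal(diag$mean_mm, 68.5, tolerance = 1e-6)
  expect_lt(diag$sd_mm, 1e-6)
})

test_that("miscalibrated cameras produce a detectable separation bias", {
  cams <- default_camera_rig()
  wand <- generate_wand(cams, n_frames = 60, seed = 6)
  bad <- cams
  bad[[1]]$L <- bad[[1]]$L * 1.01
  diag <- wand_diagnostics(bad, wand)
  expect_gt(abs(diag$mean_mm - 68.5),
            3 * diag$sd_mm / sqrt(length(diag$separation_mm)))
})

test_that("wand generation validates its inputs and is deterministic", {
  cams <- default_camera_rig()
  expect_error(generate_wand(cams, n_frames = 10), ">= 40")
  expect_error(generate_wand(cams, n_frames = 60, separation_mm = 0), "> 0")
  a <- generate_wand(cams, n_frames = 45, seed = 8)
  b <- generate_wand(cams, n_frames = 45, seed = 8)
  expect_identical(a$pixels, b$pixels)
  far <- list(center = c(1e5, 0, 0), halfwidth = c(1, 1, 1))
  expect_error(generate_wand(cams, volume = far, n_frames = 60),
               "frusta")
})

test_that("calibration RMSE is invariant to uniform pixel translation", {
  cam <- make_camera(c(90, -40, -10), c(0, 0, 0))
  xyz <- rand_points(25, seed = 9)
  set.seed(10)
  uv <- dlt_project(cam, xyz) + matrix(stats::rnorm(50, 0, 0.2), ncol = 2)
  r1 <- calibrate_dlt(xyz, uv)$rmse
  r2 <- calibrate_dlt(xyz, uv + 37.5)$rmse
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("DLT coefficient CSV keeps the 11-row one-column-per-camera layout", {
  cams <- default_camera_rig()
  path <- tempfile(fileext = ".csv")
  write_dlt_csv(cams, path)
  raw <- utils::read.csv(path, check.names = FALSE)
  expect_identical(dim(raw), c(11L, 3L))
  back <- read_dlt_csv(path)
  expect_equal(back[[2]]$L, cams[[2]]$L, tolerance = 1e-12)
  expect_identical(back[[2]]$label, "cam2")
  unlink(path)
})
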