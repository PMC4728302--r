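test_that("design matrix columns follow the term definitions", {
  tab <- make_toy_table(8, seed = 2)
  tab$beta <- c(0, 0, 90, -90, 30, -30, 10, 45)
  tab$sgn_beta <- sign(tab$beta)
  d <- design_matrix(tab, model_spec("yddot",
                                     c("g_sin_beta", "g_versine_beta",
                                       "sgnb_phi_pc_bar")))
  expect_equal(unname(d$X[1:2, "g_sin_beta"]), c(0, 0))
  expect_equal(unname(d$X[1:2, "g_versine_beta"]), c(0, 0))
  expect_equal(unname(d$X[3, "g_sin_beta"]), 980.665)
  expect_equal(unname(d$X[4, "g_sin_beta"]), -980.665)
  expect_equal(d$X[, "sgnb_phi_pc_bar"], sign(tab$beta) * tab$phi_pc_bar)
  expect_error(design_matrix(tab, model_spec("yddot", "not_a_term")),
               "unknown term")
  expect_error(model_spec("betadot", "alpha_LR", intercept = TRUE),
               "without an intercept")
})

test_that("least squares reproduces exact and hand-computed fits", {
  tab <- make_toy_table(30, seed = 4)
  tab$yddot <- 980.665 * sin(tab$beta * pi / 180)
  ft <- fit_linear(design_matrix(tab, model_spec("yddot", "g_sin_beta")))
  expect_equal(coef_of(ft, "g_sin_beta"), 1, tolerance = 1e-12)
  expect_equal(ft$r2, 1, tolerance = 1e-9)
  # 3-point dataset against the normal equations solved by hand
  tab3 <- make_toy_table(3, seed = 5)
  tab3$betadot <- c(10, -4, 7)
  tab3$alpha_LR <- c(2, -1, 0.5)
  d <- design_matrix(tab3, model_spec("betadot", "alpha_LR"))
  ft3 <- fit_linear(d)
  K_hand <- sum(d$X[, 1] * d$y) / sum(d$X[, 1]^2)
  expect_equal(coef_of(ft3, "alpha_LR"), K_hand, tolerance = 1e-12)
})

test_that("null-effect p-values are uniform", {
  pv <- replicate(300, {
    tab <- make_toy_table(30, seed = sample.int(1e6, 1))
    ft <- fit_linear(design_matrix(tab, model_spec("betadot", "alpha_LR")))
    ft$coefficients$p[1]
  })
  ks <- stats::ks.test(pv, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("AICc follows the corrected formula and its domain", {
  # hand case: n = 10, k = 3, logLik = -12.5
  expect_equal(aicc_value(-12.5, 3, 10),
               -2 * -12.5 + 2 * 3 + 2 * 3 * 4 / (10 - 3 - 1))
  # the correction vanishes for large n
  expect_lt(abs(aicc_value(0, 3, 1e6) - 6), 1e-3)
  expect_error(aicc_value(-5, 9, 10), "AICc undefined")
})

test_that("rank-deficient designs name the collinear column", {
  tab <- make_toy_table(20, seed = 6)
  tab$phi_p_LR <- tab$alpha_LR
  expect_error(
    fit_linear(design_matrix(tab, model_spec("betadot",
                                             c("alpha_LR", "phi_p_LR")))),
    "collinear.*phi_p_LR")
})

test_that("a mixed fit degenerates to least squares when groups are alike", {
  set.seed(11)
  tab <- make_toy_table(80, seed = 11)
  tab$betadot <- 3 * tab$alpha_LR + stats::rnorm(80, 0, 5)
  spec_l <- model_spec("betadot", "alpha_LR")
  spec_m <- model_spec("betadot", "alpha_LR", random_intercept = "moth")
  fl <- fit_linear(design_matrix(tab, spec_l))
  fm <- fit_mixed_random_intercept(design_matrix(tab, spec_m))
  expect_equal(coef_of(fm, "alpha_LR"), coef_of(fl, "alpha_LR"),
               tolerance = 0.01)
})

test_that("REML recovers a known random-intercept spread", {
  sds <- replicate(200, {
    n_g <- 4; n_per <- 10
    tab <- make_toy_table(n_g * n_per, seed = sample.int(1e6, 1))
    g <- factor(rep(seq_len(n_g), each = n_per))
    b <- stats::rnorm(n_g, 0, 50)
    x <- stats::rnorm(n_g * n_per, 0, 3)
    y <- 2 * x + b[g] + stats::rnorm(n_g * n_per, 0, 20)
    tab$moth_id <- paste0("m", as.integer(g))
    tab$alpha_LR <- x
    tab$betadot <- y
    fm <- fit_mixed_random_intercept(
      design_matrix(tab, model_spec("betadot", "alpha_LR",
                                    random_intercept = "moth")))
    sqrt(fm$group_var)
  })
  expect_gt(mean(sds), 35)
  expect_lt(mean(sds), 65)
})

test_that("the REML objective matches a brute-force profile grid", {
  set.seed(3)
  n <- 12
  g <- factor(rep(1:2, each = 6))
  x <- stats::rnorm(n)
  y <- 2 * x + rep(c(-3, 3), each = 6) + stats::rnorm(n)
  tab <- make_toy_table(n)
  tab$moth_id <- paste0("m", as.integer(g))
  tab$alpha_LR <- x
  tab$yddot <- y
  spec <- model_spec("yddot", "alpha_LR", intercept = TRUE,
                     random_intercept = "moth")
  fm <- fit_mixed_random_intercept(design_matrix(tab, spec))
  X <- cbind(1, x)
  Z <- stats::model.matrix(~ 0 + g)
  p <- 2
  remll <- function(lam) {
    W <- diag(n) + lam * Z %*% t(Z)
    Wi <- solve(W)
    XtWiX <- t(X) %*% Wi %*% X
    b <- solve(XtWiX, t(X) %*% Wi %*% y)
    r <- y - X %*% b
    s2 <- as.numeric(t(r) %*% Wi %*% r) / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * s2) + 1) +
              as.numeric(determinant(W)$modulus) +
              as.numeric(determinant(XtWiX)$modulus))
  }
  best <- stats::optimize(function(l) -remll(exp(l)), c(-12, 12),
                          tol = 1e-10)
  expect_equal(-best$objective, fm$logLik, tolerance = 1e-6)
})

test_that("singular random effects are flagged, not fatal", {
  set.seed(12)
  tab <- make_toy_table(40, seed = 12)
  tab$betadot <- 2 * tab$alpha_LR + stats::rnorm(40, 0, 1)
  fm <- fit_mixed_random_intercept(
    design_matrix(tab, model_spec("betadot", "alpha_LR",
                                  random_intercept = "moth")))
  expect_true(is.logical(fm$singular))
  if (fm$singular) expect_lt(fm$group_var, 1e-6)
})

test_that("contribution percentages follow the weighted-magnitude rule", {
  tab <- make_toy_table(40, seed = 7)
  tab$betadot <- 2 * tab$alpha_LR + stats::rnorm(40, 0, 3)
  f1 <- fit_linear(design_matrix(tab, model_spec("betadot", "alpha_LR")))
  expect_equal(contribution_table(f1, tab)$contribution_pct, 100)
  f3 <- fit_linear(design_matrix(tab, model_spec(
    "betadot", c("alpha_LR", "phi_p_LR", "ydot"))))
  ct <- contribution_table(f3, tab)
  d <- design_matrix(tab, f3$spec)
  w_hand <- vapply(ct$term, function(tm)
    abs(coef_of(f3, tm)) * mean(abs(d$X[, tm])), numeric(1))
  expect_equal(ct$contribution_pct, unname(100 * w_hand / sum(w_hand)),
               tolerance = 1e-12)
  expect_equal(sum(ct$contribution_pct), 100, tolerance = 1e-9)
})

test_that("damping time constants invert the fitted velocity coefficient", {
  tab <- make_toy_table(40, seed = 8)
  tab$yddot <- -log(2) * tab$ydot + stats::rnorm(40, 0, 1e-9)
  ft <- fit_linear(design_matrix(tab, model_spec("yddot", "ydot")))
  dt <- damping_time_constants(ft)
  expect_equal(dt$half_life_s, 1, tolerance = 1e-6)
  # forward-integration oracle: time for v to halve under dv/dt = K v
  K <- dt$K
  v <- 1; t <- 0; h <- 1e-4
  while (v > 0.5) { v <- v + h * K * v; t <- t + h }
  expect_equal(t, dt$half_life_s, tolerance = 1e-3)
  # undamped coefficient is flagged
  tab$yddot <- 0.3 * tab$ydot + stats::rnorm(40, 0, 1e-9)
  fu <- fit_linear(design_matrix(tab, model_spec("yddot", "ydot")))
  expect_warning(du <- damping_time_constants(fu), "non-negative")
  expect_false(du$damped)
  expect_false(is.finite(du$time_constant_s))
})

test_that("binned t statistics match the textbook formulas", {
  tab <- make_toy_table(40, seed = 9)
  tab$betadot <- rep(c(5, 200), each = 20)  # clean quartile split
  tab$alpha_L <- c(stats::rnorm(20, 45, 2), stats::rnorm(20, 50, 2))
  tab$alpha_R <- c(stats::rnorm(20, 45, 2), stats::rnorm(20, 40, 2))
  tab$phi_p_L <- stats::rnorm(40, 115, 2); tab$phi_p_R <- stats::rnorm(40, 115, 2)
  tab$theta_p_L <- stats::rnorm(40, 30, 2); tab$theta_p_R <- stats::rnorm(40, 30, 2)
  tab$theta_L <- stats::rnorm(40, 10, 2); tab$theta_R <- stats::rnorm(40, 10, 2)
  tt <- updown_binned_ttests(tab)
  row <- tt[tt$measure == "alpha" & tt$comparison == "ipsi_vs_contra", ]
  high <- 21:40  # betadot = 200 rows, all rolling rightward -> ipsi = R
  oracle <- stats::t.test(tab$alpha_R[high], tab$alpha_L[high])$p.value
  expect_equal(row$p, oracle, tolerance = 1e-12)
  expect_lt(row$p, 0.05)
  base_mu <- mean(c(tab$alpha_L[1:20], tab$alpha_R[1:20]))
  row2 <- tt[tt$measure == "alpha" & tt$comparison == "ipsi_vs_normal", ]
  oracle2 <- stats::t.test(tab$alpha_R[high], mu = base_mu)$p.value
  expect_equal(row2$p, oracle2, tolerance = 1e-12)
})

test_that("a commanded pitch split is detected with high power", {
  hits <- replicate(100, {
    tab <- make_toy_table(50, seed = sample.int(1e6, 1))
    tab$betadot <- stats::runif(50, 30, 200)   # all rightward rolls
    tab$alpha_R <- stats::rnorm(50, 40 - 5, 2)  # ipsi pitched down
    tab$alpha_L <- stats::rnorm(50, 40 + 5, 2)  # contra pitched up
    tab$phi_p_L <- stats::rnorm(50, 115, 2); tab$phi_p_R <- stats::rnorm(50, 115, 2)
    tab$theta_p_L <- stats::rnorm(50, 30, 2); tab$theta_p_R <- stats::rnorm(50, 30, 2)
    tab$theta_L <- stats::rnorm(50, 10, 2); tab$theta_R <- stats::rnorm(50, 10, 2)
    tab$betadot[1:13] <- stats::runif(13, 0, 5)  # a normal-flapping bin
    tab$alpha_R[1:13] <- stats::rnorm(13, 40, 2)
    tab$alpha_L[1:13] <- stats::rnorm(13, 40, 2)
    tt <- updown_binned_ttests(tab)
    tt$p[tt$measure == "alpha" & tt$comparison == "ipsi_vs_contra"] < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("degenerate constant bins warn and return p near 1", {
  tab <- make_toy_table(40, seed = 10)
  tab$betadot <- rep(c(1, 100), each = 20)
  for (m in c("alpha", "phi_p", "theta_p", "theta")) {
    tab[[paste0(m, "_L")]] <- 42
    tab[[paste0(m, "_R")]] <- 42
  }
  w <- testthat::capture_warnings(tt <- updown_binned_ttests(tab))
  expect_true(any(grepl("degenerate", w)))
  expect_true(all(tt$p > 0.99))
})

test_that("roll-velocity models outperform roll-acceleration models only in damped systems", {
  # heavily damped truth: betadot tracks the asymmetry
  tab <- make_toy_table(80, seed = 13)
  tab$betadot <- 15 * tab$alpha_LR + stats::rnorm(80, 0, 10)
  tab$betaddot <- stats::rnorm(80, 0, 800)
  rc <- roll_acceleration_check(tab)
  expect_gt(rc$r2_betadot, rc$r2_betaddot)
  # constructed inverse (undamped) case: acceleration tracks the asymmetry
  tab2 <- make_toy_table(80, seed = 14)
  tab2$betaddot <- 400 * tab2$alpha_LR + stats::rnorm(80, 0, 100)
  tab2$betadot <- stats::rnorm(80, 0, 50)
  rc2 <- roll_acceleration_check(tab2)
  expect_gt(rc2$r2_betaddot, rc2$r2_betadot)
})
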