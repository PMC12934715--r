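test_that("transfer functions are non-negative, saturating and monotone", {
  tfs <- sig_tfs()
  # far below the inflection the saturating form is effectively silent
  far <- transfer_function("E", c(60, 40, 2, 2, 1, 0.02), "sigmoid")
  expect_lt(eval_transfer(far, 0, 10), 1e-6)
  grid <- expand.grid(nu_E = seq(0, 20, by = 2), nu_I = c(0, 4, 10),
                      w = c(0, 50))
  for (tf in c(tfs, fitted_tfs())) {
    r <- eval_transfer(tf, grid$nu_E, grid$nu_I, grid$w)
    expect_true(all(is.finite(r)) && all(r >= 0))
    # non-decreasing in nu_E, non-increasing in w, at every other point
    r_up <- eval_transfer(tf, grid$nu_E + 0.5, grid$nu_I, grid$w)
    expect_true(all(r_up >= r - 1e-9))
    r_w <- eval_transfer(tf, grid$nu_E, grid$nu_I, grid$w + 10)
    expect_true(all(r_w <= r + 1e-9))
  }
})

test_that("inputs outside the domain are clamped to the boundary", {
  tf <- fitted_tfs()$E
  hi <- tf$domain[2]
  expect_identical(eval_transfer(tf, hi + 5, 4), eval_transfer(tf, hi, 4))
  expect_identical(eval_transfer(tf, 2, -3), eval_transfer(tf, 2, 0))
})

test_that("non-finite coefficients are rejected as an invalid model", {
  tf <- sigmoid_transfer("E")
  tf$coefficients[2] <- NaN
  expect_error(eval_transfer(tf, 1, 1), "invalid model")
  expect_error(transfer_function("E", c(1, NA, 1, 1, 1, 1), "sigmoid"),
               "invalid model")
})

test_that("node drift vanishes at a fixed point and scales inversely with T", {
  tfs <- sig_tfs()
  st <- stationary_state(tfs$E, tfs$I, ext_E = 6, ext_I = 6, tol = 1e-10)
  expect_true(attr(st, "converged"))
  d <- node_drift(st, tfs$E, tfs$I, 6, 6)
  expect_lt(abs(d$dr_E), 1e-8)
  expect_lt(abs(d$dr_I), 1e-8)
  expect_lt(abs(d$dw), 1e-12)

  # away from the fixed point, doubling T halves the rate derivatives
  s2 <- node_state(st$r_E + 1, st$r_I, st$w_E)
  d1 <- node_drift(s2, tfs$E, tfs$I, 6, 6, cfg = mean_field_config(T_ms = 5))
  d2 <- node_drift(s2, tfs$E, tfs$I, 6, 6, cfg = mean_field_config(T_ms = 10))
  expect_equal(d1$dr_E, 2 * d2$dr_E)
  expect_equal(d1$dr_I, 2 * d2$dr_I)
})

test_that("adaptation is inert when b = 0 and relaxes at rate 1/tau_w", {
  tfs <- sig_tfs()
  p0 <- population_params("E", b = 0)
  d <- node_drift(node_state(3, 2, 0), tfs$E, tfs$I, 1, 1, params_E = p0)
  expect_identical(d$dw, 0)
  pb <- population_params("E", b = 40, tau_w = 500)
  db <- node_drift(node_state(3, 2, 10), tfs$E, tfs$I, 1, 1, params_E = pb)
  expect_equal(db$dw, -10 / 500 + 40 * 3 * 1e-3)
})

test_that("stationary state is init-independent and self-consistent", {
  tfs <- fitted_tfs()
  for (ext in c(0.6, 1.2)) {
    a <- stationary_state(tfs$E, tfs$I, ext, 1.4 * ext, tol = 1e-10,
                          init = node_state(0, 0, 0))
    b <- stationary_state(tfs$E, tfs$I, ext, 1.4 * ext, tol = 1e-10,
                          init = node_state(50, 50, 0))
    expect_true(attr(a, "converged") && attr(b, "converged"))
    expect_equal(a$r_E, b$r_E, tolerance = 1e-6)
    # independent residual re-evaluation
    FE <- eval_transfer(tfs$E, a$r_E + ext, a$r_I, a$w_E)
    FI <- eval_transfer(tfs$I, a$r_E + 1.4 * ext, a$r_I, 0)
    expect_lt(abs(FE - a$r_E), 1e-8)
    expect_lt(abs(FI - a$r_I), 1e-8)
  }
})

test_that("zero drive with a silent transfer function stays at rest", {
  tfs <- fitted_tfs()
  st <- stationary_state(tfs$E, tfs$I, 0, 0, init = node_state(0, 0, 0))
  expect_lt(st$r_E, 1e-4)
  expect_lt(st$r_I, 1e-4)
})

test_that("stationary excitatory rate is non-increasing in Qi", {
  tfs <- fitted_tfs()
  rates <- vapply(c(4, 5, 6), function(qi)
    stationary_state(tfs$E, tfs$I, 1, 1.4, qi = qi)$r_E, 0)
  expect_true(all(diff(rates) <= 1e-9))
})

test_that("fit_transfer recovers known coefficients exactly", {
  truth <- transfer_function("E", c(-50, 4, -6, 1, -1, 8, -2, 3, 0.5, -1),
                             "threshold_poly", domain = c(0, 20, 0, 20, 0, 100))
  grid <- expand.grid(nu_E = c(0.5, 1, 2, 4, 8, 12), nu_I = c(1, 3, 6, 10),
                      w = c(0, 40))
  grid$rate <- eval_transfer(truth, grid$nu_E, grid$nu_I, grid$w)
  fit <- fit_transfer(grid, "E", domain = truth$domain)
  # recovery is limited by the erfc inversion in the far tail
  expect_equal(coef(fit), coef(truth), tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_lt(fit$fit$rmse, 1e-3)

  # permuting the sample order leaves the fit unchanged
  set.seed(1)
  fit2 <- fit_transfer(grid[sample(nrow(grid)), ], "E",
                       domain = truth$domain)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-8)
})

test_that("degenerate fitting designs are rejected", {
  one <- data.frame(nu_E = 2, nu_I = 2, w = 0, rate = 5)
  expect_error(fit_transfer(one[rep(1, 20), ], "E"), "degenerate")
  few <- data.frame(nu_E = 1:4, nu_I = 1, w = 0, rate = c(1, 2, 3, 4))
  expect_error(fit_transfer(few, "E"), "degenerate")
})

test_that("transfer functions round-trip through the coefficient table", {
  tf <- transfer_function("E", c(-50, 4, -6, 1, -1, 8, -2, 3, 0.5, -1),
                          "threshold_poly", domain = c(0, 20, 0, 20, 0, 100))
  path <- tempfile(fileext = ".tsv")
  write_transfer_table(list(tf), path)
  back <- read_transfer_table(path)
  expect_equal(coef(back$E), coef(tf), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$E$domain, tf$domain, tolerance = 1e-12)
})
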