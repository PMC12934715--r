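test_that("a quiet network with subthreshold rest never spikes", {
  spec <- spiking_net_spec(N_E = 5, N_I = 2, p_conn = 0.2,
                           params_E = population_params("E", sigma = 0),
                           params_I = population_params("I", sigma = 0),
                           duration = 1, seed = 1)
  rec <- simulate_spiking(spec)
  expect_identical(nrow(rec$spikes), 0L)
  expect_identical(unname(rec$rates), c(0, 0))
})

test_that("the sharp-threshold limit reproduces the leaky IF interspike time", {
  p <- population_params("E", Delta = 1e-4, sigma = 0)
  I0 <- 300  # pA, suprathreshold: gL (Vthr - EL) = 130 pA
  spec <- spiking_net_spec(N_E = 1, N_I = 1, p_conn = 0, params_E = p,
                           I_ext = I0, duration = 1, dt = 0.01, seed = 1)
  rec <- simulate_spiking(spec)
  isi <- diff(rec$spikes$time[rec$spikes$neuron == 1])
  # reset is to EL, so the closed form reduces to Cm/gL log(I0/(I0 - gL(Vthr-EL)))
  pred <- p$Cm / p$gL * log(I0 / (I0 - p$gL * (p$Vthr - p$EL))) / 1000
  expect_gt(length(isi), 10)
  expect_lt(abs(mean(isi) - pred) / pred, 0.02)
})

test_that("strong adaptation slows firing across the first interspike intervals", {
  p <- population_params("E", Delta = 1e-4, sigma = 0, b = 60, tau_w = 2000)
  spec <- spiking_net_spec(N_E = 1, N_I = 1, p_conn = 0, params_E = p,
                           I_ext = 400, duration = 2, dt = 0.01, seed = 1)
  sp <- simulate_spiking(spec)$spikes
  isi <- diff(sp$time[sp$neuron == 1])
  expect_gt(length(isi), 5)
  expect_true(all(diff(isi[1:5]) > 0))
})

test_that("synaptic conductance decays e-fold in tau_syn after a spike", {
  # neuron 1 (E) fires periodically under constant current; neuron 2 (I)
  # stays silent (no drive) and its G_E trace shows the jumps and decay
  pE <- population_params("E", Delta = 1e-4, sigma = 0)
  pI <- population_params("I", sigma = 0, Vthr = 20)  # kept subthreshold
  spec <- spiking_net_spec(N_E = 1, N_I = 1, p_conn = 1, params_E = pE,
                           params_I = pI, I_ext = 200, duration = 0.5,
                           dt = 0.01, seed = 1, record_neuron = 2)
  rec <- simulate_spiking(spec)
  tsp <- rec$spikes$time[rec$spikes$neuron == 1]
  expect_gt(min(diff(tsp)), 0.02)  # isolated on the 5 ms scale
  k0 <- round(tsp[1] * 1000 / spec$dt)
  g0 <- rec$trace[k0 + 1, "G_E"]
  g5 <- rec$trace[k0 + 1 + round(5 / spec$dt), "G_E"]
  expect_equal(unname(g5 / g0), exp(-1), tolerance = 1e-3)
  expect_true(all(rec$trace[, c("G_E", "G_I")] >= 0))
})

test_that("identical seeds give bit-identical spike trains", {
  spec <- spiking_net_spec(N_E = 20, N_I = 5, ext_rate_E = 2000,
                           duration = 0.5, seed = 42)
  expect_identical(simulate_spiking(spec)$spikes,
                   simulate_spiking(spec)$spikes)
})

test_that("oversized integration steps raise an instability error", {
  spec <- spiking_net_spec(N_E = 2, N_I = 1, ext_rate_E = 5e4, dt = 40,
                           duration = 2, seed = 1)
  expect_error(simulate_spiking(spec), "diverged")
})

test_that("stationary rate estimates behave like sample means", {
  spec <- spiking_net_spec(N_E = 40, N_I = 10, p_conn = 0,
                           ext_rate_E = 400 * 2, ext_rate_I = 100 * 2,
                           duration = 4, seed = 1)
  est <- estimate_stationary_rate(spec, discard = 1)
  expect_error(estimate_stationary_rate(spec, discard = 5), "zero usable")

  # zero-spike record gives zero rates
  quiet <- spiking_net_spec(N_E = 3, N_I = 2,
                            params_E = population_params("E", sigma = 0),
                            params_I = population_params("I", sigma = 0),
                            duration = 1, seed = 1)
  e0 <- estimate_stationary_rate(quiet, discard = 0.1)
  expect_identical(c(e0$rate_E, e0$rate_I), c(0, 0))

  # two seeds agree within 3 pooled standard errors
  est2 <- estimate_stationary_rate(
    spiking_net_spec(N_E = 40, N_I = 10, p_conn = 0, ext_rate_E = 400 * 2,
                     ext_rate_I = 100 * 2, duration = 4, seed = 2),
    discard = 1)
  pooled <- sqrt(est$se_E^2 + est2$se_E^2)
  expect_lt(abs(est$rate_E - est2$rate_E), 3 * pooled + 1e-9)

  # stationarity: discard choice barely moves the estimate
  long <- estimate_stationary_rate(
    spiking_net_spec(N_E = 40, N_I = 10, p_conn = 0, ext_rate_E = 400 * 2,
                     ext_rate_I = 100 * 2, duration = 8, seed = 3), 0)
  half <- estimate_stationary_rate(
    spiking_net_spec(N_E = 40, N_I = 10, p_conn = 0, ext_rate_E = 400 * 2,
                     ext_rate_I = 100 * 2, duration = 8, seed = 3), 4)
  expect_lt(abs(long$rate_E - half$rate_E), long$se_E + half$se_E)
})

test_that("spike trains round-trip through the two-column text format", {
  spec <- spiking_net_spec(N_E = 10, N_I = 3, ext_rate_E = 1500,
                           duration = 0.5, seed = 7)
  rec <- simulate_spiking(spec)
  path <- tempfile(fileext = ".tsv")
  write_spikes(rec, path)
  back <- read.delim(path)
  expect_equal(back$neuron, rec$spikes$neuron)
  expect_equal(back$time, rec$spikes$time, tolerance = 1e-12)
})
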