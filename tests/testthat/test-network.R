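two_region_conn <- function(w = 2, len = 3) {
  labels <- c("A_L", "B_L", "A_R", "B_R")
  W <- matrix(0, 4, 4)
  W[2, 1] <- w; W[4, 3] <- w  # A -> B only
  L <- matrix(0, 4, 4); L[W > 0] <- len
  connectome(W, L, labels)
}

test_that("coupling input applies weights, delays and the routing ratio", {
  conn <- two_region_conn(w = 2, len = 3)
  delays <- compute_delays(conn, v_ax = 3)  # 1 ms
  cfg <- sim_config(R = 1.4, coupling_scale = 0.5)
  times <- seq(0, 5, by = 0.5)
  hist <- matrix(0, 4, length(times))
  hist[1, times == 2] <- 10  # impulse in A_L at t = 2 ms
  for (t in c(2, 2.5, 3, 3.5)) {
    ext <- coupling_input(conn, delays, hist, times, t, cfg)
    if (t == 3) {
      expect_equal(ext$ext_E[2], 0.5 * 2 * 10)        # scale * w * impulse
      expect_equal(ext$ext_I[2], 1.4 * 0.5 * 2 * 10)  # routed to I with R
    } else {
      expect_equal(ext$ext_E[2], 0)
    }
    expect_equal(ext$ext_E[1], 0)  # no afferents into A
  }
  # W = 0 network: only the noise term remains
  conn0 <- connectome(matrix(0, 2, 2), matrix(0, 2, 2), c("A_L", "A_R"))
  ext0 <- coupling_input(conn0, matrix(0, 2, 2), matrix(5, 2, 10),
                         1:10, 8, cfg, noise = 0.7)
  expect_equal(ext0$ext_E, c(0.7, 0.7) * 0.5 * 0 + 0.7)
  expect_error(coupling_input(conn, delays, hist[, 1:5, drop = FALSE],
                              times[1:5], 0.2, cfg),
               "insufficient history")
})

test_that("the integrator delivers a single-edge impulse after exactly L/v_ax", {
  conn <- two_region_conn(w = 2, len = 3)
  tfs <- sig_tfs()
  cfg <- quiet_cfg(duration = 0.05, record_dt = 0.1, drive_E = 0,
                   coupling_scale = 0.5)
  net <- mf_network(conn, tf = tfs, cfg = cfg)
  # pulse into A starting at t = 10 ms; B's drift must change exactly
  # 1 ms after A's rate first moves
  prot <- stim_protocol("A", amplitude = 5, width = 0.02, period = 0.03,
                        onset = 0.01, hemisphere = "both")
  sim <- simulate(net, seed = 1, protocol = prot)
  # the paired no-stimulus run is identical until the response arrives,
  # so the difference isolates the stimulus-locked perturbation exactly
  rest <- simulate(net, seed = 1)
  tA <- sim$time[min(which(abs(sim$rE[1, ] - rest$rE[1, ]) > 0))]
  tB <- sim$time[min(which(abs(sim$rI[2, ] - rest$rI[2, ]) > 0))]
  expect_equal(tB - tA, 0.001, tolerance = 1e-9)
})

test_that("a zero-amplitude protocol is indistinguishable from rest", {
  conn <- synthetic_connectome()
  net <- mf_network(conn, tf = sig_tfs(), cfg = sim_config(duration = 3, transient = 0))
  prot <- stim_protocol("insula", amplitude = 0)
  a <- simulate(net, seed = 5, protocol = prot)
  b <- simulate(net, seed = 5)
  expect_identical(a$rE, b$rE)
  expect_identical(a$rI, b$rI)
})

test_that("a disconnected region settles on the mean-field fixed point", {
  conn0 <- connectome(matrix(0, 2, 2), matrix(0, 2, 2), c("A_L", "A_R"))
  tfs <- fitted_tfs()
  cfg <- quiet_cfg(duration = 3, drive_E = 0.8, R = 1.4)
  net <- mf_network(conn0, tf = tfs, cfg = cfg)
  sim <- simulate(net, seed = 1)
  st <- stationary_state(tfs$E, tfs$I, ext_E = 0.8, ext_I = 1.4 * 0.8,
                         tol = 1e-10)
  expect_equal(unname(sim$rE[1, ncol(sim$rE)]), st$r_E, tolerance = 1e-4)
  expect_equal(unname(sim$rI[1, ncol(sim$rI)]), st$r_I, tolerance = 1e-4)
})

test_that("protocol bookkeeping counts complete epochs", {
  prot <- stim_protocol("insula", onset = 5, period = 2)
  expect_identical(n_complete_epochs(prot, 150), 72L)
  expect_identical(n_complete_epochs(prot, 35), 15L)
  expect_identical(n_complete_epochs(prot, 5.5), 0L)
  lim <- stim_protocol("insula", onset = 5, period = 2, n_pulses = 10)
  expect_identical(n_complete_epochs(lim, 150), 10L)
})

test_that("region relabelling commutes with deterministic simulation", {
  conn <- synthetic_connectome()
  tfs <- sig_tfs()
  cfg <- quiet_cfg(duration = 1)
  sim <- simulate(mf_network(conn, tf = tfs, cfg = cfg), seed = 1)
  perm <- c(13:24, 1:12)  # swap hemisphere blocks
  connp <- connectome(conn$W[perm, perm], conn$L[perm, perm],
                      conn$labels[perm], conn$hemisphere[perm], conn$groups)
  simp <- simulate(mf_network(connp, tf = tfs, cfg = cfg), seed = 1)
  expect_equal(simp$rE[match(conn$labels, connp$labels), ], sim$rE,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("mirrored noise and stimulation preserve hemispheric symmetry", {
  conn <- synthetic_connectome()
  net <- mf_network(conn, tf = fitted_tfs(),
                    cfg = sim_config(duration = 6, mirror_noise = TRUE))
  prot <- stim_protocol("insula", hemisphere = "both")
  sim <- simulate(net, seed = 3, protocol = prot)
  p <- homotopic_partners(conn)
  expect_lt(max(abs(sim$rE - sim$rE[p, ])), 1e-10)
  expect_lt(max(abs(sim$rI - sim$rI[p, ])), 1e-10)
})

test_that("identical seeds give bit-identical simulations", {
  conn <- synthetic_connectome()
  net <- mf_network(conn, tf = fitted_tfs(), cfg = sim_config(duration = 2, transient = 0))
  prot <- stim_protocol("insula")
  a <- simulate(net, seed = 11, protocol = prot)
  b <- simulate(net, seed = 11, protocol = prot)
  expect_identical(a$rE, b$rE)
  expect_identical(a$w, b$w)
  expect_false(identical(a$rE, simulate(net, seed = 12, protocol = prot)$rE))
})

test_that("downsampling block-averages and preserves the mean", {
  sur <- generate_surrogate_evoked(n_regions = 3, duration = 15, fs = 1000,
                                   effects = 0, noise_sd = 1, seed = 2)
  ds <- downsample_sim(sur, 10)
  expect_identical(ncol(ds$rE) * 100L, ncol(sur$rE))
  expect_equal(mean(ds$rE), mean(sur$rE), tolerance = 1e-12)
  # a constant series stays constant
  cst <- sur
  cst$rE[] <- 4
  expect_true(all(downsample_sim(cst, 10)$rE == 4))
  expect_error(downsample_sim(sur, 2000), "exceeds")
})

test_that("rates stay non-negative and finite under strong inhibition", {
  conn <- synthetic_connectome()
  net <- mf_network(conn, tf = fitted_tfs(),
                    cfg = sim_config(duration = 2, transient = 0, noise_amp = 0.5))
  net <- apply_ei_perturbation(net, "dmn", qi = 8)
  sim <- simulate(net, seed = 4)
  expect_true(all(is.finite(sim$rE)) && all(sim$rE >= 0))
  expect_true(all(is.finite(sim$rI)) && all(sim$rI >= 0))
})

test_that("simulations export to readable text tables", {
  sur <- generate_surrogate_evoked(n_regions = 2, duration = 9, fs = 20,
                                   effects = 0, seed = 1)
  dir <- tempfile()
  paths <- write_sim_tables(sur, dir)
  expect_true(all(file.exists(paths)))
  re <- read.delim(paths["rates_E"], header = FALSE, row.names = 1)
  expect_equal(unname(as.matrix(re)), unname(sur$rE), tolerance = 1e-10)
})
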