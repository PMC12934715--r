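#' Network simulation settings
#'
#' @param dt Integration step, ms.
#' @param duration Simulated time, s.
#' @param transient Initial span excluded from spontaneous-activity
#'   analyses (functional connectivity), s.
#' @param R Inter-regional E-to-I vs E-to-E routing ratio: long-range
#'   excitatory projections reach destination E populations with weight
#'   `R_E = 1` and destination I populations with weight `R_I = R`.
#' @param v_ax Axonal propagation speed for delays, m/s.
#' @param drive_E Constant background external excitatory rate, Hz, common
#'   to all regions (sets the spontaneous operating point).
#' @param noise_amp Stationary standard deviation of the
#'   Ornstein-Uhlenbeck noise added to the afferent drive, Hz.
#' @param noise_tau Noise correlation time, ms.
#' @param coupling_scale Global rescaling of the weight matrix. The
#'   default (0.5) puts the afferent drives of the synthetic brain in
#'   the sensitive range of the fitted transfer functions;
#'   [coupling_scale()] implements the alternative normalisation rule
#'   (divide by the maximum in-strength), selected by passing its value
#'   here.
#' @param record_dt Sampling interval of the stored trajectories, ms.
#' @param method Integration scheme, `"heun"` (stochastic Heun) or
#'   `"euler"`.
#' @param stim_to_I Deliver the stimulus to the I population as well as
#'   the E population of target regions (scaled by `R` like any
#'   afferent). The default drives the E population only, so that
#'   stimulation excites its target as in optogenetic excitation; with
#'   `TRUE` and `R > 1` the local inhibitory response dominates and the
#'   stimulated region is itself suppressed.
#' @param mirror_noise Share the noise realization and initial state
#'   across homotopic region pairs (used by the hemispheric symmetry
#'   checks).
#' @param init_jitter Draw per-seed initial rates by jittering the
#'   uncoupled operating point (uniform 0.5-1.5 factor); `FALSE` starts
#'   every realization exactly at the operating point.
#' @param rate_floor Lower clamp on rates after each step, Hz.
#' @param T_ms Mean-field relaxation time, ms.
#' @param seed Default RNG seed used when [simulate.mf_network()] is
#'   called without one.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(dt = 0.1, duration = 150, transient = 5, R = 1.4,
                       v_ax = 3, drive_E = 0.6, noise_amp = 0.1,
                       noise_tau = 5, coupling_scale = 0.5, record_dt = 1,
                       method = c("heun", "euler"), stim_to_I = FALSE,
                       mirror_noise = FALSE, init_jitter = TRUE,
                       rate_floor = 0, T_ms = 5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(dt > 0, duration > transient, transient >= 0, R >= 0, v_ax > 0,
            record_dt >= dt, noise_amp >= 0, noise_tau > 0, T_ms > 0)
  structure(list(dt = dt, duration = duration, transient = transient, R = R,
                 v_ax = v_ax, drive_E = drive_E, noise_amp = noise_amp,
                 noise_tau = noise_tau, coupling_scale = coupling_scale,
                 record_dt = record_dt, method = method,
                 stim_to_I = stim_to_I, mirror_noise = mirror_noise,
                 init_jitter = init_jitter, rate_floor = rate_floor,
                 T_ms = T_ms, seed = as.integer(seed)),
            class = "sim_config")
}

#' Square-wave stimulation protocol
#'
#' The optogenetic-style drive used throughout: square pulses of firing
#' rate added to the afferent input of the target regions. Defaults are
#' 0.1 Hz amplitude, 0.5 s pulses every 2 s after a 5 s onset.
#'
#' @param targets Character vector of region labels, base labels or group
#'   names (multi-subdivision targets are stimulated simultaneously at
#'   equal amplitude).
#' @param amplitude Pulse amplitude, Hz.
#' @param width Pulse duration, s (0 < width < period).
#' @param period Pulse period, s.
#' @param onset Time of the first pulse, s.
#' @param n_pulses Optional pulse-count limit; `NULL` continues to the end
#'   of the simulation.
#' @param hemisphere Which hemisphere's members of `targets` receive the
#'   stimulus (default right, matching unilateral stimulation
#'   experiments).
#' @return An object of class `"stim_protocol"`.
#' @export
stim_protocol <- function(targets, amplitude = 0.1, width = 0.5, period = 2,
                          onset = 5, n_pulses = NULL,
                          hemisphere = c("right", "left", "both")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(amplitude >= 0, width > 0, width < period, onset >= 0)
  structure(list(targets = as.character(targets), amplitude = amplitude,
                 width = width, period = period, onset = onset,
                 n_pulses = if (is.null(n_pulses)) NULL
                            else as.integer(n_pulses),
                 hemisphere = hemisphere),
            class = "stim_protocol")
}

#' Number of complete stimulation epochs in a run
#'
#' An epoch is the full inter-pulse period around one pulse (the 2 s
#' analysis window, 1 s before the pulse to 1 s after, always fits inside
#' it for the default protocol); a pulse counts only when its full period
#' fits before the end of the run: `floor((duration - onset) / period)`.
#'
#' @param protocol A [stim_protocol()].
#' @param duration Run duration, s.
#' @return Integer number of complete epochs.
#' @examples
#' n_complete_epochs(stim_protocol("AI"), duration = 150)  # 72
#' @export
n_complete_epochs <- function(protocol, duration) {
  n <- floor((duration - protocol$onset) / protocol$period + 1e-9)
  n <- max(0L, as.integer(n))
  if (!is.null(protocol$n_pulses)) n <- min(n, protocol$n_pulses)
  n
}

#' Whole-brain mean-field network model
#'
#' Couples one E/I mean-field node per connectome region through the
#' directed weight matrix with tract-length transmission delays. Only
#' excitatory rates propagate between regions; the afferent drive of
#' region i,
#' `a_i(t) = g * sum_j W[i,j] rE_j(t - L[i,j]/v_ax) + drive_E + noise_i(t)`,
#' reaches its E population with weight 1 and its I population with
#' weight `R` (the E-to-I vs E-to-E routing ratio). Synaptic quanta
#' (`qe`, `qi`) and the adaptation increment `b` are per-region vectors,
#' so regional excitation-inhibition perturbations are plain field
#' updates (see [apply_ei_perturbation()]).
#'
#' @param conn A [connectome()].
#' @param tf `list(E = , I = )` of [transfer_function()]s; defaults to the
#'   package's fitted conductance-based pair
#'   ([default_transfer_functions()]).
#' @param cfg A [sim_config()].
#' @param tau_w Adaptation decay time, ms (taken from the E-population
#'   parameters of `tf` when omitted).
#' @return An object of class `"mf_network"` with per-region fields `qe`,
#'   `qi`, `b`.
#' @seealso [simulate.mf_network()], [run_stim_campaign()]
#' @export
mf_network <- function(conn, tf = default_transfer_functions(),
                       cfg = sim_config(), tau_w = NULL) {
  stopifnot(inherits(conn, "connectome"), inherits(cfg, "sim_config"))
  if (!all(c("E", "I") %in% names(tf)))
    stop("'tf' must be a list with elements E and I")
  n <- conn$n_regions
  structure(list(conn = conn, tf = tf, cfg = cfg,
                 qe = rep(tf$E$params$Qe, n), qi = rep(tf$E$params$Qi, n),
                 b = rep(tf$E$params$b, n),
                 tau_w = if (is.null(tau_w)) tf$E$params$tau_w else tau_w),
            class = "mf_network")
}

#' @export
print.mf_network <- function(x, ...) {
  cat(sprintf("mean-field network: %d regions, R = %g, %s transfer functions\n",
              x$conn$n_regions, x$cfg$R, x$tf$E$form))
  pert <- sum(x$qe != x$qe[1]) + sum(x$qi != x$qi[1]) + sum(x$b != x$b[1])
  if (pert > 0) cat("  (regionally perturbed parameters present)\n")
  invisible(x)
}

#' @export
summary.mf_network <- function(object, ...) {
  print(object)
  print(object$conn)
  cat(sprintf("  qe %g-%g nS, qi %g-%g nS, b %g-%g; drive %g Hz, noise sd %g Hz\n",
              min(object$qe), max(object$qe), min(object$qi), max(object$qi),
              min(object$b), max(object$b), object$cfg$drive_E,
              object$cfg$noise_amp))
  invisible(object)
}

#' Simulate a mean-field network
#'
#' Integrates the delay-coupled rate equations with the stochastic Heun
#' scheme (or Euler). Each seed draws its own initial conditions (rates
#' jittered around the uncoupled stationary state) and noise realization;
#' identical seeds give bit-identical results.
#'
#' @param object An [mf_network()].
#' @param nsim Number of independent realizations.
#' @param seed Integer seed (realization k uses `seed + k - 1`); defaults
#'   to `object$cfg$seed`.
#' @param protocol Optional [stim_protocol()].
#' @param duration Override of `cfg$duration`, s.
#' @param ... Unused.
#' @return For `nsim = 1` an object of class `"mf_sim"`: list with `time`
#'   (s), `rE`, `rI` (region x sample matrices, Hz), `w` (pA), `labels`,
#'   `config`, `protocol`, `seed`. For `nsim > 1`, a list of those.
#' @examples
#' conn <- synthetic_connectome()
#' net <- mf_network(conn, tf = list(E = sigmoid_transfer("E"),
#'                                   I = sigmoid_transfer("I")),
#'                   cfg = sim_config(duration = 2, transient = 0))
#' sim <- simulate(net, seed = 1)
#' sim
#' @export
simulate.mf_network <- function(object, nsim = 1, seed = NULL,
                                protocol = NULL, duration = NULL, ...) {
  net <- object
  cfg <- net$cfg
  if (is.null(seed)) seed <- cfg$seed
  if (!is.null(duration)) cfg$duration <- duration
  if (nsim > 1) {
    out <- lapply(seq_len(nsim), function(k)
      simulate.mf_network(object, nsim = 1, seed = seed + k - 1,
                          protocol = protocol, duration = cfg$duration))
    return(out)
  }
  conn <- net$conn
  n <- conn$n_regions
  dt <- cfg$dt
  n_steps <- as.integer(round(cfg$duration * 1000 / dt))
  record_every <- max(1L, as.integer(round(cfg$record_dt / dt)))
  delays <- compute_delays(conn, cfg$v_ax)
  dsteps <- matrix(as.integer(round(delays / dt)), n, n)
  gscale <- if (is.null(cfg$coupling_scale)) coupling_scale(conn)
            else cfg$coupling_scale
  partner <- if (cfg$mirror_noise) homotopic_partners(conn) - 1L
             else rep(-1L, n)

  if (is.null(protocol)) {
    stim_idx <- integer(0)
    samp <- 0; sons <- 0; swid <- 1; sper <- 2; snp <- 0L; stoI <- TRUE
  } else {
    stim_idx <- resolve_regions(conn, protocol$targets,
                                hemisphere = protocol$hemisphere) - 1L
    if (length(stim_idx) == 0)
      stop("stimulation protocol resolves to no regions")
    samp <- protocol$amplitude
    sons <- protocol$onset * 1000
    swid <- protocol$width * 1000
    sper <- protocol$period * 1000
    snp <- if (is.null(protocol$n_pulses)) -1L else protocol$n_pulses
    stoI <- cfg$stim_to_I
  }

  set.seed(seed)
  # uncoupled operating point per distinct (qe, qi, b) triple
  key <- paste(net$qe, net$qi, net$b)
  rE0 <- rI0 <- w0 <- numeric(n)
  for (k in unique(key)) {
    i <- which(key == k)[1]
    pE <- net$tf$E$params
    pE$b <- net$b[i]; pE$tau_w <- net$tau_w
    st <- stationary_state(net$tf$E, net$tf$I, ext_E = cfg$drive_E,
                           ext_I = cfg$R * cfg$drive_E, params_E = pE,
                           cfg = mean_field_config(cfg$T_ms, cfg$rate_floor),
                           qe = net$qe[i], qi = net$qi[i])
    sel <- key == k
    rE0[sel] <- st$r_E; rI0[sel] <- st$r_I; w0[sel] <- st$w_E
  }
  jit <- if (isFALSE(cfg$init_jitter)) rep(1, n)
         else stats::runif(n, 0.5, 1.5)
  if (cfg$mirror_noise) {
    p1 <- partner + 1L
    copy <- which(p1 >= 1 & p1 < seq_len(n))
    jit[copy] <- jit[p1[copy]]
  }
  rE0 <- rE0 * jit; rI0 <- rI0 * jit

  raw <- simulate_network_cpp(
    conn$W, dsteps, as_tf_cstruct(net$tf$E), as_tf_cstruct(net$tf$I),
    net$qe, net$qi, net$b, net$tau_w, cfg$T_ms, 1, cfg$R, gscale, dt,
    n_steps, record_every, rE0, rI0, w0, cfg$drive_E, cfg$noise_amp,
    cfg$noise_tau, partner, stim_idx, samp, sons, swid, sper, snp, stoI,
    if (cfg$method == "heun") 1L else 0L, cfg$rate_floor)

  rownames(raw$rE) <- rownames(raw$rI) <- rownames(raw$w) <- conn$labels
  structure(list(time = raw$time, rE = raw$rE, rI = raw$rI, w = raw$w,
                 labels = conn$labels, groups = conn$groups, config = cfg,
                 protocol = protocol, seed = seed),
            class = "mf_sim")
}

#' @export
print.mf_sim <- function(x, ...) {
  cat(sprintf("mean-field simulation: %d regions, %g s at %g ms sampling\n",
              nrow(x$rE), max(x$time), x$config$record_dt))
  if (!is.null(x$protocol))
    cat(sprintf("  stimulation of %s: %g Hz, %g s every %g s from %g s\n",
                paste(x$protocol$targets, collapse = "+"),
                x$protocol$amplitude, x$protocol$width, x$protocol$period,
                x$protocol$onset))
  cat(sprintf("  mean E rate %.3g Hz (range %.3g-%.3g)\n", mean(x$rE),
              min(x$rE), max(x$rE)))
  invisible(x)
}

#' @export
plot.mf_sim <- function(x, regions = NULL, population = c("E", "I"), ...) {
  population <- match.arg(population)
  m <- if (population == "E") x$rE else x$rI
  idx <- if (is.null(regions)) seq_len(min(6, nrow(m)))
         else resolve_regions(list2conn(x), regions)
  graphics::matplot(x$time, t(m[idx, , drop = FALSE]), type = "l", lty = 1,
                    xlab = "time (s)", ylab = sprintf("r_%s (Hz)", population),
                    ...)
  graphics::legend("topright", legend = x$labels[idx], lty = 1,
                   col = seq_along(idx), cex = 0.7, bty = "n")
  invisible(x)
}

# minimal connectome view of a simulation for label resolution
list2conn <- function(sim) {
  n <- length(sim$labels)
  structure(list(n_regions = n, labels = sim$labels,
                 hemisphere = ifelse(grepl("_L$", sim$labels), "left",
                                     "right"),
                 groups = if (is.null(sim$groups)) list() else sim$groups),
            class = "connectome")
}

#' Region-by-population-by-time rate array of a simulation
#'
#' @param sim An `"mf_sim"`.
#' @return Array with dim `(region, population, time)`, dimnames
#'   `labels x c("E","I") x NULL`.
#' @export
as_rates_array <- function(sim) {
  stopifnot(inherits(sim, "mf_sim"))
  a <- array(0, c(nrow(sim$rE), 2, ncol(sim$rE)),
             dimnames = list(sim$labels, c("E", "I"), NULL))
  a[, 1, ] <- sim$rE
  a[, 2, ] <- sim$rI
  a
}

#' Inter-regional coupling input at one time point
#'
#' Reference implementation of the delayed coupling term:
#' `ext_mu_i = R_mu * (g * sum_{j != i} W[i,j] rE_j(t - delay[i,j]) + noise_i)`
#' evaluated from an explicit history of past excitatory rates. The
#' compiled integrator applies the same rule internally; this function
#' exposes it for inspection and testing.
#'
#' @param conn A [connectome()].
#' @param delays Delay matrix (ms) from [compute_delays()].
#' @param history Region x time matrix of past E rates, Hz.
#' @param times Time stamps (ms) of the history columns (uniform grid).
#' @param t Evaluation time, ms.
#' @param cfg A [sim_config()] (supplies `R` and the coupling scale).
#' @param noise Optional per-region noise rate added to the afferent
#'   drive, Hz.
#' @return `list(ext_E, ext_I)` of per-region drives, Hz.
#' @export
coupling_input <- function(conn, delays, history, times, t, cfg = sim_config(),
                           noise = 0) {
  n <- conn$n_regions
  stopifnot(nrow(history) == n, ncol(history) == length(times))
  need <- t - max(delays)
  if (need < min(times) - 1e-9)
    stop("insufficient history: need rates back to t - max(delay)")
  step <- if (length(times) > 1) times[2] - times[1] else 1
  aff <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || conn$W[i, j] == 0) next
      k <- round((t - delays[i, j] - times[1]) / step) + 1
      if (k < 1 || k > length(times))
        stop("insufficient history: need rates back to t - max(delay)")
      aff[i] <- aff[i] + conn$W[i, j] * history[j, k]
    }
  }
  gscale <- if (is.null(cfg$coupling_scale)) coupling_scale(conn)
            else cfg$coupling_scale
  aff <- gscale * aff + rep_len(noise, n)
  list(ext_E = pmax(aff, 0), ext_I = cfg$R * pmax(aff, 0))
}

#' Export a simulation as delimited text tables
#'
#' Writes `time.tsv` (seconds), `rates_E.tsv`, `rates_I.tsv` (region x
#' sample, Hz), `adaptation.tsv` (pA) and a `config.json` echo of the
#' simulation settings and protocol.
#'
#' @param sim An `"mf_sim"` (consider [downsample_sim()] first; full-rate
#'   tables are large).
#' @param dir Output directory, created if needed.
#' @return Named vector of written paths, invisibly.
#' @export
write_sim_tables <- function(sim, dir) {
  stopifnot(inherits(sim, "mf_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(time = file.path(dir, "time.tsv"),
             rates_E = file.path(dir, "rates_E.tsv"),
             rates_I = file.path(dir, "rates_I.tsv"),
             adaptation = file.path(dir, "adaptation.tsv"),
             config = file.path(dir, "config.json"))
  utils::write.table(data.frame(time = sim$time), paths["time"],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  wm <- function(m, p) utils::write.table(
    data.frame(region = rownames(m), m, check.names = FALSE), p,
    sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  wm(sim$rE, paths["rates_E"])
  wm(sim$rI, paths["rates_I"])
  wm(sim$w, paths["adaptation"])
  jsonlite::write_json(list(config = unclass(sim$config),
                            protocol = if (!is.null(sim$protocol))
                              unclass(sim$protocol),
                            seed = sim$seed),
                       paths["config"], auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(paths)
}

#' Downsample a simulation by block averaging
#'
#' Consecutive samples are averaged in non-overlapping blocks whose size
#' is the nearest integer ratio of the native and target rates (an
#' incomplete trailing block is dropped). Block means preserve the series
#' mean over the retained span.
#'
#' @param sim An `"mf_sim"`.
#' @param target_rate Target sampling rate, Hz (at most the native rate).
#' @return A new `"mf_sim"` on the coarser grid.
#' @export
downsample_sim <- function(sim, target_rate) {
  stopifnot(inherits(sim, "mf_sim"), target_rate > 0)
  native <- 1000 / sim$config$record_dt
  if (target_rate > native + 1e-9)
    stop("target rate exceeds the native sampling rate")
  k <- max(1L, as.integer(round(native / target_rate)))
  nt <- ncol(sim$rE)
  nb <- nt %/% k
  if (nb < 1) stop("series too short to downsample")
  blk <- function(m) {
    m <- m[, seq_len(nb * k), drop = FALSE]
    dim(m) <- c(nrow(m), k, nb)
    r <- apply(m, c(1, 3), mean)
    rownames(r) <- sim$labels
    r
  }
  tnew <- colMeans(matrix(sim$time[seq_len(nb * k)], k, nb))
  out <- sim
  out$time <- tnew
  out$rE <- blk(sim$rE); out$rI <- blk(sim$rI); out$w <- blk(sim$w)
  out$config$record_dt <- sim$config$record_dt * k
  out
}
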