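#' Specification of a small AdEx spiking network
#'
#' Describes the spiking-network oracle used to fit and validate the mean
#' field: `N_E` excitatory and `N_I` inhibitory AdEx neurons, random
#' directed connectivity with probability `p_conn` per ordered pair, and
#' independent external Poisson drive. Defaults give the desk-scale
#' 80E/20I network at 5\% connectivity.
#'
#' `ext_rate_E` and `ext_rate_I` are the *total* Poisson event rates (Hz)
#' of E-type and I-type external input delivered to every neuron; to
#' emulate a per-synapse presynaptic rate `nu` over `K` synapses pass
#' `K * nu` (as [measure_transfer_grid()] does).
#'
#' With `w_fixed = TRUE` the adaptation current is clamped at `w0` for the
#' whole run (no decay, no spike increments); this is how the transfer
#' function is measured at a prescribed adaptation level.
#'
#' @param N_E,N_I Neuron counts per population.
#' @param p_conn Connection probability per ordered pair.
#' @param params_E,params_I [population_params()] of the two cell types.
#' @param ext_rate_E,ext_rate_I Total external Poisson drive rates, Hz.
#' @param I_ext Constant injected current, pA.
#' @param duration Simulated time, s.
#' @param dt Integration step, ms.
#' @param seed Integer RNG seed (connectivity, noise, Poisson drive).
#' @param w_fixed Clamp the adaptation current (see Details).
#' @param w0 Initial / clamped adaptation current, pA.
#' @param vcut_mult Spike-detection cutoff in units of Delta above
#'   threshold: `V_cut = Vthr + vcut_mult * Delta` (reset to `EL`, no
#'   refractory period).
#' @param record_neuron Optional 1-based neuron index whose state
#'   trajectory (V, G_E, G_I, w) is recorded every step.
#' @return An object of class `"spiking_net_spec"`.
#' @export
spiking_net_spec <- function(N_E = 80, N_I = 20, p_conn = 0.05,
                             params_E = population_params("E"),
                             params_I = population_params("I"),
                             ext_rate_E = 0, ext_rate_I = 0, I_ext = 0,
                             duration = 10, dt = 0.1, seed = 1L,
                             w_fixed = FALSE, w0 = 0, vcut_mult = 5,
                             record_neuron = NA_integer_) {
  stopifnot(N_E >= 1, N_I >= 1, p_conn >= 0, p_conn <= 1, dt > 0,
            duration > 0, ext_rate_E >= 0, ext_rate_I >= 0)
  structure(list(N_E = as.integer(N_E), N_I = as.integer(N_I),
                 p_conn = p_conn, params_E = params_E, params_I = params_I,
                 ext_rate_E = ext_rate_E, ext_rate_I = ext_rate_I,
                 I_ext = I_ext, duration = duration, dt = dt,
                 seed = as.integer(seed), w_fixed = w_fixed, w0 = w0,
                 vcut_mult = vcut_mult,
                 record_neuron = as.integer(record_neuron)),
            class = "spiking_net_spec")
}

par_vec <- function(p) c(p$Cm, p$gL, p$EL, p$Delta, p$Vthr, p$sigma, p$b,
                         p$tau_w)

#' Simulate an AdEx spiking network
#'
#' Euler-Maruyama integration of the AdEx membrane, conductance and
#' adaptation equations for every neuron of a [spiking_net_spec()].
#' Identical seeds give bit-identical spike trains.
#'
#' @param spec A [spiking_net_spec()].
#' @return An object of class `"spike_record"`: list with `spikes`
#'   (data.frame `neuron`, `time` in s; neurons `1..N_E` are excitatory),
#'   `rates` (population mean rates over the full duration, Hz), `spec`,
#'   and optionally `trace` (matrix V/G_E/G_I/w per step for
#'   `record_neuron`).
#' @examples
#' spec <- spiking_net_spec(N_E = 10, N_I = 3, duration = 0.5,
#'                          ext_rate_E = 2000)
#' rec <- simulate_spiking(spec)
#' rec$rates
#' @export
simulate_spiking <- function(spec) {
  stopifnot(inherits(spec, "spiking_net_spec"))
  set.seed(spec$seed)
  N <- spec$N_E + spec$N_I
  if (spec$p_conn > 0 && N > 1) {
    m <- matrix(stats::runif(N * N) < spec$p_conn, N, N)
    diag(m) <- FALSE
    idx <- which(m, arr.ind = TRUE)  # row = pre, col = post
    pre <- idx[, 1] - 1L
    post <- idx[, 2] - 1L
  } else {
    pre <- post <- integer(0)
  }
  pe <- spec$params_E
  out <- simulate_spiking_cpp(spec$N_E, spec$N_I, pre, post,
                              par_vec(pe), par_vec(spec$params_I),
                              pe$Qe, pe$Qi, pe$E_rev_e, pe$E_rev_i,
                              pe$tau_syn, spec$ext_rate_E, spec$ext_rate_I,
                              spec$I_ext, spec$duration, spec$dt,
                              spec$vcut_mult, spec$w_fixed, spec$w0,
                              if (is.na(spec$record_neuron)) -1L
                              else spec$record_neuron - 1L)
  spikes <- data.frame(neuron = out$neuron, time = out$time)
  rates <- c(E = sum(spikes$neuron <= spec$N_E) / (spec$N_E * spec$duration),
             I = sum(spikes$neuron > spec$N_E) / (spec$N_I * spec$duration))
  rec <- list(spikes = spikes, rates = rates, spec = spec)
  if (!is.null(out$trace)) {
    colnames(out$trace) <- c("V", "G_E", "G_I", "w")
    rec$trace <- out$trace
  }
  structure(rec, class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("AdEx spike record: %d E + %d I neurons, %g s\n",
              x$spec$N_E, x$spec$N_I, x$spec$duration))
  cat(sprintf("  %d spikes; mean rates E %.3g Hz, I %.3g Hz\n",
              nrow(x$spikes), x$rates["E"], x$rates["I"]))
  invisible(x)
}

#' Stationary population rates from a spike record
#'
#' Mean population rates over `[discard, duration]`, with a standard error
#' estimated from the across-neuron spread of single-neuron rates.
#'
#' @param rec A `"spike_record"` (or a [spiking_net_spec()], which is
#'   simulated first).
#' @param discard Initial transient to drop, s.
#' @return `list(rate_E, rate_I, se_E, se_I, window)`; rates in Hz.
#' @export
estimate_stationary_rate <- function(rec, discard = 1) {
  if (inherits(rec, "spiking_net_spec")) rec <- simulate_spiking(rec)
  stopifnot(inherits(rec, "spike_record"))
  spec <- rec$spec
  win <- spec$duration - discard
  if (win <= 0) stop("zero usable window: discard >= duration")
  sp <- rec$spikes[rec$spikes$time >= discard, ]
  per <- tabulate(sp$neuron, nbins = spec$N_E + spec$N_I) / win
  iE <- seq_len(spec$N_E)
  rE <- per[iE]; rI <- per[-iE]
  se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  list(rate_E = mean(rE), rate_I = mean(rI), se_E = se(rE), se_I = se(rI),
       window = c(discard, spec$duration))
}

#' Measure the population transfer function on a drive grid
#'
#' Runs unconnected populations of AdEx neurons (`p_conn = 0`) under
#' independent Poisson drive emulating presynaptic rates `nu_E`, `nu_I`
#' through `K_e`, `K_i` synapses, with the adaptation current clamped at
#' `w`, and records the stationary output rates of both cell types. This
#' is the sampling step behind [fit_transfer()].
#'
#' @param nu_E,nu_I,w Grid axes: per-synapse presynaptic rates (Hz) and
#'   adaptation currents (pA). The full crossing is simulated.
#' @param params_E,params_I [population_params()] (supply `K_e`, `K_i` and
#'   the membrane constants).
#' @param n_per_type Neurons per population; more neurons average out
#'   Poisson sampling noise.
#' @param duration,discard Simulated seconds per grid point and initial
#'   transient dropped when estimating rates.
#' @param dt Integration step, ms.
#' @param seed Base seed; each grid point uses `seed + point index`.
#' @return data.frame with columns `nu_E`, `nu_I`, `w`, `rate_E`, `rate_I`,
#'   `se_E`, `se_I`.
#' @seealso [transfer_samples()] to reshape for [fit_transfer()].
#' @export
measure_transfer_grid <- function(nu_E, nu_I, w = 0,
                                  params_E = population_params("E"),
                                  params_I = population_params("I"),
                                  n_per_type = 50, duration = 5,
                                  discard = 1, dt = 0.1, seed = 1L) {
  grid <- expand.grid(nu_E = nu_E, nu_I = nu_I, w = w,
                      KEEP.OUT.ATTRS = FALSE)
  res <- matrix(NA_real_, nrow(grid), 4)
  for (k in seq_len(nrow(grid))) {
    spec <- spiking_net_spec(
      N_E = n_per_type, N_I = n_per_type, p_conn = 0,
      params_E = params_E, params_I = params_I,
      ext_rate_E = params_E$K_e * grid$nu_E[k],
      ext_rate_I = params_E$K_i * grid$nu_I[k],
      duration = duration, dt = dt, seed = seed + k,
      w_fixed = TRUE, w0 = grid$w[k])
    est <- estimate_stationary_rate(simulate_spiking(spec), discard)
    res[k, ] <- c(est$rate_E, est$rate_I, est$se_E, est$se_I)
  }
  cbind(grid, rate_E = res[, 1], rate_I = res[, 2], se_E = res[, 3],
        se_I = res[, 4])
}

#' Reshape a measured transfer grid for fitting
#'
#' Selects the observed rate column of one cell type and renames it to
#' `rate` as expected by [fit_transfer()]. For the inhibitory population
#' only `w == 0` rows are kept, since the mean field evaluates `F_I` at
#' zero adaptation.
#'
#' @param grid Output of [measure_transfer_grid()].
#' @param cell_type `"E"` or `"I"`.
#' @return data.frame with columns `nu_E`, `nu_I`, `w`, `rate`.
#' @export
transfer_samples <- function(grid, cell_type = c("E", "I")) {
  cell_type <- match.arg(cell_type)
  if (cell_type == "I") grid <- grid[grid$w == 0, ]
  data.frame(nu_E = grid$nu_E, nu_I = grid$nu_I, w = grid$w,
             rate = if (cell_type == "E") grid$rate_E else grid$rate_I)
}

#' Write spike times as two-column delimited text
#'
#' @param rec A `"spike_record"`.
#' @param path Output file (columns `neuron`, `time` in s, tab-separated).
#' @return `path`, invisibly.
#' @export
write_spikes <- function(rec, path) {
  stopifnot(inherits(rec, "spike_record"))
  utils::write.table(rec$spikes, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
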