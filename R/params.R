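#' Biophysical parameters of one neural population
#'
#' Bundles the AdEx single-neuron constants and the synaptic parameters of
#' an excitatory (`"E"`) or inhibitory (`"I"`) population. The defaults are
#' the cortical values used throughout the package: membrane capacitance
#' 200 pF, leak conductance 10 nS, leak reversal -63 mV (E) / -65 mV (I),
#' spike sharpness 2 mV (E) / 0.5 mV (I), threshold -50 mV, membrane noise
#' 0.0315 pA, synaptic quanta Qe = 1.5 nS and Qi = 5 nS with a 5 ms decay,
#' and no spike-frequency adaptation (b = 0).
#'
#' `K_e` and `K_i` are the effective numbers of recurrent excitatory and
#' inhibitory synapses per neuron assumed by the mean field (defaults 400
#' and 100, an 80/20 network of 10^4 neurons at 5\% connectivity).
#'
#' The adaptation increment `b` is applied to the adaptation current w once
#' per spike; w enters the membrane equation as a current, so b is
#' numerically a current increment per spike. `tau_w` is the adaptation
#' decay time in ms (default 500).
#'
#' @param cell_type `"E"` or `"I"`.
#' @param Cm Membrane capacitance, pF.
#' @param gL Leak conductance, nS.
#' @param EL Leak reversal potential, mV (default -63 for E, -65 for I).
#' @param Delta Spike sharpness, mV (default 2 for E, 0.5 for I).
#' @param Vthr Spike threshold, mV.
#' @param sigma Membrane noise amplitude, pA.
#' @param Qe,Qi Excitatory / inhibitory synaptic conductance quanta, nS.
#' @param tau_syn Synaptic decay time constant, ms.
#' @param E_rev_e,E_rev_i Synaptic reversal potentials, mV.
#' @param b Adaptation increment per spike (see Details).
#' @param tau_w Adaptation decay time constant, ms.
#' @param K_e,K_i Effective recurrent synapse numbers assumed by the mean
#'   field.
#' @return An object of class `"population_params"` (a named list).
#' @examples
#' population_params("E")
#' population_params("I", Qi = 4)  # weakened inhibition
#' @export
population_params <- function(cell_type = c("E", "I"), Cm = 200, gL = 10,
                              EL = if (cell_type == "E") -63 else -65,
                              Delta = if (cell_type == "E") 2 else 0.5,
                              Vthr = -50, sigma = 0.0315, Qe = 1.5, Qi = 5,
                              tau_syn = 5, E_rev_e = 0, E_rev_i = -80,
                              b = 0, tau_w = 500, K_e = 400, K_i = 100) {
  cell_type <- match.arg(cell_type)
  p <- list(cell_type = cell_type, Cm = Cm, gL = gL, EL = EL, Delta = Delta,
            Vthr = Vthr, sigma = sigma, Qe = Qe, Qi = Qi, tau_syn = tau_syn,
            E_rev_e = E_rev_e, E_rev_i = E_rev_i, b = b, tau_w = tau_w,
            K_e = K_e, K_i = K_i)
  validate_population_params(p)
  structure(p, class = "population_params")
}

validate_population_params <- function(p) {
  pos <- c("Cm", "gL", "Delta", "tau_syn", "tau_w")
  for (f in pos)
    if (!is.finite(p[[f]]) || p[[f]] <= 0)
      stop(sprintf("'%s' must be positive and finite", f), call. = FALSE)
  nonneg <- c("Qe", "Qi", "b", "sigma", "K_e", "K_i")
  for (f in nonneg)
    if (!is.finite(p[[f]]) || p[[f]] < 0)
      stop(sprintf("'%s' must be non-negative and finite", f), call. = FALSE)
  if (!is.finite(p$EL) || !is.finite(p$Vthr) || p$EL >= p$Vthr)
    stop("'EL' must lie below 'Vthr'", call. = FALSE)
  invisible(p)
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf("AdEx %s-population parameters\n", x$cell_type))
  cat(sprintf("  Cm %g pF, gL %g nS, EL %g mV, Delta %g mV, Vthr %g mV\n",
              x$Cm, x$gL, x$EL, x$Delta, x$Vthr))
  cat(sprintf("  Qe %g nS, Qi %g nS, tau_syn %g ms, E_rev %g / %g mV\n",
              x$Qe, x$Qi, x$tau_syn, x$E_rev_e, x$E_rev_i))
  cat(sprintf("  adaptation: b %g per spike, tau_w %g ms; K_e %g, K_i %g\n",
              x$b, x$tau_w, x$K_e, x$K_i))
  invisible(x)
}

#' Mean-field relaxation settings
#'
#' @param T_ms Relaxation time constant of the rate equations, ms. Sets the
#'   timescale on which population rates approach the transfer-function
#'   value.
#' @param rate_floor Lower clamp applied to rates after every integration
#'   step, Hz.
#' @return An object of class `"mean_field_config"`.
#' @export
mean_field_config <- function(T_ms = 5, rate_floor = 0) {
  if (!is.finite(T_ms) || T_ms <= 0) stop("'T_ms' must be positive")
  if (!is.finite(rate_floor) || rate_floor < 0)
    stop("'rate_floor' must be non-negative")
  structure(list(T_ms = T_ms, rate_floor = rate_floor),
            class = "mean_field_config")
}

#' Population state of one region
#'
#' @param r_E,r_I Excitatory / inhibitory population rates, Hz.
#' @param w_E Mean adaptation current of the E population, pA (the I
#'   population is non-adapting).
#' @return An object of class `"node_state"`.
#' @export
node_state <- function(r_E = 0, r_I = 0, w_E = 0) {
  if (!all(is.finite(c(r_E, r_I, w_E)))) stop("state must be finite")
  if (r_E < 0 || r_I < 0) stop("rates must be non-negative")
  structure(list(r_E = r_E, r_I = r_I, w_E = w_E), class = "node_state")
}
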