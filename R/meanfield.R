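#' Drift of the mean-field rate equations for one region
#'
#' One region holds an excitatory and an inhibitory population. The rates
#' relax towards the transfer-function value with time constant `T_ms`:
#' `T dr_E/dt = F_E(r_E + ext_E, r_I, w) - r_E` and
#' `T dr_I/dt = F_I(r_E + ext_I, r_I, 0) - r_I`, where `ext_E`/`ext_I` are
#' the external excitatory drives routed to the E and I populations
#' (inter-regional input is always carried by excitatory rates). The mean
#' adaptation current of the E population follows
#' `dw/dt = -w/tau_w + b r_E` (the I population is non-adapting).
#'
#' @param state A [node_state()].
#' @param tf_E,tf_I Transfer functions of the two populations.
#' @param ext_E,ext_I External excitatory drive to the E / I population, Hz
#'   (non-negative).
#' @param params_E [population_params()] of the E population (source of
#'   `b` and `tau_w`).
#' @param cfg A [mean_field_config()].
#' @return `list(dr_E, dr_I, dw)`; rates of change in Hz/ms and pA/ms.
#' @export
node_drift <- function(state, tf_E, tf_I, ext_E, ext_I,
                       params_E = population_params("E"),
                       cfg = mean_field_config()) {
  stopifnot(inherits(state, "node_state"))
  if (ext_E < 0 || ext_I < 0) stop("external drives must be non-negative")
  F_E <- eval_transfer(tf_E, state$r_E + ext_E, state$r_I, state$w_E)
  F_I <- eval_transfer(tf_I, state$r_E + ext_I, state$r_I, 0)
  list(dr_E = (F_E - state$r_E) / cfg$T_ms,
       dr_I = (F_I - state$r_I) / cfg$T_ms,
       dw = -state$w_E / params_E$tau_w + params_E$b * state$r_E * 1e-3)
}

#' Stationary state of an isolated region
#'
#' Damped fixed-point iteration on the rate equations:
#' `r <- (1 - damping) r + damping F(r)`, with the adaptation current set
#' to its stationary value `w = b tau_w r_E` at every iterate. Convergence
#' is declared when both rate residuals `|r - F(r)|` fall below `tol`.
#' Non-convergence is reported through the `converged` attribute, not as
#' an error.
#'
#' @inheritParams node_drift
#' @param tol Residual tolerance, Hz.
#' @param max_iter Maximum number of iterations.
#' @param init Initial [node_state()].
#' @param damping Relaxation factor in (0, 1]; smaller is more robust.
#' @param qe,qi Synaptic quanta overriding the reference values of the
#'   transfer functions (regional E/I perturbations).
#' @return A [node_state()] with attributes `converged` (logical),
#'   `residual` (Hz) and `iterations`.
#' @examples
#' tfs <- list(E = sigmoid_transfer("E"), I = sigmoid_transfer("I"))
#' stationary_state(tfs$E, tfs$I, ext_E = 5, ext_I = 5)
#' @export
stationary_state <- function(tf_E, tf_I, ext_E = 0, ext_I = 0,
                             params_E = population_params("E"),
                             cfg = mean_field_config(), tol = 1e-8,
                             max_iter = 5000L, init = node_state(),
                             damping = 0.5, qe = NULL, qi = NULL) {
  stopifnot(tol > 0, damping > 0, damping <= 1)
  r_E <- init$r_E; r_I <- init$r_I
  res <- Inf; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    w <- params_E$b * params_E$tau_w * r_E * 1e-3
    F_E <- eval_transfer(tf_E, r_E + ext_E, r_I, w, qe = qe, qi = qi)
    F_I <- eval_transfer(tf_I, r_E + ext_I, r_I, 0, qe = qe, qi = qi)
    res <- max(abs(F_E - r_E), abs(F_I - r_I))
    if (res < tol) break
    r_E <- max((1 - damping) * r_E + damping * F_E, cfg$rate_floor)
    r_I <- max((1 - damping) * r_I + damping * F_I, cfg$rate_floor)
  }
  out <- node_state(r_E, r_I, params_E$b * params_E$tau_w * r_E * 1e-3)
  attr(out, "converged") <- res < tol
  attr(out, "residual") <- res
  attr(out, "iterations") <- it
  out
}
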