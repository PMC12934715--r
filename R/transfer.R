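#' Population transfer functions
#'
#' A transfer function maps the presynaptic excitatory rate `nu_E`, the
#' inhibitory rate `nu_I` (both Hz, per-synapse rates multiplied internally
#' by the synapse counts `K_e`, `K_i`) and the adaptation current `w` (pA)
#' to the stationary output rate of a population.
#'
#' Two functional forms are available:
#' \describe{
#'   \item{`"threshold_poly"`}{The semi-analytic conductance-based form.
#'     Mean, standard deviation and autocorrelation time of the membrane
#'     potential are computed from the input rates via the synaptic
#'     conductance equations; the effective spike threshold is a
#'     second-order polynomial (10 coefficients) in the normalised
#'     statistics; the rate is
#'     `erfc((Vthr_eff - mu_V)/(sqrt(2) sigma_V)) / (2 tau_V)`. The
#'     coefficients are fitted against the spiking-network oracle with
#'     [fit_transfer()]. Because the synaptic quanta enter the membrane
#'     statistics directly, regional Qe/Qi perturbations do not require
#'     refitting.}
#'   \item{`"sigmoid"`}{A saturating logistic fallback used in fast tests:
#'     `r_max / (1 + exp(-(x - theta)/slope))` with drive
#'     `x = a_E (Qe/Qe0) nu_E - a_I (Qi/Qi0) nu_I - a_w w` and coefficients
#'     `c(r_max, theta, slope, a_E, a_I, a_w)`.}
#' }
#'
#' Inputs outside `domain` are clamped to the domain boundary, so the
#' function saturates rather than extrapolates.
#'
#' @param cell_type `"E"` or `"I"`.
#' @param coefficients Numeric coefficient vector (10 for
#'   `"threshold_poly"`, 6 for `"sigmoid"`).
#' @param form Functional form, see Details.
#' @param params [population_params()] of the population (membrane and
#'   synaptic constants used by the conductance form and as the reference
#'   quanta of the sigmoid form).
#' @param domain Length-6 numeric: valid box
#'   `c(nuE_min, nuE_max, nuI_min, nuI_max, w_min, w_max)`.
#' @return An object of class `"transfer_function"`.
#' @seealso [eval_transfer()], [fit_transfer()],
#'   [default_transfer_functions()]
#' @export
transfer_function <- function(cell_type = c("E", "I"), coefficients,
                              form = c("threshold_poly", "sigmoid"),
                              params = population_params(cell_type),
                              domain = c(0, 30, 0, 30, 0, 1000)) {
  cell_type <- match.arg(cell_type)
  form <- match.arg(form)
  n_coef <- if (form == "threshold_poly") 10L else 6L
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != n_coef)
    stop(sprintf("form '%s' needs %d coefficients", form, n_coef))
  if (!all(is.finite(coefficients)))
    stop("invalid model: non-finite transfer-function coefficients")
  if (length(domain) != 6 || any(domain[c(2, 4, 6)] < domain[c(1, 3, 5)]))
    stop("'domain' must be c(nuE_min, nuE_max, nuI_min, nuI_max, w_min, w_max)")
  structure(list(cell_type = cell_type, form = form,
                 form_id = paste0(form, "_v1"),
                 coefficients = coefficients, params = params,
                 domain = as.numeric(domain)),
            class = "transfer_function")
}

# internal: representation consumed by the C++ kernels
as_tf_cstruct <- function(tf) {
  p <- tf$params
  list(form_code = if (tf$form == "threshold_poly") 0L else 1L,
       coefficients = tf$coefficients,
       membrane = list(Cm = p$Cm, gL = p$gL, EL = p$EL, E_rev_e = p$E_rev_e,
                       E_rev_i = p$E_rev_i, tau_syn = p$tau_syn, K_e = p$K_e,
                       K_i = p$K_i, Qe = p$Qe, Qi = p$Qi),
       domain = tf$domain,
       norm = tf_norm_constants(p))
}

# normalisation constants of the polynomial basis: centre/scale for mu_V
# (mV), sigma_V (mV), and the membrane time at rest (s) for tau_V
tf_norm_constants <- function(params) {
  c(-60, 10, 4, 6, params$Cm / params$gL * 1e-3)
}

#' Evaluate a transfer function
#'
#' @param tf A [transfer_function()].
#' @param nu_E,nu_I Presynaptic excitatory / inhibitory rates, Hz
#'   (vectorised, recycled to a common length).
#' @param w Adaptation current, pA.
#' @param qe,qi Synaptic quanta in effect, nS; default to the reference
#'   quanta stored in `tf$params`. Regional E/I perturbations pass modified
#'   values here.
#' @return Numeric vector of output rates, Hz (finite, non-negative).
#' @examples
#' tf <- sigmoid_transfer("E")
#' eval_transfer(tf, nu_E = c(0, 5, 10), nu_I = 2)
#' @export
eval_transfer <- function(tf, nu_E, nu_I, w = 0, qe = NULL, qi = NULL) {
  stopifnot(inherits(tf, "transfer_function"))
  if (!all(is.finite(tf$coefficients)))
    stop("invalid model: non-finite transfer-function coefficients")
  n <- max(length(nu_E), length(nu_I), length(w))
  nu_E <- rep_len(as.numeric(nu_E), n)
  nu_I <- rep_len(as.numeric(nu_I), n)
  w <- rep_len(as.numeric(w), n)
  if (any(!is.finite(nu_E)) || any(!is.finite(nu_I)) || any(!is.finite(w)))
    stop("inputs must be finite")
  qe <- if (is.null(qe)) tf$params$Qe else qe
  qi <- if (is.null(qi)) tf$params$Qi else qi
  tf_eval_cpp(as_tf_cstruct(tf), nu_E, nu_I, w, qe, qi)
}

#' Saturating-sigmoid transfer function with package default coefficients
#'
#' Fast fallback form for tests and examples; not fitted to spiking data.
#' The inhibitory population is given a steeper gain than the excitatory
#' one, as in conductance-based cortical models.
#'
#' @inheritParams transfer_function
#' @param ... Passed to [transfer_function()].
#' @return A `"transfer_function"` of form `"sigmoid"`.
#' @export
sigmoid_transfer <- function(cell_type = c("E", "I"), ...) {
  cell_type <- match.arg(cell_type)
  coefficients <- if (cell_type == "E")
    c(r_max = 60, theta = 10, slope = 4, a_E = 2, a_I = 1, a_w = 0.02)
  else
    c(r_max = 120, theta = 8, slope = 3, a_E = 2.5, a_I = 1, a_w = 0.02)
  transfer_function(cell_type, coefficients, form = "sigmoid", ...)
}

#' Fit the conductance-based transfer function to rate samples
#'
#' Fits the 10 effective-threshold polynomial coefficients of the
#' `"threshold_poly"` form by linear least squares. For every sample with a
#' positive observed rate the effective threshold is recovered by inverting
#' the erfc rate equation at the membrane statistics implied by the inputs,
#' and the polynomial basis is regressed on those thresholds. Samples with
#' zero observed rate carry no threshold information and are excluded from
#' the regression (they still enter the reported in-sample RMSE).
#'
#' @param samples `data.frame` with columns `nu_E`, `nu_I`, `w`,
#'   `rate` (observed stationary output rate, Hz), e.g. produced by
#'   [measure_transfer_grid()].
#' @param cell_type `"E"` or `"I"`.
#' @param params [population_params()] describing the neurons the samples
#'   came from (including `K_e`, `K_i` of the drive).
#' @param domain Domain box of the returned function; defaults to the
#'   bounding box of the samples.
#' @return A `"transfer_function"` with an additional `fit` element:
#'   `list(rmse, n, n_used)` where `rmse` is the in-sample root mean square
#'   error in Hz.
#' @seealso [measure_transfer_grid()] for generating `samples` from the
#'   spiking oracle.
#' @export
fit_transfer <- function(samples, cell_type = c("E", "I"),
                         params = population_params(cell_type),
                         domain = NULL) {
  cell_type <- match.arg(cell_type)
  need <- c("nu_E", "nu_I", "w", "rate")
  if (!all(need %in% names(samples)))
    stop("'samples' needs columns nu_E, nu_I, w, rate")
  samples <- as.data.frame(samples)[need]
  if (anyNA(samples) || !all(vapply(samples, is.numeric, TRUE)))
    stop("'samples' must be numeric and complete")
  if (is.null(domain))
    domain <- c(0, max(samples$nu_E), 0, max(samples$nu_I),
                0, max(samples$w, 1))
  proto <- transfer_function(cell_type, rep(0, 10), "threshold_poly",
                             params = params, domain = domain)
  st <- tf_stats_cpp(as_tf_cstruct(proto), samples$nu_E, samples$nu_I,
                     samples$w, params$Qe, params$Qi)
  mu_V <- st[, 1]; sig_V <- pmax(st[, 2], 1e-6); tau_V <- st[, 3]
  # invert r = erfc((Veff - muV)/(sqrt(2) sigV)) / (2 tauV) for Veff
  y2 <- 2 * samples$rate * tau_V
  use <- samples$rate > 0 & y2 < 2
  if (sum(use) < 10)
    stop("degenerate fit: fewer than 10 usable (positive-rate) samples")
  erfcinv <- function(y) stats::qnorm(y / 2, lower.tail = FALSE) / sqrt(2)
  v_eff <- mu_V[use] + sqrt(2) * sig_V[use] * erfcinv(y2[use])
  X <- tf_poly_basis(mu_V[use], sig_V[use], tau_V[use],
                     tf_norm_constants(params))
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("degenerate fit: rank-deficient design (add more distinct samples)")
  coefs <- qr.coef(qrX, v_eff)
  tf <- transfer_function(cell_type, coefs, "threshold_poly",
                          params = params, domain = domain)
  pred <- eval_transfer(tf, samples$nu_E, samples$nu_I, samples$w)
  tf$fit <- list(rmse = sqrt(mean((pred - samples$rate)^2)),
                 n = nrow(samples), n_used = sum(use))
  tf
}

tf_poly_basis <- function(mu_V, sig_V, tau_V, norm) {
  xm <- (mu_V - norm[1]) / norm[2]
  xs <- (sig_V - norm[3]) / norm[4]
  xt <- tau_V / norm[5] - 0.5
  cbind(1, xm, xs, xt, xm^2, xs^2, xt^2, xm * xs, xm * xt, xs * xt)
}

#' @export
coef.transfer_function <- function(object, ...) object$coefficients

#' @export
predict.transfer_function <- function(object, newdata, ...) {
  eval_transfer(object, newdata$nu_E, newdata$nu_I,
                if (is.null(newdata$w)) 0 else newdata$w)
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("%s transfer function (%s population)\n", x$form, x$cell_type))
  cat("  coefficients:", paste(signif(x$coefficients, 4), collapse = " "),
      "\n")
  cat(sprintf("  domain: nu_E [%g, %g] Hz, nu_I [%g, %g] Hz, w [%g, %g] pA\n",
              x$domain[1], x$domain[2], x$domain[3], x$domain[4],
              x$domain[5], x$domain[6]))
  if (!is.null(x$fit))
    cat(sprintf("  fitted on %d samples (%d used), in-sample RMSE %.3g Hz\n",
                x$fit$n, x$fit$n_used, x$fit$rmse))
  invisible(x)
}

#' Package default fitted transfer functions
#'
#' Loads the transfer-function coefficients shipped with the package
#' (plain-text table under `extdata/`). They were fitted with
#' [fit_transfer()] against the package's own AdEx spiking oracle
#' ([measure_transfer_grid()]) at the default [population_params()]; the
#' generating script is `tools/fit_default_transfer.R` in the source
#' repository.
#'
#' @param params_E,params_I Population parameters to attach; must match the
#'   constants the coefficients were fitted at for the fit to be
#'   meaningful (the defaults do).
#' @return `list(E = , I = )` of `"transfer_function"` objects.
#' @export
default_transfer_functions <- function(params_E = population_params("E"),
                                       params_I = population_params("I")) {
  path <- system.file("extdata", "transfer_coefficients_default.tsv",
                      package = "mfbrain", mustWork = TRUE)
  read_transfer_table(path, params_E, params_I)
}

#' @rdname write_transfer_table
#' @param params_E,params_I Population parameters attached to the E / I
#'   functions on read.
#' @export
read_transfer_table <- function(path, params_E = population_params("E"),
                                params_I = population_params("I")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  one <- function(ct, params) {
    sub <- tab[tab$cell_type == ct, ]
    if (nrow(sub) == 0) return(NULL)
    coefs <- sub$value[match(paste0("coef_", 1:10), sub$name)]
    dom <- sub$value[match(paste0("dom_", 1:6), sub$name)]
    transfer_function(ct, coefs, "threshold_poly", params = params,
                      domain = dom)
  }
  out <- list(E = one("E", params_E), I = one("I", params_I))
  out[!vapply(out, is.null, TRUE)]
}

#' Write / read transfer-function coefficients as a delimited table
#'
#' @param tfs A named list of `"transfer_function"` objects (names ignored;
#'   cell types are taken from the objects).
#' @param path File path of the tab-separated table with columns
#'   `cell_type`, `name`, `value`.
#' @return `write_transfer_table()` returns `path` invisibly.
#' @export
write_transfer_table <- function(tfs, path) {
  rows <- lapply(tfs, function(tf) {
    data.frame(cell_type = tf$cell_type,
               name = c(paste0("coef_", seq_along(tf$coefficients)),
                        paste0("dom_", 1:6)),
               value = c(tf$coefficients, tf$domain))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
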