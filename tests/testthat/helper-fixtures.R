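# shared fixtures: fast sigmoid transfer functions, the default fitted
# pair (read once from extdata), and a small deterministic config

sig_tfs <- function() list(E = sigmoid_transfer("E"),
                           I = sigmoid_transfer("I"))

fitted_tfs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_transfer_functions()
    cache
  }
})

quiet_cfg <- function(...) sim_config(noise_amp = 0, init_jitter = FALSE,
                                      transient = 0, ...)

# brute-force exact two-tailed signed-rank p by enumerating all 2^n sign
# assignments (midranks for ties, zeros dropped); independent of the
# package's dynamic-programming implementation
enum_signed_rank_p <- function(x) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) return(NA_real_)
  rk <- rank(abs(x))
  W <- sum(rk[x > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  Ws <- apply(signs, 1, function(s) sum(rk[as.logical(s)]))
  p_le <- mean(Ws <= W + 1e-12)
  p_ge <- mean(Ws >= W - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}
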