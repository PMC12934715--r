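#' Synthetic bilateral connectome with a default-mode-like motif
#'
#' Generates a small mirrored two-hemisphere connectome reproducing the
#' structural features the analyses rely on: a default-mode-like core
#' (retrosplenial / cingulate / prelimbic analogues, labels `RSCv`,
#' `Cgv`, `PrL`), a posterior DMN extension (`RSCd`, `PTLp`), an
#' insula-like hub (`AI`) that has *no direct projection* to the DMN core
#' but reaches it through a relay pathway (`AI -> Rel1 -> Rel2 -> core`),
#' a frontal pair (`ORB`, `FRP`) and background regions (`Bg1`, `Bg2`).
#' All edges are bilateral (weights and lengths equalised across
#' hemispheres) and homotopic partners are connected callosally.
#'
#' The relay pathway has odd length by construction: in the
#' inhibition-dominated operating regime of the network model (routing
#' ratio R > 1), each inter-regional hop inverts the sign of a
#' steady-state rate perturbation, so an odd number of hops from the hub
#' delivers net suppression to the core while the hub itself is excited
#' by the stimulus.
#'
#' The default 24-region brain (12 per hemisphere) keeps full experiment
#' pipelines desk-fast while exercising the group bookkeeping of the real
#' atlas: groups `dmn_core`, `dmn`, `insula`, `frontal`, `relay` and
#' `background` are registered on the result.
#'
#' @param seed RNG seed for tract lengths.
#' @param n_per_module Named integer vector of module sizes per
#'   hemisphere; names `dmn_core`, `dmn_post`, `insula`, `frontal`,
#'   `relay`, `background`.
#' @param intra_weight Weight of within-module edges.
#' @param inter_weight Weight of between-module, callosal and
#'   hub-entry (`AI -> Rel1`) edges.
#' @param hub_to_relay_weight Weight of the relay-chain edges
#'   (`Rel1 -> Rel2`, `Rel2 -> core`: the indirect suppression pathway).
#' @param forbid_direct_hub_to_core Keep hub-to-DMN-core entries exactly
#'   zero (the defining structural motif). When `FALSE` a direct edge of
#'   weight `hub_to_relay_weight` is added instead.
#' @param spatial_scale Median tract length, mm (inter-hemispheric tracts
#'   are drawn at twice the scale).
#' @return A [connectome()] with groups registered.
#' @examples
#' conn <- synthetic_connectome()
#' conn
#' max(conn$W[resolve_regions(conn, "dmn_core"),
#'            resolve_regions(conn, "insula")])  # 0: no direct hub->core
#' @export
synthetic_connectome <- function(seed = 1L,
                                 n_per_module = c(dmn_core = 3, dmn_post = 2,
                                                  insula = 1, frontal = 2,
                                                  relay = 2, background = 2),
                                 intra_weight = 1, inter_weight = 0.3,
                                 hub_to_relay_weight = 2,
                                 forbid_direct_hub_to_core = TRUE,
                                 spatial_scale = 3) {
  stopifnot(all(n_per_module >= 1), intra_weight >= 0, inter_weight >= 0,
            hub_to_relay_weight >= 0, spatial_scale > 0)
  base_names <- list(
    dmn_core = c("RSCv", "Cgv", "PrL"), dmn_post = c("RSCd", "PTLp"),
    insula = "AI", frontal = c("ORB", "FRP"), relay = c("Rel1", "Rel2"),
    background = c("Bg1", "Bg2"))
  modules <- lapply(names(n_per_module), function(m) {
    k <- n_per_module[[m]]
    nm <- base_names[[m]]
    if (k <= length(nm)) nm[seq_len(k)]
    else c(nm, paste0(nm[length(nm)], seq_len(k - length(nm)) + 1))
  })
  names(modules) <- names(n_per_module)
  bases <- unlist(modules, use.names = FALSE)
  labels <- c(paste0(bases, "_L"), paste0(bases, "_R"))
  n <- length(labels)
  module_of <- rep(rep(names(modules), lengths(modules)), 2)

  W <- matrix(0, n, n)
  idx <- function(mod, hemi) which(module_of == mod &
                                     grepl(paste0("_", hemi, "$"), labels))
  for (hemi in c("L", "R")) {
    for (m in c("dmn_core", "dmn_post", "frontal", "background")) {
      i <- idx(m, hemi)
      W[i, i] <- intra_weight  # within module, all-to-all
    }
    core <- idx("dmn_core", hemi); post <- idx("dmn_post", hemi)
    hub <- idx("insula", hemi); fr <- idx("frontal", hemi)
    rel <- idx("relay", hemi); bg <- idx("background", hemi)
    # W[target, source]: orientation is source -> target
    W[core, post] <- W[post, core] <- inter_weight
    # indirect hub-to-core pathway: hub -> Rel1 -> ... -> RelK -> core;
    # the hub entry edge carries the within-module weight
    W[rel[1], hub] <- intra_weight
    if (length(rel) > 1)
      for (k in seq_len(length(rel) - 1))
        W[rel[k + 1], rel[k]] <- hub_to_relay_weight
    W[core, rel[length(rel)]] <- hub_to_relay_weight
    W[fr, hub] <- inter_weight               # hub -> frontal
    W[hub, fr] <- inter_weight
    W[hub, core] <- inter_weight             # core -> hub (feedback)
    W[bg, c(post, fr)] <- inter_weight
    W[c(post, fr), bg] <- inter_weight
    if (!forbid_direct_hub_to_core) W[core, hub] <- hub_to_relay_weight
  }
  # callosal homotopic edges
  half <- n / 2
  for (i in seq_len(half)) {
    W[i, i + half] <- W[i + half, i] <- inter_weight
  }
  diag(W) <- 0
  if (forbid_direct_hub_to_core) {
    core_all <- which(module_of == "dmn_core")
    hub_all <- which(module_of == "insula")
    W[core_all, hub_all] <- 0
  }

  set.seed(seed)
  L <- matrix(stats::rlnorm(n * n, meanlog = log(spatial_scale),
                            sdlog = 0.3), n, n)
  inter_h <- outer(grepl("_L$", labels), grepl("_R$", labels), `!=`)
  L[inter_h] <- 2 * L[inter_h]
  L[W == 0] <- 0
  diag(L) <- 0

  groups <- list(
    dmn_core = modules$dmn_core,
    dmn = c(modules$dmn_core, modules$dmn_post),
    insula = modules$insula, frontal = modules$frontal,
    relay = modules$relay, background = modules$background)
  mirror_hemispheres(connectome(W, L, labels,
                                ifelse(grepl("_L$", labels), "left", "right"),
                                groups))
}

#' Surrogate evoked time series with known ground truth
#'
#' Generates stationary block-correlated Gaussian rate series with
#' additive square-wave evoked responses of prescribed per-region effect
#' sizes, shaped like an `"mf_sim"` so the full epoching / delta /
#' testing pipeline runs on data whose true effects are known. The
#' effect is applied for 1 s from each pulse onset (the full
#' post-stimulus analysis window), so the expected pre/post delta of
#' region k equals `effects[k]` exactly.
#'
#' @param n_regions Number of regions.
#' @param duration Series length, s.
#' @param fs Sampling rate, Hz.
#' @param effects Per-region evoked effect sizes, Hz (recycled).
#' @param noise_sd Marginal standard deviation of the noise, Hz.
#' @param blocks Optional list of `list(regions =, rho =)` giving groups
#'   of regions sharing a common correlation `rho` (factor model:
#'   pairwise correlation within the block is `rho`).
#' @param baseline Baseline rate, Hz.
#' @param protocol A [stim_protocol()]; its targets are ignored (effects
#'   are set per region), its timing defines the trial structure.
#' @param seed RNG seed.
#' @return An `"mf_sim"`-shaped object (regions labelled `R1..Rn`).
#' @export
generate_surrogate_evoked <- function(n_regions = 4, duration = 65, fs = 100,
                                      effects = 0, noise_sd = 1,
                                      blocks = NULL, baseline = 5,
                                      protocol = stim_protocol(
                                        "all", hemisphere = "both"),
                                      seed = 1L) {
  stopifnot(fs > 0, duration > 0, noise_sd >= 0)
  set.seed(seed)
  nt <- as.integer(round(duration * fs))
  time <- seq_len(nt) / fs
  effects <- rep_len(effects, n_regions)
  x <- matrix(stats::rnorm(n_regions * nt, sd = noise_sd), n_regions, nt)
  if (!is.null(blocks)) {
    for (b in blocks) {
      rho <- b$rho
      if (abs(rho) > 1) stop("|block correlation| must be <= 1")
      f <- stats::rnorm(nt, sd = noise_sd)
      for (i in b$regions)
        x[i, ] <- sqrt(abs(rho)) * sign(rho) * f +
          sqrt(1 - abs(rho)) * x[i, ]
    }
  }
  x <- x + baseline
  n_tr <- n_complete_epochs(protocol, duration)
  for (k in seq_len(n_tr)) {
    t0 <- protocol$onset + (k - 1) * protocol$period
    on <- time >= t0 & time < t0 + 1
    x[, on] <- x[, on] + effects
  }
  labels <- paste0("R", seq_len(n_regions))
  rownames(x) <- labels
  cfg <- sim_config(dt = 1000 / fs, duration = duration,
                    transient = min(protocol$onset, duration / 2),
                    record_dt = 1000 / fs)
  structure(list(time = time, rE = x,
                 rI = matrix(0, n_regions, nt, dimnames = list(labels, NULL)),
                 w = matrix(0, n_regions, nt, dimnames = list(labels, NULL)),
                 labels = labels, config = cfg, protocol = protocol,
                 seed = seed),
            class = "mf_sim")
}
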