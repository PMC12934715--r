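#' Run a repeated-stimulation campaign
#'
#' Simulates the network once per seed under a square-wave stimulation
#' protocol, epochs each realization and collects the per-seed, per-region
#' pre/post deltas. Paired designs are obtained by running two campaigns
#' with the same `seeds` (identical initial conditions and noise
#' realizations; only the condition of interest differs).
#'
#' @param net An [mf_network()].
#' @param targets Stimulation targets (labels, base labels or group
#'   names); ignored when `protocol` is supplied.
#' @param seeds Integer vector of distinct seeds, one realization each.
#' @param protocol A [stim_protocol()]; defaults to the standard pulse
#'   train on `targets`.
#' @param duration Simulated seconds per realization (default from the
#'   network config).
#' @param keep_fc Also accumulate the across-seed mean functional
#'   connectivity over `fc_regions` from the same simulations.
#' @param fc_regions Regions entering the FC matrix when `keep_fc`.
#' @return An object of class `"stim_campaign"`: list with `deltas`
#'   (seed x region matrix, Hz), `seeds`, `protocol`, and optionally
#'   `fc`.
#' @seealso [campaign_tests()], [parameter_sweep()]
#' @export
run_stim_campaign <- function(net, targets, seeds = 1:20, protocol = NULL,
                              duration = NULL, keep_fc = FALSE,
                              fc_regions = "dmn") {
  stopifnot(inherits(net, "mf_network"), length(seeds) >= 1)
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  if (is.null(protocol)) protocol <- stim_protocol(targets)
  # resolve now so an unknown label fails before any simulation
  resolve_regions(net$conn, protocol$targets,
                  hemisphere = protocol$hemisphere)
  deltas <- matrix(NA_real_, length(seeds), net$conn$n_regions,
                   dimnames = list(seeds, net$conn$labels))
  fc_idx <- if (keep_fc) resolve_regions(net$conn, fc_regions,
                                         hemisphere = "right")
  fc_acc <- NULL
  for (k in seq_along(seeds)) {
    sim <- simulate(net, seed = seeds[k], protocol = protocol,
                    duration = duration)
    deltas[k, ] <- prepost_delta(epoch_and_average(sim, protocol))
    if (keep_fc) {
      fc <- functional_connectivity(sim, regions = net$conn$labels[fc_idx])
      fc_acc <- if (is.null(fc_acc)) fc else fc_acc + fc
    }
  }
  out <- list(deltas = deltas, seeds = seeds, protocol = protocol,
              targets = protocol$targets)
  if (keep_fc) {
    fc <- fc_acc / length(seeds)
    diag(fc) <- 1
    out$fc <- structure(fc, class = c("fc_matrix", "matrix", "array"))
  }
  structure(out, class = "stim_campaign")
}

#' @export
print.stim_campaign <- function(x, ...) {
  cat(sprintf("stimulation campaign: %s, %d seeds\n",
              paste(x$targets, collapse = "+"), length(x$seeds)))
  med <- apply(x$deltas, 2, stats::median)
  top <- order(abs(med), decreasing = TRUE)[seq_len(min(5, length(med)))]
  cat("  largest median deltas (Hz):\n")
  for (i in top) cat(sprintf("    %-8s %+.4g\n", colnames(x$deltas)[i],
                             med[i]))
  invisible(x)
}

#' Per-region significance of campaign deltas
#'
#' One-sample Wilcoxon test of the per-seed deltas against zero for each
#' requested region (subdivisions of a base label are averaged per seed
#' first), with BH-FDR over the region family.
#'
#' @param campaign A `"stim_campaign"` (or for the paired variant, two of
#'   them with identical seeds via `campaign2`).
#' @param net The network the campaign was run on (for label
#'   resolution).
#' @param regions Readout regions: labels, base labels or group names.
#' @param hemisphere Hemisphere of the readouts.
#' @param alpha FDR level.
#' @param campaign2 Optional second campaign; when given, paired Wilcoxon
#'   tests of campaign vs campaign2 deltas are performed instead.
#' @return data.frame with one row per readout: `region`, `delta_mean`,
#'   `delta_median`, `W`, `p`, `q`, `direction`, `signif`.
#' @export
campaign_tests <- function(campaign, net, regions,
                           hemisphere = c("right", "left", "both"),
                           alpha = 0.05, campaign2 = NULL) {
  hemisphere <- match.arg(hemisphere)
  if (!is.null(campaign2) &&
      !identical(campaign$seeds, campaign2$seeds))
    stop("pairing error: campaigns were run with different seeds")
  per_region <- function(camp, idx) rowMeans(camp$deltas[, idx, drop = FALSE])
  rows <- list()
  tests <- list()
  for (r in regions) {
    idx <- resolve_regions(net$conn, r, hemisphere = hemisphere)
    d <- per_region(campaign, idx)
    tst <- if (is.null(campaign2)) wilcoxon_one_sample(d)
           else wilcoxon_paired(d, per_region(campaign2, idx))
    tests[[r]] <- tst
    rows[[r]] <- data.frame(region = r, delta_mean = mean(d),
                            delta_median = stats::median(d),
                            W = tst$statistic, p = tst$p)
  }
  tests <- adjust_tests(tests, alpha)
  out <- do.call(rbind, rows)
  out$q <- vapply(tests, function(t) t$q, 0)
  out$direction <- vapply(tests, function(t) t$direction, "")
  out$signif <- attr(tests, "reject")
  rownames(out) <- NULL
  out
}

#' Regional excitation/inhibition perturbation
#'
#' Returns a copy of the network in which the inhibitory (and optionally
#' excitatory) synaptic conductance quantum or the adaptation increment
#' of the target regions is replaced; all other regions are untouched
#' and the input network is not modified. Perturbations are bilateral by
#' default.
#'
#' @param net An [mf_network()].
#' @param regions Labels, base labels or group names (must be
#'   non-empty).
#' @param qi,qe,b New parameter values (nS / nS / per-spike increment);
#'   `NULL` leaves a field unchanged.
#' @param hemisphere Scope of the perturbation.
#' @return The perturbed [mf_network()].
#' @examples
#' net <- mf_network(synthetic_connectome(),
#'                   tf = list(E = sigmoid_transfer("E"),
#'                             I = sigmoid_transfer("I")))
#' net4 <- apply_ei_perturbation(net, "RSCv", qi = 4)
#' @export
apply_ei_perturbation <- function(net, regions, qi = NULL, qe = NULL,
                                  b = NULL,
                                  hemisphere = c("both", "left", "right")) {
  hemisphere <- match.arg(hemisphere)
  stopifnot(inherits(net, "mf_network"))
  if (length(regions) == 0) stop("empty region set")
  idx <- resolve_regions(net$conn, regions, hemisphere = hemisphere)
  if (length(idx) == 0) stop("empty region set after hemisphere filter")
  if (!is.null(qi)) { stopifnot(qi > 0); net$qi[idx] <- qi }
  if (!is.null(qe)) { stopifnot(qe > 0); net$qe[idx] <- qe }
  if (!is.null(b)) { stopifnot(b >= 0); net$b[idx] <- b }
  net
}

#' Classify the DMN response regime of one parameter cell
#'
#' Rule-based labelling of how insula-driven DMN suppression behaves,
#' from the core readout deltas (retrosplenial, cingulate and prelimbic
#' analogues), their FDR-corrected significance, and the number of
#' clusters the DMN group splits into at the reference linkage height.
#' Precedence: fragmentation > distributed_reversal > local_reversal >
#' unresponsive; `robust_suppression` requires all three readouts
#' significantly negative. Cells matching no rule are labelled
#' `unresponsive` (indeterminate responses are treated as loss of
#' responsiveness).
#'
#' @param deltas Named numeric: elements `RSCv`, `Cgv`, `PrL` (Hz).
#' @param signif Named logical rejection flags for the same elements.
#' @param dmn_clusters Number of clusters the DMN group occupies at the
#'   reference linkage height (1 = intact).
#' @param theta_u Unresponsiveness threshold on `|delta_RSCv|`, Hz
#'   (sweeps use 5\% of the across-grid delta IQR).
#' @return One of `"robust_suppression"`, `"unresponsive"`,
#'   `"local_reversal"`, `"distributed_reversal"`, `"fragmentation"`.
#' @export
classify_failure_mode <- function(deltas, signif, dmn_clusters = 1,
                                  theta_u = 0.01) {
  need <- c("RSCv", "Cgv", "PrL")
  if (!all(need %in% names(deltas)) || !all(need %in% names(signif)))
    stop("deltas and signif must be named with RSCv, Cgv, PrL")
  d <- deltas[need]; s <- signif[need]
  # undefined FC (frozen, zero-variance rates) cannot show fragmentation
  if (is.na(dmn_clusters)) dmn_clusters <- 1
  if (dmn_clusters >= 2) return("fragmentation")
  if (s["RSCv"] && d["RSCv"] > 0 && s["Cgv"] && d["Cgv"] > 0)
    return("distributed_reversal")
  if (s["RSCv"] && d["RSCv"] > 0 && d["Cgv"] <= 0)
    return("local_reversal")
  if (abs(d["RSCv"]) < theta_u && !s["RSCv"]) return("unresponsive")
  if (all(s) && all(d < 0)) return("robust_suppression")
  "unresponsive"
}

#' Four-dimensional parameter sweep with failure-mode classification
#'
#' Crosses regional excitatory and inhibitory synaptic conductance (in
#' `perturb_regions`, bilaterally) with the global E-to-I/E-to-E routing
#' ratio and the adaptation increment. Each cell runs a reduced
#' stimulation campaign (default 35 s, 20 seeds), tests the core
#' readouts with FDR correction, measures DMN fragmentation at the
#' reference linkage height and assigns a regime label. Default axes:
#' QE 0.1-4.1 nS in steps of 0.2 (21 values), QI 4-6 nS in steps of 0.1
#' (21 values; 441 cells per (R, b) pair), R in {1, 1.2, 1.4, 1.6}, b in
#' {0, 25, 50, 100}.
#'
#' Results are appended to `out_file` (CSV) as each cell completes;
#' re-running with the same file skips completed cells, so interrupted
#' sweeps resume and re-runs are idempotent.
#'
#' @param net An [mf_network()].
#' @param targets Stimulation targets (default the insula-like hub).
#' @param readout Core readout base labels.
#' @param perturb_regions Regions whose QE/QI are swept (bilaterally).
#' @param qe_axis,qi_axis,R_axis,b_axis Sweep axes.
#' @param n_seeds Realizations per cell.
#' @param duration Simulated seconds per realization.
#' @param h_ref Reference linkage height (on the `1 - r` scale) at which
#'   DMN fragmentation is assessed; the default (0.95) sits between the
#'   height at which the intact DMN completes (about 0.89 at baseline)
#'   and the height at which it joins the insular/frontal cluster.
#' @param alpha FDR level within each cell.
#' @param out_file Optional CSV path for incremental persistence.
#' @return An object of class `"sweep_result"`: long data.frame (one row
#'   per cell x readout) with the axes, `delta_mean`, `p`, `q`,
#'   `signif`, `dmn_clusters` and the per-cell `mode` label; axes stored
#'   as attributes. `theta_u` (5\% of the across-grid IQR of the RSCv
#'   deltas) is applied when all cells are available.
#' @export
parameter_sweep <- function(net, targets = "insula",
                            readout = c("RSCv", "Cgv", "PrL"),
                            perturb_regions = c("RSCv", "RSCd"),
                            qe_axis = seq(0.1, 4.1, by = 0.2),
                            qi_axis = seq(4, 6, by = 0.1),
                            R_axis = c(1, 1.2, 1.4, 1.6),
                            b_axis = c(0, 25, 50, 100), n_seeds = 20,
                            duration = 35, h_ref = 0.95, alpha = 0.05,
                            out_file = NULL) {
  stopifnot(length(qe_axis) > 0, length(qi_axis) > 0, length(R_axis) > 0,
            length(b_axis) > 0)
  grid <- expand.grid(qe = qe_axis, qi = qi_axis, R = R_axis, b = b_axis,
                      KEEP.OUT.ATTRS = FALSE)
  done <- NULL
  if (!is.null(out_file) && file.exists(out_file)) {
    done <- utils::read.csv(out_file)
  }
  key <- function(df) paste(signif(df$qe, 10), signif(df$qi, 10),
                            signif(df$R, 10), signif(df$b, 10))
  rows <- if (is.null(done)) list() else list(done)
  done_keys <- if (is.null(done)) character(0) else unique(key(done))
  for (ci in seq_len(nrow(grid))) {
    cell <- grid[ci, ]
    if (key(cell) %in% done_keys) next
    net2 <- apply_ei_perturbation(net, perturb_regions, qi = cell$qi,
                                  qe = cell$qe)
    net2$b[] <- cell$b
    net2$cfg$R <- cell$R
    camp <- run_stim_campaign(net2, targets, seeds = seq_len(n_seeds),
                              duration = duration, keep_fc = TRUE,
                              fc_regions = "dmn")
    tst <- campaign_tests(camp, net2, readout, alpha = alpha)
    ncl <- tryCatch(
      length(unique(cut_clusters(hcluster_fc(camp$fc), h = h_ref))),
      error = function(e) NA_integer_)
    row <- cbind(cell[rep(1, nrow(tst)), ], tst, dmn_clusters = ncl,
                 row.names = NULL)
    rows[[length(rows) + 1]] <- row
    if (!is.null(out_file))
      utils::write.table(row, out_file, sep = ",", append =
                           file.exists(out_file), col.names =
                           !file.exists(out_file), row.names = FALSE)
  }
  res <- do.call(rbind, rows)
  # regime label per cell, using theta_u from the across-grid spread
  rscv <- res[res$region == "RSCv", ]
  theta_u <- 0.05 * stats::IQR(rscv$delta_mean, na.rm = TRUE)
  lab <- character(nrow(rscv))
  for (i in seq_len(nrow(rscv))) {
    sel <- key(res) == key(rscv[i, ])
    sub <- res[sel, ]
    d <- stats::setNames(sub$delta_mean, sub$region)
    s <- stats::setNames(sub$signif, sub$region)
    lab[i] <- classify_failure_mode(d, s, sub$dmn_clusters[1], theta_u)
  }
  modes <- stats::setNames(lab, key(rscv))
  res$mode <- modes[key(res)]
  structure(res, axes = list(qe = qe_axis, qi = qi_axis, R = R_axis,
                             b = b_axis),
            theta_u = theta_u, h_ref = h_ref, class = c("sweep_result",
                                                        "data.frame"))
}

#' Enumerate stimulation sites for an all-site campaign
#'
#' Groups the regions of one hemisphere by base label (subdivisions of a
#' parent region are stimulated together) and returns one target set per
#' site.
#'
#' @param conn A [connectome()].
#' @param hemisphere Hemisphere to enumerate.
#' @return Named list of label vectors, one element per site.
#' @export
stimulation_sites <- function(conn, hemisphere = "right") {
  idx <- which(conn$hemisphere == hemisphere)
  split(conn$labels[idx], parent_label(base_label(conn$labels[idx])))
}

# parent region of a subdivision label: strip the trailing lowercase /
# digit subdivision suffix (RSCv, RSCd, RSCagl -> RSC; Cgv -> Cg), keeping
# at least two leading characters where possible
parent_label <- function(x) {
  p <- sub("[a-z0-9]+$", "", x)
  short <- nchar(p) < 2
  p[short] <- sub("[a-z0-9]$", "", x[short])
  p[nchar(p) < 1] <- x[nchar(p) < 1]
  p
}
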