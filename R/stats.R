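#' Epoch a simulation into stimulus-aligned trials
#'
#' Cuts the rate series into 2 s windows, each starting 1 s before a
#' pulse onset, for every complete epoch of the protocol (see
#' [n_complete_epochs()]).
#'
#' @param sim An `"mf_sim"`.
#' @param protocol A [stim_protocol()]; defaults to the protocol stored
#'   in `sim`.
#' @param population `"E"` or `"I"` rates.
#' @return An object of class `"evoked_response"`: array
#'   `(trial, sample, region)` with attributes `fs` (Hz), `onset_in_window`
#'   (1 s) and `labels`.
#' @export
epoch_and_average <- function(sim, protocol = sim$protocol,
                              population = c("E", "I")) {
  population <- match.arg(population)
  if (is.null(protocol)) stop("no stimulation protocol available")
  m <- if (population == "E") sim$rE else sim$rI
  fs <- 1000 / sim$config$record_dt
  duration <- max(sim$time)
  n_tr <- n_complete_epochs(protocol, duration)
  if (n_tr < 1) stop("zero complete epochs in the simulated span")
  n_s <- as.integer(round(2 * fs))
  half <- n_s %/% 2L
  ev <- array(NA_real_, c(n_tr, n_s, nrow(m)))
  for (k in seq_len(n_tr)) {
    t0 <- protocol$onset + (k - 1) * protocol$period - 1
    i0 <- which.min(abs(sim$time - t0))
    ev[k, , ] <- t(m[, i0 + seq_len(n_s) - 1L, drop = FALSE])
  }
  structure(ev, fs = fs, onset_in_window = 1, labels = rownames(m),
            class = "evoked_response")
}

#' Pre/post stimulus rate change per region
#'
#' The suppression / enhancement statistic: mean of the trial-averaged
#' evoked trace over the second after stimulus onset minus its mean over
#' the second before.
#'
#' @param ev An `"evoked_response"` from [epoch_and_average()].
#' @return Named numeric vector of deltas, Hz (one per region).
#' @export
prepost_delta <- function(ev) {
  stopifnot(inherits(ev, "evoked_response"))
  n_s <- dim(ev)[2]
  half <- n_s %/% 2L
  avg <- apply(ev, c(2, 3), mean)  # sample x region
  out <- colMeans(avg[(half + 1):n_s, , drop = FALSE]) -
    colMeans(avg[1:half, , drop = FALSE])
  names(out) <- attr(ev, "labels")
  out
}

# exact null distribution of the signed-rank statistic W+ over sign
# assignments; ranks may be midranks (multiples of 1/2), handled by
# doubling. Returns P(W+ <= w) and P(W+ >= w).
signed_rank_tails <- function(ranks, W) {
  r2 <- as.integer(round(2 * ranks))
  tot <- sum(r2)
  f <- numeric(tot + 1)  # f[s+1] = number of assignments with 2*W+ == s
  f[1] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1):(tot + 1)] <- g[(r + 1):(tot + 1)] + f[1:(tot - r + 1)]
    f <- g
  }
  w2 <- round(2 * W)
  p_le <- sum(f[seq_len(min(w2, tot) + 1)]) / 2^length(r2)
  p_ge <- sum(f[(max(w2, 0) + 1):(tot + 1)]) / 2^length(r2)
  c(le = p_le, ge = p_ge)
}

wilcoxon_core <- function(d, exact_max = 25L) {
  d <- d[is.finite(d)]
  d <- d[d != 0]  # zero differences dropped (Wilcoxon's policy)
  n <- length(d)
  if (n == 0)
    return(structure(list(statistic = NA_real_, p = NA_real_,
                          q = NA_real_, direction = "none", n = 0L,
                          method = "none", no_test = TRUE),
                     class = "mf_test"))
  rk <- rank(abs(d))  # midranks under ties
  W <- sum(rk[d > 0])
  EW <- n * (n + 1) / 4
  if (n <= exact_max) {
    tails <- signed_rank_tails(rk, W)
    p <- min(1, 2 * min(tails["le"], tails["ge"]))
    method <- "exact"
  } else {
    ties <- table(rk)
    VW <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - EW) / sqrt(VW)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  direction <- if (W > EW) "enhancement" else if (W < EW) "suppression"
               else "none"
  structure(list(statistic = W, p = p, q = NA_real_, direction = direction,
                 n = n, method = method, no_test = FALSE),
            class = "mf_test")
}

#' Exact one-sample Wilcoxon signed-rank test
#'
#' Two-tailed test of the per-seed deltas against `mu`. Zero differences
#' are dropped; tied absolute values receive midranks. The p-value is
#' exact (full sign-assignment null distribution, tie-aware) for n <= 25
#' and a tie-corrected normal approximation above. When every difference
#' is zero no test is possible: the result is flagged (`no_test`) with an
#' undefined p, and treated as non-significant downstream.
#'
#' @param deltas Numeric vector (e.g. per-seed pre/post deltas).
#' @param mu Null location.
#' @return An object of class `"mf_test"`: list with `statistic` (W+),
#'   `p`, `q` (NA until FDR adjustment), `direction` (`"suppression"`,
#'   `"enhancement"` or `"none"`), `n`, `method`, `no_test`.
#' @examples
#' wilcoxon_one_sample(c(1, 2, 3, 4, 5, 6))  # W = 21, p = 2/64
#' @export
wilcoxon_one_sample <- function(deltas, mu = 0) {
  wilcoxon_core(as.numeric(deltas) - mu)
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test on the per-seed differences `a - b` of two
#' seed-aligned conditions. `direction = "enhancement"` means `a` tends
#' to exceed `b`.
#'
#' @param a,b Numeric vectors of equal length, aligned by seed.
#' @return An `"mf_test"` (see [wilcoxon_one_sample()]).
#' @export
wilcoxon_paired <- function(a, b) {
  if (length(a) != length(b))
    stop("pairing error: conditions have different lengths")
  wilcoxon_core(as.numeric(a) - as.numeric(b))
}

#' @export
print.mf_test <- function(x, ...) {
  if (x$no_test) {
    cat("Wilcoxon signed-rank: no non-zero differences (no test)\n")
  } else {
    cat(sprintf("Wilcoxon signed-rank (%s): W+ = %g, n = %d, p = %.4g%s\n",
                x$method, x$statistic, x$n, x$p,
                if (!is.na(x$q)) sprintf(", q = %.4g", x$q) else ""))
    cat(sprintf("  direction: %s\n", x$direction))
  }
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]) and rejection
#' flags at level `alpha`.
#'
#' @param pvals Numeric p-values in `[0, 1]` (NAs propagate).
#' @param alpha FDR level.
#' @return `list(q, reject)`.
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.04))$q  # 0.03 0.03 0.04
#' @export
fdr_bh <- function(pvals, alpha = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(pvals, method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha)
}

#' Adjust a set of region-level tests for multiple comparisons
#'
#' Applies [fdr_bh()] over a list of `"mf_test"` results (one FDR family
#' per experiment), filling their `q` fields. Flagged no-test entries are
#' excluded from the family and kept non-significant.
#'
#' @param tests Named list of `"mf_test"` objects.
#' @param alpha FDR level.
#' @return The list with `q` filled in and a `reject` attribute.
#' @export
adjust_tests <- function(tests, alpha = 0.05) {
  p <- vapply(tests, function(t) if (t$no_test) NA_real_ else t$p, 0)
  adj <- fdr_bh(p, alpha)
  for (i in seq_along(tests)) tests[[i]]$q <- adj$q[i]
  attr(tests, "reject") <- adj$reject
  tests
}

#' Functional connectivity averaged over realizations
#'
#' Pearson correlation matrices of the excitatory rate series (after
#' transient removal) of each realization, averaged elementwise; the
#' diagonal is forced to 1. Regions with zero variance in any
#' realization yield undefined entries, which are kept as NA with a
#' warning.
#'
#' @param sims A single `"mf_sim"` or list of them (equal lengths).
#' @param regions Optional subset (labels, base labels or group names
#'   resolved against the region labels).
#' @param transient Seconds dropped from the start of each series;
#'   defaults to the config transient.
#' @return An `"fc_matrix"`: symmetric correlation matrix with unit
#'   diagonal.
#' @export
functional_connectivity <- function(sims, regions = NULL, transient = NULL) {
  if (inherits(sims, "mf_sim")) sims <- list(sims)
  stopifnot(length(sims) >= 1)
  acc <- NULL
  for (s in sims) {
    tr <- if (is.null(transient)) s$config$transient else transient
    keep <- s$time > tr
    m <- s$rE[, keep, drop = FALSE]
    if (!is.null(regions))
      m <- m[resolve_regions(list2conn(s), regions), , drop = FALSE]
    sdv <- apply(m, 1, stats::sd)
    if (any(sdv == 0))
      warning(sprintf("zero-variance region(s): %s (FC entries undefined)",
                      paste(rownames(m)[sdv == 0], collapse = ", ")))
    cc <- suppressWarnings(stats::cor(t(m)))
    acc <- if (is.null(acc)) cc else acc + cc
  }
  fc <- acc / length(sims)
  diag(fc) <- 1
  structure(fc, class = c("fc_matrix", class(fc)))
}

#' Complete-linkage clustering of a functional-connectivity matrix
#'
#' Agglomerates regions with `1 - r` as the distance and complete
#' linkage. Undefined FC entries are an error naming the regions
#' involved.
#'
#' @param fc An `"fc_matrix"` (or plain correlation matrix).
#' @return An object of class `"fc_clust"` wrapping the
#'   [stats::hclust()] tree (elements `merge`, `height`, `labels`).
#' @export
hcluster_fc <- function(fc) {
  if (anyNA(fc)) {
    bad <- rownames(fc)[apply(is.na(fc), 1, any)]
    stop(sprintf("undefined FC entries for region(s): %s",
                 paste(bad, collapse = ", ")))
  }
  hc <- stats::hclust(stats::as.dist(1 - fc), method = "complete")
  structure(list(hclust = hc, labels = hc$labels), class = "fc_clust")
}

#' @export
print.fc_clust <- function(x, ...) {
  cat(sprintf("complete-linkage tree over %d regions; merge heights %s\n",
              length(x$labels),
              paste(signif(x$hclust$height, 3), collapse = ", ")))
  invisible(x)
}

#' @export
plot.fc_clust <- function(x, ...) {
  plot(x$hclust, xlab = "", sub = "", main = "complete linkage on 1 - r",
       ...)
  invisible(x)
}

#' Cut a cluster tree
#'
#' @param tree An `"fc_clust"`.
#' @param k Number of clusters, or
#' @param h Cut height on the `1 - r` scale.
#' @return Named integer cluster memberships ([stats::cutree()]).
#' @export
cut_clusters <- function(tree, k = NULL, h = NULL) {
  stopifnot(inherits(tree, "fc_clust"))
  stats::cutree(tree$hclust, k = k, h = h)
}

#' Merge table of a cluster tree
#'
#' @param tree An `"fc_clust"`.
#' @return data.frame with columns `step`, `a`, `b` (negative = leaf
#'   index, positive = earlier merge step) and `height`.
#' @export
merge_table <- function(tree) {
  stopifnot(inherits(tree, "fc_clust"))
  hc <- tree$hclust
  data.frame(step = seq_along(hc$height), a = hc$merge[, 1],
             b = hc$merge[, 2], height = hc$height)
}

#' Nested-list text serialization of a dendrogram
#'
#' @param tree An `"fc_clust"`.
#' @param path Optional file to write the single-line serialization to.
#' @return Character scalar, e.g. `"((A,B):0.1,C):0.9"`.
#' @export
dendrogram_text <- function(tree, path = NULL) {
  hc <- tree$hclust
  lab <- hc$labels
  render <- function(node) {
    if (node < 0) return(lab[-node])
    sprintf("(%s,%s):%g", render(hc$merge[node, 1]),
            render(hc$merge[node, 2]), hc$height[node])
  }
  out <- render(nrow(hc$merge))
  if (!is.null(path)) writeLines(out, path)
  out
}
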