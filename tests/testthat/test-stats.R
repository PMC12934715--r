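flat_sim <- function(value = 3, duration = 20, fs = 100) {
  sur <- generate_surrogate_evoked(n_regions = 2, duration = duration,
                                   fs = fs, effects = 0, noise_sd = 0,
                                   baseline = value, seed = 1)
  sur
}

test_that("epoching aligns 2 s windows around each pulse", {
  sim <- flat_sim()
  ev <- epoch_and_average(sim)
  expect_identical(dim(ev)[1], n_complete_epochs(sim$protocol, 20))
  expect_true(all(ev == 3))
  expect_identical(dim(ev)[2], 200L)  # 2 s at 100 Hz

  # a 150 s run with 5 s onset and 2 s period gives 72 trials
  long <- generate_surrogate_evoked(n_regions = 1, duration = 150, fs = 20,
                                    effects = 0, noise_sd = 0, seed = 1)
  expect_identical(dim(epoch_and_average(long))[1], 72L)

  # an injected effect occupies the post-onset half of every trial
  prot <- stim_protocol("all", hemisphere = "both")
  sur <- generate_surrogate_evoked(n_regions = 1, duration = 21, fs = 100,
                                   effects = -1, noise_sd = 0,
                                   protocol = prot, seed = 1)
  ev2 <- epoch_and_average(sur, prot)
  expect_true(all(abs(ev2[, 101:200, 1] - (5 - 1)) < 1e-9))
  expect_true(all(abs(ev2[, 1:100, 1] - 5) < 1e-9))

  short <- flat_sim(duration = 6)
  expect_error(epoch_and_average(short), "zero complete epochs")
})

test_that("pre/post deltas are post-window minus pre-window means", {
  sim <- flat_sim()
  expect_equal(unname(prepost_delta(epoch_and_average(sim))), c(0, 0))
  prot <- stim_protocol("all", hemisphere = "both")
  sur <- generate_surrogate_evoked(n_regions = 1, duration = 21, fs = 100,
                                   effects = 3, noise_sd = 0, baseline = 2,
                                   protocol = prot, seed = 1)
  expect_equal(unname(prepost_delta(epoch_and_average(sur, prot))), 3)
})

test_that("the exact signed-rank test reproduces hand-enumerated cases", {
  t1 <- wilcoxon_one_sample(c(1, 2, 3, 4, 5, 6))
  expect_equal(t1$statistic, 21)
  expect_equal(t1$p, 2 / 64)
  expect_identical(t1$direction, "enhancement")

  t2 <- wilcoxon_one_sample(c(-1, 1))
  expect_equal(t2$p, 1)
  expect_identical(t2$direction, "none")

  expect_true(wilcoxon_one_sample(c(0, 0, 0))$no_test)
})

test_that("exact p equals full sign-assignment enumeration for n <= 10", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(3:10, 1)
    x <- round(rnorm(n), sample(0:1, 1))  # rounding induces ties and zeros
    if (all(x == 0)) next
    expect_equal(wilcoxon_one_sample(x)$p, enum_signed_rank_p(x),
                 tolerance = 1e-12, label = paste(x, collapse = ","))
  }
})

test_that("exact p matches stats::wilcox.test on tie-free data", {
  set.seed(9)
  for (rep in 1:20) {
    x <- rnorm(sample(6:20, 1))
    expect_equal(wilcoxon_one_sample(x)$p,
                 suppressWarnings(wilcox.test(x, exact = TRUE)$p.value),
                 tolerance = 1e-12)
  }
})

test_that("large samples switch to the tie-corrected normal approximation", {
  set.seed(3)
  x <- rnorm(40) + 0.4
  t <- wilcoxon_one_sample(x)
  expect_identical(t$method, "normal approximation")
  ref <- suppressWarnings(wilcox.test(x, exact = FALSE, correct = FALSE))
  expect_equal(t$p, ref$p.value, tolerance = 1e-10)
})

test_that("the paired test works on seed-aligned differences", {
  a <- c(3, 5, 2, 8, 1, 4)
  t <- wilcoxon_paired(a + 1, a)
  expect_equal(t$p, 0.03125)
  expect_identical(t$direction, "enhancement")
  swapped <- wilcoxon_paired(a, a + 1)
  expect_equal(swapped$p, t$p)
  expect_identical(swapped$direction, "suppression")
  expect_true(wilcoxon_paired(a, a)$no_test)
  expect_error(wilcoxon_paired(1:3, 1:4), "pairing error")
})

test_that("BH adjustment reproduces the step-up worked example", {
  adj <- fdr_bh(c(0.01, 0.02, 0.04))
  expect_equal(adj$q, c(0.03, 0.03, 0.04))
  expect_identical(adj$reject, c(TRUE, TRUE, TRUE))
  expect_equal(fdr_bh(0.2)$q, 0.2)
  p <- c(0.001, 0.5, 0.03, 0.2, 0.04)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(fdr_bh(p[perm])$q, fdr_bh(p)$q[perm])
  expect_true(all(fdr_bh(p)$q >= p))
  expect_error(fdr_bh(c(0.5, 1.2)), "must lie in")
})

test_that("functional connectivity averages realizations with unit diagonal", {
  t1 <- seq(0, 4 * pi, length.out = 400)
  mk <- function(a, b, cpy) {
    s <- flat_sim(duration = 4, fs = 100)
    s$rE <- rbind(a, b, if (cpy) a else -a)
    rownames(s$rE) <- s$labels <- paste0("R", 1:3)
    s$rI <- s$w <- s$rE * 0
    s$config$transient <- 0
    s
  }
  a <- sin(t1) + 5
  b <- cos(3 * t1) + 5
  fc <- functional_connectivity(list(mk(a, b, TRUE), mk(a, b, TRUE)))
  expect_equal(diag(fc), rep(1, 3), ignore_attr = TRUE)
  expect_equal(fc[1, 3], 1)  # identical series
  expect_equal(fc, t(fc))
  fc2 <- functional_connectivity(list(mk(a, b, TRUE), mk(a, b, FALSE)))
  expect_equal(fc2[1, 3], 0)  # mean of r = 1 and r = -1

  z <- mk(a, b, TRUE)
  z$rE[2, ] <- 7  # zero variance
  expect_warning(fcz <- functional_connectivity(z), "zero-variance")
  expect_true(is.na(fcz[1, 2]))
  expect_error(hcluster_fc(fcz), "undefined FC.*R2")
})

test_that("complete linkage reproduces the hand-computed merge sequence", {
  fc <- matrix(c(1, 0.9, 0.1,
                 0.9, 1, 0.2,
                 0.1, 0.2, 1), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- hcluster_fc(fc)
  mt <- merge_table(tree)
  # D(A,B) = 0.1 merges first; C joins at the complete-linkage height 0.9
  expect_equal(mt$height, c(0.1, 0.9))
  expect_setequal(unlist(mt[1, c("a", "b")]), c(-1, -2))
  expect_identical(unname(cut_clusters(tree, k = 2)),
                   c(1L, 1L, 2L))
  expect_true(all(diff(tree$hclust$height) >= 0))
  txt <- dendrogram_text(tree)
  expect_match(txt, "\\(A,B\\):0.1")   # first merge pairs A and B
  expect_match(txt, "\\):0.9$")        # final merge at the complete height
})

test_that("equal distances merge at a single height", {
  fc <- matrix(0.5, 4, 4); diag(fc) <- 1
  rownames(fc) <- colnames(fc) <- paste0("R", 1:4)
  tree <- hcluster_fc(fc)
  expect_true(all(abs(tree$hclust$height - 0.5) < 1e-12))
})

test_that("cutting at two clusters recovers the surrogate block structure", {
  sur <- generate_surrogate_evoked(n_regions = 6, duration = 125, fs = 50,
                                   effects = 0, noise_sd = 1,
                                   blocks = list(list(regions = 1:3, rho = 0.9),
                                                 list(regions = 4:6, rho = 0.9)),
                                   seed = 8)
  fc <- functional_connectivity(sur, transient = 0)
  cl <- cut_clusters(hcluster_fc(fc), k = 2)
  expect_length(unique(cl[1:3]), 1)
  expect_length(unique(cl[4:6]), 1)
  expect_true(cl[1] != cl[4])
})

test_that("spontaneous activity segregates the DMN from the insular-frontal group", {
  net <- mf_network(synthetic_connectome(), tf = fitted_tfs(),
                    cfg = sim_config(duration = 30))
  sims <- simulate(net, nsim = 6, seed = 31)
  idx <- resolve_regions(net$conn, c("dmn", "insula", "frontal"),
                         hemisphere = "right")
  fc <- functional_connectivity(sims, regions = net$conn$labels[idx])
  cl <- cut_clusters(hcluster_fc(fc), k = 2)
  dmn <- paste0(c("RSCv", "Cgv", "PrL", "RSCd", "PTLp"), "_R")
  other <- paste0(c("AI", "ORB", "FRP"), "_R")
  expect_length(unique(cl[dmn]), 1)
  expect_true(all(cl[other] != cl[dmn[1]]))
})
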