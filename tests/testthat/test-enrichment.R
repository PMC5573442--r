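test_that("low-signal filter drops probes only when low in every sample", {
  m <- rbind(allLow = c(29, 29, 29, 29, 29, 29),
             oneHigh = c(31, 0, 0, 0, 0, 0),
             high = c(100, 90, 95, 40, 50, 60))
  ce <- make_ce(m)
  kept <- filterLowSignal(ce, 30)
  expect_equal(rownames(kept), c("oneHigh", "high"))
  empty <- filterLowSignal(ce[0, ], 30)
  expect_equal(nrow(empty), 0L)
})

test_that("nuclear percentage is the replicate-mean share of total signal", {
  m <- rbind(p1 = c(90, 90, 90, 10, 10, 10),
             p2 = c(50, 60, 70, 50, 60, 70),
             p3 = c(0, 0, 0, 0, 0, 0),
             p4 = c(5, 5, 5, 0, 0, 0))
  ce <- make_ce(m)
  pct <- nuclearPercentage(ce)
  expect_equal(unname(pct[c("p1", "p2", "p4")]), c(90, 50, 100))
  expect_true(is.na(pct["p3"]))
  # invariance to global rescaling
  ce3 <- make_ce(3 * m)
  expect_equal(nuclearPercentage(ce3), pct)
  # single-compartment input is a configuration error
  nucOnly <- CompartmentExperiment(m[, 1:3], rep("nuclear", 3), 1:3)
  expect_error(nuclearPercentage(nucOnly), "both nuclear and cytoplasmic")
})

test_that("percentage calls use a strict threshold and skip undefined probes", {
  pct <- c(a = 71.94, b = 70, c = 0, d = NA, e = 70.0001)
  call <- callNuclearPercentage(pct, 70)
  expect_equal(unname(call), c(TRUE, FALSE, FALSE, FALSE, TRUE))
})

test_that("rank scores follow the in-sample median-distance definition", {
  ce <- CompartmentExperiment(
    matrix(c(10, 20, 30), 3, 1, dimnames = list(paste0("p", 1:3), "N1")),
    "nuclear", 1L)
  expect_equal(unname(rankScores(ce)[, 1]), c(-1, 0, 1))
  tied <- CompartmentExperiment(
    matrix(7, 4, 1, dimnames = list(paste0("p", 1:4), "N1")),
    "nuclear", 1L)
  expect_equal(unname(rankScores(tied)[, 1]), rep(0, 4))
  # oracle comparison on a random 50-probe sample
  set.seed(7)
  m <- matrix(rlnorm(50 * 4, 5, 1), 50, 4,
              dimnames = list(sprintf("p%02d", 1:50), NULL))
  ce <- make_ce(m)
  sc <- rankScores(ce)
  for (j in 1:4) expect_equal(unname(sc[, j]), oracle_rank_scores(m[, j]))
})

test_that("rank-separation calls require strict full separation", {
  comp <- rep(c("nuclear", "cytoplasmic"), each = 3)
  sc <- rbind(sep = c(5, 4, 6, 1, 2, 3),
              overlap = c(5, 2, 6, 1, 3, 4),
              tie = c(3, 4, 5, 1, 2, 3))
  calls <- callRankSeparation(sc, comp)
  expect_equal(unname(calls), c(TRUE, FALSE, FALSE))
})

test_that("rank method is invariant to strictly monotone in-sample transforms", {
  sim <- simulateExpression(nProbes = 60, nEnriched = 6, seed = 17)
  ce <- sim$experiment
  comp <- compartments(ce)
  base <- callRankSeparation(rankScores(ce), comp)
  sq <- CompartmentExperiment(signalMatrix(ce)^2, comp, replicates(ce))
  lg <- CompartmentExperiment(log1p(signalMatrix(ce)), comp, replicates(ce))
  expect_identical(callRankSeparation(rankScores(sq), comp), base)
  expect_identical(callRankSeparation(rankScores(lg), comp), base)
})

test_that("quantile normalization equalizes sample distributions", {
  m <- matrix(rep(c(1, 5, 9), 4), 3, 4,
              dimnames = list(paste0("p", 1:3), c("n1", "n2", "c1", "c2")))
  ce <- make_ce(m)
  expect_equal(signalMatrix(quantileNormalize(ce)), m)
  # defining property and oracle comparison on a tie-free random matrix
  set.seed(8)
  m2 <- matrix(rlnorm(20 * 4, 4, 1), 20, 4,
               dimnames = list(sprintf("p%02d", 1:20),
                               c("n1", "n2", "c1", "c2")))
  qn <- signalMatrix(quantileNormalize(make_ce(m2)))
  sorted <- apply(qn, 2, sort)
  expect_equal(sorted, sorted[, c(1, 1, 1, 1)], ignore_attr = TRUE)
  expect_equal(qn, oracle_quantile_normalize(m2))
})

test_that("moderated t reduces to the ordinary pooled t when d0 = 0", {
  sim <- simulateExpression(nProbes = 50, nEnriched = 5, seed = 2)
  qn <- quantileNormalize(filterLowSignal(sim$experiment))
  res <- moderatedT(qn, prior = list(d0 = 0))
  y <- log2(signalMatrix(qn) + 1)
  comp <- compartments(qn)
  for (i in sample(nrow(y), 10)) {
    g1 <- y[i, comp == "nuclear"]; g2 <- y[i, comp == "cytoplasmic"]
    if (var(g1) + var(g2) == 0) next
    ref <- t.test(g1, g2, var.equal = TRUE)
    expect_equal(res$t[i], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], ref$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t handles equal group means and degenerate designs", {
  m <- rbind(flat = c(10, 20, 30, 30, 20, 10),
             diff = c(100, 110, 90, 10, 12, 9))
  res <- moderatedT(make_ce(m))
  expect_equal(res$t[1], 0)
  expect_equal(res$p[1], 1)
  expect_gt(res$t[2], 0)
  one_rep <- CompartmentExperiment(m[, c(1, 4)],
                                   c("nuclear", "cytoplasmic"), c(1L, 1L))
  expect_error(moderatedT(one_rep), "two replicates")
})

test_that("moderated t is calibrated under the null", {
  set.seed(42)
  m <- matrix(rlnorm(1000 * 6, 5, 1), 1000, 6,
              dimnames = list(sprintf("p%04d", 1:1000), NULL))
  res <- moderatedT(make_ce(m))
  expect_true(abs(mean(res$p < 0.05) - 0.05) < 0.02)
})

test_that("moderated t agrees with an independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  sim <- simulateExpression(nProbes = 200, nEnriched = 10, seed = 19)
  qn <- quantileNormalize(filterLowSignal(sim$experiment))
  res <- moderatedT(qn)
  y <- log2(signalMatrix(qn) + 1)
  design <- cbind(1, compartments(qn) == "nuclear")
  fit <- limma::eBayes(limma::lmFit(y, design))
  expect_gt(cor(res$t, fit$t[, 2]), 0.95)
  expect_gt(cor(res$t, fit$t[, 2], method = "spearman"), 0.95)
})

test_that("variance-prior fit recovers simulated prior parameters", {
  set.seed(33)
  d <- 4; d0 <- 8; s02 <- 0.5
  s2 <- s02 * d0 / rchisq(20000, d0) * rchisq(20000, d) / d
  fit <- fitVariancePrior(s2, d)
  expect_equal(fit$d0, d0, tolerance = 0.25)
  expect_equal(fit$s02, s02, tolerance = 0.1)
  # homogeneous variances give a degenerate (infinite-df) prior
  s2c <- rep(1, 100)
  expect_equal(fitVariancePrior(s2c, d)$d0, Inf)
})

test_that("the enrichment table reports all three methods per retained probe", {
  sim <- simulateExpression(nProbes = 120, nEnriched = 6, seed = 27)
  tab <- enrichmentTable(sim$experiment)
  expect_equal(tab$probe_id,
               rownames(filterLowSignal(sim$experiment, 30)))
  expect_named(tab, c("probe_id", "mean_nuclear", "mean_cytoplasmic",
                      "nuclear_pct", "method2_call", "method1_t",
                      "method1_p", "method1_q", "method3_call"))
  # the implied cytoplasmic percent complements the nuclear percent
  cyt_pct <- 100 * tab$mean_cytoplasmic /
    (tab$mean_nuclear + tab$mean_cytoplasmic)
  expect_equal(tab$nuclear_pct + cyt_pct, rep(100, nrow(tab)))
})
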