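# Twin-design DMR testing: per-pair logFCs, the (moderated) one-sample
# test, and the discordant-vs-concordant Wilcoxon stage.

makeTwinMe <- function(nReg = 50, nMzd = 3, nMzc = 2, mu = 100, seed = 9) {
  set.seed(seed)
  pairIds <- c(sprintf("MZD%02d", 1:nMzd), sprintf("MZC%02d", 1:nMzc))
  samples <- as.vector(t(cbind(paste0(pairIds, "_1"), paste0(pairIds, "_2"))))
  m <- matrix(rnbinom(nReg * length(samples), mu = mu, size = 10),
              nReg, length(samples),
              dimnames = list(sprintf("r%03d", 1:nReg), samples))
  design <- data.frame(
    sample = samples, organism = "human",
    group = rep(c("responder", "nonresponder"), length(pairIds)),
    pair_id = rep(pairIds, each = 2),
    pair_type = rep(c("MZD", "MZC"), c(nMzd, nMzc))[rep(1:length(pairIds),
                                                        each = 2)],
    stringsAsFactors = FALSE)
  design$group[design$pair_type == "MZC"] <- "nonresponder"
  regions <- RegionSet(rep("chr1", nReg), seq_len(nReg) * 1000,
                       seq_len(nReg) * 1000 + 500, "toy",
                       name = rownames(m))
  me <- MethylExperiment(m, design, regions)
  colnames(me) <- samples
  me
}

test_that("twinPairLogFC contrasts responder over non-responder per pair", {
  me <- makeTwinMe()
  counts <- methCounts(me)
  norm <- tmmFactors(counts)
  norm$factors[] <- 1
  norm$effective_lib_size <- norm$lib_size
  lfc <- twinPairLogFC(counts, norm, studyDesign(me),
                       DmrTestConfig(pseudocount = 0))
  # direct arithmetic for the first MZD pair
  cpmMat <- cpm(counts, norm)
  expect_equal(lfc$mzd[, "MZD01"],
               log2(cpmMat[, "MZD01_1"] / cpmMat[, "MZD01_2"]))
  # swapping twin labels flips the sign
  d2 <- studyDesign(me)
  i <- d2$pair_id == "MZD01"
  d2$group[i] <- rev(d2$group[i])
  lfc2 <- twinPairLogFC(counts, norm, d2, DmrTestConfig(pseudocount = 0))
  expect_equal(lfc2$mzd[, "MZD01"], -lfc$mzd[, "MZD01"])
  # equal cpm in both twins gives logFC 0
  cEq <- counts; cEq[, "MZD02_2"] <- cEq[, "MZD02_1"]
  normEq <- norm
  normEq$lib_size <- colSums(cEq); normEq$effective_lib_size <- colSums(cEq)
  lfcEq <- twinPairLogFC(cEq, normEq, studyDesign(me), DmrTestConfig())
  expect_equal(unname(lfcEq$mzd[, "MZD02"]), rep(0, nrow(cEq)))
  # a 4x responder CPM excess is ~2 on the log2 scale (pseudocount small)
  c4 <- counts; c4[, "MZD03_1"] <- c4[, "MZD03_2"] * 4L
  norm4 <- norm
  norm4$effective_lib_size[] <- 1e6  # cpm == counts
  lfc4 <- twinPairLogFC(c4, norm4, studyDesign(me), DmrTestConfig())
  expect_equal(unname(lfc4$mzd[, "MZD03"]), rep(2, nrow(c4)),
               tolerance = 0.02)
  # incomplete pair errors with the pair id
  dBad <- studyDesign(me)[-1, ]
  cBad <- counts
  expect_error(twinPairLogFC(cBad, norm, dBad, DmrTestConfig()), "MZD01")
})

test_that("unmoderated twin test matches the textbook one-sample t", {
  withr::local_seed(31)
  lfc <- matrix(rnorm(500 * 9), 500, 9,
                dimnames = list(sprintf("r%03d", 1:500), NULL))
  out <- twinDmrTest(lfc, DmrTestConfig(moderation = "off"))
  tOracle <- apply(lfc, 1, function(x) stats::t.test(x)$p.value)
  expect_equal(out$p, unname(tOracle), tolerance = 1e-10)
  expect_equal(out$direction,
               unname(ifelse(rowMeans(lfc) >= 0, "hyper", "hypo")))
  expect_true(all(out$significant == (out$p < 0.001)))
})

test_that("moderated twin test matches the limma empirical-Bayes oracle", {
  skip_if_not_installed("limma")
  withr::local_seed(32)
  sd0 <- sqrt(1 / rgamma(400, shape = 4, rate = 4))  # heterogeneous variances
  lfc <- matrix(rnorm(400 * 9, sd = rep(sd0, 9)), 400, 9,
                dimnames = list(sprintf("r%03d", 1:400), NULL))
  out <- twinDmrTest(lfc, DmrTestConfig(moderation = "on"))
  fit <- limma::eBayes(limma::lmFit(lfc))
  expect_equal(out$p, unname(fit$p.value[, 1]), tolerance = 1e-8)
  expect_equal(out$statistic, unname(fit$t[, 1]), tolerance = 1e-8)
})

test_that("degenerate regions follow the stated conventions", {
  lfc <- rbind(allzero = rep(0, 9),
               constant = rep(1, 9),
               jitter = 1 + c(rep(0, 8), 1e-9))
  out <- twinDmrTest(lfc, DmrTestConfig(moderation = "off"))
  expect_equal(out$p[1], 1)
  expect_equal(out$statistic[1], 0)
  expect_equal(out$statistic[2], Inf)
  expect_equal(out$p[2], .Machine$double.xmin)
  expect_true(out$significant[3])  # near-constant nonzero mean
})

test_that("unmoderated test is calibrated at the DMR threshold", {
  withr::local_seed(33)
  n <- 40000
  lfc <- matrix(rnorm(n * 9), n, 9, dimnames = list(paste0("r", 1:n), NULL))
  out <- twinDmrTest(lfc, DmrTestConfig(moderation = "off"))
  frac <- mean(out$p < 0.001)
  mcSd <- sqrt(0.001 * 0.999 / n)
  expect_lt(abs(frac - 0.001), 3 * mcSd)
})

test_that("Wilcoxon stage: exact branch matches known constants", {
  cfg <- DmrTestConfig()
  # all 9 MZD values above all 9 MZC values
  mzd <- matrix(10 + 1:9, 1, dimnames = list("r1", NULL))
  mzc <- matrix(1:9 / 10, 1, dimnames = list("r1", NULL))
  out <- discordanceWilcoxon(mzd, mzc, "r1", cfg)
  expect_equal(out$wilcoxon_p, 1 / choose(18, 9), tolerance = 1e-12)
  # identical multisets are not separable
  same <- matrix(1:9, 1, dimnames = list("r1", NULL))
  outSame <- discordanceWilcoxon(same, same + 1e-9, "r1", cfg)
  expect_gte(outSame$wilcoxon_p, 0.5)
  # n = 2 vs 2, complete separation: p = 1/6
  a <- matrix(c(3, 4), 1, dimnames = list("r1", NULL))
  b <- matrix(c(1, 2), 1, dimnames = list("r1", NULL))
  expect_equal(discordanceWilcoxon(a, b, "r1", cfg)$wilcoxon_p, 1 / 6,
               tolerance = 1e-12)
  expect_error(discordanceWilcoxon(a, b, "rX", cfg), "present in both")
})

test_that("Wilcoxon exact branch matches full enumeration for n1=n2<=8", {
  withr::local_seed(34)
  cfg <- DmrTestConfig()
  for (n in 2:8) {
    for (rep in 1:3) {
      x <- matrix(runif(n, 0, 2), 1, dimnames = list("r1", NULL))
      y <- matrix(runif(n, 0, 2), 1, dimnames = list("r1", NULL))
      ours <- discordanceWilcoxon(x, y, "r1", cfg)$wilcoxon_p
      expect_equal(ours, wilcoxEnumOracle(as.numeric(x), as.numeric(y)),
                   tolerance = 1e-12, label = paste("n =", n))
    }
  }
})

test_that("tied data fall back to the corrected normal approximation", {
  cfg <- DmrTestConfig()
  x <- matrix(c(1, 2, 2, 3, 5, 6, 7, 8, 9), 1, dimnames = list("r1", NULL))
  y <- matrix(c(1, 2, 3, 3, 4, 4, 5, 5, 6), 1, dimnames = list("r1", NULL))
  ours <- discordanceWilcoxon(x, y, "r1", cfg)$wilcoxon_p
  ref <- suppressWarnings(wilcox.test(as.numeric(x), as.numeric(y),
                                      alternative = "greater",
                                      exact = FALSE)$p.value)
  expect_equal(ours, ref, tolerance = 1e-12)
})
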