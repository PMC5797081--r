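# Twin-design differential methylation: per-pair log fold changes, the
# (optionally moderated) one-sample test across discordant pairs, and the
# discordant-versus-concordant one-tailed Wilcoxon contrast.

# Newton inversion of the trigamma function (for the moment estimator of
# the prior degrees of freedom).
trigammaInverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

# Empirical-Bayes moment estimator: fit a scaled inverse-chi-square prior
# to the observed residual variances via the moments of log variances,
# then return posterior (shrunken) variances and the prior df.
squeezeVariances <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L)
    return(list(df_prior = 0, var_prior = NA_real_, var_post = s2))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigammaInverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
    var_post <- (df_prior * var_prior + df * s2) / (df_prior + df)
  } else {
    df_prior <- Inf
    var_prior <- exp(emean)
    var_post <- rep(var_prior, length(s2))
  }
  list(df_prior = df_prior, var_prior = var_prior, var_post = var_post)
}

#' Per-pair log2 fold changes of normalized counts
#'
#' For each discordant (MZD) pair, `logFC = log2((cpm_responder + pc) /
#' (cpm_nonresponder + pc))` per region, where the pseudocount `pc` is the
#' configured raw-count pseudocount rescaled to each sample's CPM units.
#' For concordant (MZC) pairs the two members are contrasted in
#' lexicographic sample-id order (the choice is immaterial downstream,
#' where only the absolute value is used).
#'
#' @param counts [MethylExperiment-class] or count matrix.
#' @param norm `NormalizationResult` from [tmmFactors()].
#' @param design data.frame with columns `sample` (or rownames), `group`,
#'   `pair_id`, `pair_type` (`"MZD"`/`"MZC"`); only needed when `counts`
#'   is a bare matrix.
#' @param cfg a [DmrTestConfig()].
#' @return list with matrices `mzd` and `mzc` (regions x pairs of logFC,
#'   pair ids as colnames).
#' @export
twinPairLogFC <- function(counts, norm, design = NULL,
                          cfg = DmrTestConfig()) {
  if (is(counts, "MethylExperiment") && is.null(design))
    design <- studyDesign(counts)
  counts <- .asCountMatrix(counts)
  if (is.null(design$sample)) design$sample <- rownames(design)
  cpmMat <- cpm(counts, norm)
  pc <- cfg$pseudocount / norm$effective_lib_size * 1e6
  oneType <- function(type) {
    d <- design[design$pair_type == type, , drop = FALSE]
    pairs <- sort(unique(d$pair_id))
    cols <- vapply(pairs, function(p) {
      m <- d[d$pair_id == p, , drop = FALSE]
      if (nrow(m) != 2L)
        stop("incomplete pair '", p, "': expected 2 members, got ", nrow(m))
      if (type == "MZD") {
        num <- m$sample[m$group == "responder"]
        den <- m$sample[m$group == "nonresponder"]
        if (length(num) != 1L || length(den) != 1L)
          stop("MZD pair '", p, "' must have one responder and one non-responder")
      } else {
        ord <- order(m$sample)
        num <- m$sample[ord[1L]]
        den <- m$sample[ord[2L]]
      }
      c(num, den)
    }, character(2))
    if (!length(pairs))
      return(matrix(numeric(), nrow(cpmMat), 0))
    lfc <- vapply(seq_along(pairs), function(k) {
      num <- cols[1, k]; den <- cols[2, k]
      log2((cpmMat[, num] + pc[num]) / (cpmMat[, den] + pc[den]))
    }, numeric(nrow(cpmMat)))
    lfc <- matrix(lfc, nrow = nrow(cpmMat),
                  dimnames = list(rownames(cpmMat), pairs))
    lfc
  }
  list(mzd = oneType("MZD"), mzc = oneType("MZC"))
}

#' Test per-region mean logFC across discordant pairs
#'
#' Intercept-only linear model on the per-pair logFCs of each region,
#' i.e. a one-sample test of mean logFC != 0 (two-sided). With
#' `moderation = "on"` region variances are shrunk toward a common prior
#' via the empirical-Bayes moment estimator (prior df and prior variance
#' fitted on log sample variances); the statistic then uses the posterior
#' variance with prior + residual degrees of freedom. Regions with zero
#' variance and zero mean get p = 1 by convention; zero variance with a
#' nonzero mean gives an infinite statistic and the smallest representable
#' positive p.
#'
#' @param logfc regions x MZD-pairs matrix from [twinPairLogFC()].
#' @param cfg a [DmrTestConfig()].
#' @return data.frame (one row per region): `region_id`, `logFC` (mean of
#'   pair logFCs), `statistic`, `p`, `direction` (`hyper`/`hypo` in the
#'   responder twin), `significant` (p < `p_threshold`).
#' @export
twinDmrTest <- function(logfc, cfg = DmrTestConfig()) {
  logfc <- as.matrix(logfc)
  n <- ncol(logfc)
  if (n < 2L) stop("need at least 2 pairs")
  m <- rowMeans(logfc)
  s2 <- rowSums((logfc - m)^2) / (n - 1)
  df <- n - 1
  if (cfg$moderation == "on") {
    sq <- squeezeVariances(s2, df)
    se <- sqrt(sq$var_post / n)
    dfTot <- df + sq$df_prior
  } else {
    se <- sqrt(s2 / n)
    dfTot <- df
  }
  stat <- m / se
  p <- 2 * stats::pt(-abs(stat), df = dfTot)
  zeroVar <- se == 0
  if (any(zeroVar)) {
    zm <- zeroVar & m == 0
    p[zm] <- 1; stat[zm] <- 0
    znz <- zeroVar & m != 0
    stat[znz] <- sign(m[znz]) * Inf
    p[znz] <- .Machine$double.xmin
  }
  data.frame(region_id = rownames(logfc), logFC = m, statistic = stat,
             p = p, direction = ifelse(m >= 0, "hyper", "hypo"),
             significant = p < cfg$p_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' One-tailed Wilcoxon contrast of absolute logFCs, MZD vs MZC
#'
#' For each candidate DMR, tests whether the absolute per-pair logFCs of
#' the discordant pairs are stochastically greater than those of the
#' concordant pairs (one-tailed rank-sum). The exact null distribution is
#' enumerated when both group sizes are at most 12 and there are no ties;
#' otherwise the normal approximation with tie correction (and continuity
#' correction) is used.
#'
#' @param absLogfcMzd,absLogfcMzc regions x pairs matrices of absolute
#'   logFC values sharing rownames.
#' @param dmrIds region ids to test (the p < `p_threshold` DMRs).
#' @param cfg a [DmrTestConfig()].
#' @return data.frame: `region_id`, `wilcoxon_p`, `retained`
#'   (p < `wilcoxon_alpha`).
#' @export
discordanceWilcoxon <- function(absLogfcMzd, absLogfcMzc, dmrIds,
                                cfg = DmrTestConfig()) {
  if (!all(dmrIds %in% rownames(absLogfcMzd)) ||
      !all(dmrIds %in% rownames(absLogfcMzc)))
    stop("dmrIds must be present in both logFC matrices")
  pv <- vapply(dmrIds, function(id) {
    x <- as.numeric(absLogfcMzd[id, ])
    y <- as.numeric(absLogfcMzc[id, ])
    ties <- anyDuplicated(c(x, y)) > 0
    useExact <- !ties && length(x) <= 12L && length(y) <= 12L
    suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                        exact = useExact,
                                        correct = TRUE)$p.value)
  }, numeric(1))
  data.frame(region_id = dmrIds, wilcoxon_p = unname(pv),
             retained = unname(pv) < cfg$wilcoxon_alpha,
             stringsAsFactors = FALSE)
}

#' Run the complete twin DMR analysis
#'
#' TMM normalization, per-pair logFCs, the across-pair test, and the
#' MZD-vs-MZC Wilcoxon stage, returning one merged table.
#'
#' @param me [MethylExperiment-class] with twin design columns
#'   (`group`, `pair_id`, `pair_type`).
#' @param cfg a [DmrTestConfig()].
#' @return list with `dmr` (the [twinDmrTest()] table plus `wilcoxon_p`
#'   and `retained` for significant regions), `norm`, and `logfc`.
#' @export
twinDmrPipeline <- function(me, cfg = DmrTestConfig()) {
  norm <- tmmFactors(me, cfg)
  lfc <- twinPairLogFC(me, norm, cfg = cfg)
  tab <- twinDmrTest(lfc$mzd, cfg)
  dmrIds <- tab$region_id[tab$significant]
  tab$wilcoxon_p <- NA_real_
  tab$retained <- FALSE
  if (length(dmrIds)) {
    wt <- discordanceWilcoxon(abs(lfc$mzd), abs(lfc$mzc), dmrIds, cfg)
    idx <- match(wt$region_id, tab$region_id)
    tab$wilcoxon_p[idx] <- wt$wilcoxon_p
    tab$retained[idx] <- wt$retained
  }
  list(dmr = tab, norm = norm, logfc = lfc)
}
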