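# Two-group animal differential methylation: negative binomial GLM with a
# log link, log effective-library-size offsets, an immunoprecipitation-pool
# nuisance factor, a single common dispersion, and a likelihood-ratio test
# of the group effect.

# Common NB dispersion by method of moments on Pearson residuals: find the
# alpha for which the Pearson statistic of per-region group+pool Poisson
# mean fits matches its residual degrees of freedom. Floored at 0.
estimateCommonDispersion <- function(counts, offsets, X) {
  nPar <- qr(X)$rank
  resDf <- ncol(counts) - nPar
  if (resDf <= 0) stop("no residual degrees of freedom")
  mus <- t(apply(counts, 1, function(y) {
    fit <- stats::glm.fit(X, y, family = stats::poisson(), offset = offsets)
    fit$fitted.values
  }))
  y <- counts
  pearson <- function(alpha)
    sum((y - mus)^2 / (mus + alpha * mus^2)) - nrow(counts) * resDf
  if (pearson(0) <= 0) return(0)
  upper <- 10
  while (pearson(upper) > 0 && upper < 1e4) upper <- upper * 10
  stats::uniroot(pearson, c(0, upper), tol = 1e-8)$root
}

#' Negative binomial GLM test for two-group animal DMRs
#'
#' For each (pre-filtered) region, fits a log-link negative binomial GLM
#' with offsets `log(effective library size)` and design
#' `~ group + ip_pool`, using a single common dispersion estimated across
#' regions by method of moments on Pearson residuals (floored at 0; the
#' Poisson limit). The group effect is tested by a likelihood-ratio
#' chi-square(1) of the full model against the pool-only model. IRLS runs
#' to convergence tolerance 1e-8, at most 100 iterations; non-converged
#' regions are flagged with `p = NA` and excluded from the significant set.
#'
#' @param counts count matrix restricted to filtered regions, or a
#'   [MethylExperiment-class].
#' @param norm `NormalizationResult` from [tmmFactors()] (computed on the
#'   full matrix before filtering).
#' @param design data.frame with columns `group` (levels `CT`, `RCF`;
#'   `CT` is the reference, so `logFC` is RCF vs CT) and `ip_pool`; taken
#'   from `colData` when `counts` is a `MethylExperiment`.
#' @param cfg a [DmrTestConfig()].
#' @return data.frame: `region_id`, `logFC` (log2, RCF vs CT),
#'   `statistic` (LRT chi-square), `p`, `direction`, `significant`,
#'   `converged`, plus attributes `dispersion` (the common alpha).
#' @export
mouseDmrGlm <- function(counts, norm, design = NULL, cfg = DmrTestConfig()) {
  if (is(counts, "MethylExperiment") && is.null(design))
    design <- studyDesign(counts)
  counts <- .asCountMatrix(counts)
  if (!identical(colnames(counts), names(norm$factors)))
    stop("sample sets of counts and normalization result differ")
  group <- factor(design$group, levels = c("CT", "RCF"))
  if (any(is.na(group))) stop("group must be CT or RCF")
  if (min(table(group)) < 2L) stop("need >= 2 samples per group")
  pool <- factor(design$ip_pool)
  offsets <- log(norm$effective_lib_size)
  if (nlevels(pool) > 1L) {
    X <- stats::model.matrix(~ group + pool)
    Xred <- stats::model.matrix(~ pool)
  } else {
    X <- stats::model.matrix(~ group)
    Xred <- stats::model.matrix(~ 1, data = data.frame(row.names = seq_along(group)))
  }
  alpha <- estimateCommonDispersion(counts, offsets, X)
  fam <- if (alpha <= 0) stats::poisson()
         else MASS::negative.binomial(theta = 1 / alpha)
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  groupCol <- which(colnames(X) == "groupRCF")
  res <- t(apply(counts, 1, function(y) {
    full <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = fam, offset = offsets,
                                      control = ctrl)),
      error = function(e) NULL)
    red <- tryCatch(
      suppressWarnings(stats::glm.fit(Xred, y, family = fam, offset = offsets,
                                      control = ctrl)),
      error = function(e) NULL)
    if (is.null(full) || is.null(red) || !full$converged || !red$converged)
      return(c(NA_real_, NA_real_, NA_real_, 0))
    lrt <- max(0, red$deviance - full$deviance)
    c(full$coefficients[groupCol] / log(2), lrt,
      stats::pchisq(lrt, df = 1, lower.tail = FALSE), 1)
  }))
  converged <- res[, 4] == 1
  if (any(!converged))
    logMsg(sum(!converged), " region(s) did not converge; excluded")
  out <- data.frame(region_id = rownames(counts), logFC = res[, 1],
                    statistic = res[, 2], p = res[, 3],
                    direction = ifelse(is.na(res[, 1]) | res[, 1] >= 0,
                                       "hyper", "hypo"),
                    significant = !is.na(res[, 3]) & res[, 3] < cfg$p_threshold,
                    converged = converged,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dispersion") <- alpha
  out
}

#' Run the complete animal DMR analysis
#'
#' TMM normalization on all regions, CPM filtering, then the NB GLM with
#' pool covariate on the retained regions.
#'
#' @param me [MethylExperiment-class] with `group` and `ip_pool` columns.
#' @param cfg a [DmrTestConfig()].
#' @return list with `dmr` (the [mouseDmrGlm()] table), `norm`, and
#'   `kept_regions`.
#' @export
mouseDmrPipeline <- function(me, cfg = DmrTestConfig()) {
  norm <- tmmFactors(me, cfg)
  cpmMat <- cpm(me, norm)
  keep <- filterRegions(cpmMat, cfg)
  counts <- methCounts(me)[keep, , drop = FALSE]
  tab <- mouseDmrGlm(counts, norm, studyDesign(me), cfg)
  list(dmr = tab, norm = norm, kept_regions = keep)
}
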