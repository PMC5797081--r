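# Between-library normalization for methylation peak counts: trimmed mean
# of M-values (TMM), counts per million, and the minimum-expression filter.

#' Configuration for DMR testing and normalization
#'
#' Bundles the tunable constants of the normalization and DMR stages. The
#' defaults follow the canonical TMM description (double trim 0.3 on
#' M-values and 0.05 on A-values, reference chosen by 75th-percentile
#' closeness) and the study design thresholds (p < 0.001 for DMRs, CPM > 1
#' in at least 5 samples, one-tailed Wilcoxon at 0.05).
#'
#' @param p_threshold DMR significance threshold on the raw p-value.
#' @param cpm_threshold CPM filter threshold (strict `>`).
#' @param min_samples_cpm minimum number of samples exceeding
#'   `cpm_threshold` for a region to be kept (the size of the smallest
#'   experimental group).
#' @param wilcoxon_alpha one-tailed Wilcoxon retention threshold.
#' @param logratio_trim trim fraction on M-values.
#' @param abs_expr_trim trim fraction on A-values.
#' @param pseudocount pseudocount (in raw count units, rescaled to CPM
#'   units where needed) protecting log fold changes against zeros.
#' @param moderation `"on"` for empirical-Bayes moderated variances in the
#'   twin test, `"off"` for the ordinary one-sample t-test.
#' @return A named list of class `DmrTestConfig`.
#' @export
DmrTestConfig <- function(p_threshold = 0.001, cpm_threshold = 1,
                          min_samples_cpm = 5, wilcoxon_alpha = 0.05,
                          logratio_trim = 0.3, abs_expr_trim = 0.05,
                          pseudocount = 0.5, moderation = c("on", "off")) {
  moderation <- match.arg(moderation)
  stopifnot(p_threshold > 0, p_threshold <= 1,
            cpm_threshold >= 0, min_samples_cpm >= 1,
            wilcoxon_alpha > 0, wilcoxon_alpha <= 1,
            logratio_trim >= 0, logratio_trim < 0.5,
            abs_expr_trim >= 0, abs_expr_trim < 0.5,
            pseudocount >= 0)
  structure(list(p_threshold = p_threshold, cpm_threshold = cpm_threshold,
                 min_samples_cpm = min_samples_cpm,
                 wilcoxon_alpha = wilcoxon_alpha,
                 logratio_trim = logratio_trim,
                 abs_expr_trim = abs_expr_trim,
                 pseudocount = pseudocount, moderation = moderation),
            class = "DmrTestConfig")
}

.asCountMatrix <- function(counts) {
  if (is(counts, "MethylExperiment")) counts <- methCounts(counts)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  counts
}

# Per-sample 75th-percentile of counts scaled by library size.
.factorQuantile <- function(counts, libSize, p = 0.75) {
  apply(counts, 2, function(x) stats::quantile(x, p = p)) / libSize
}

# Doubly trimmed, precision-weighted mean of M-values of one sample
# against the reference; the canonical TMM recipe.
.tmmPair <- function(obs, ref, libObs, libRef, logratioTrim, sumTrim) {
  obs <- as.numeric(obs); ref <- as.numeric(ref)
  logR <- log2((obs / libObs) / (ref / libRef))
  absE <- (log2(obs / libObs) + log2(ref / libRef)) / 2
  v <- (libObs - obs) / libObs / obs + (libRef - ref) / libRef / ref
  fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
  if (!any(fin)) return(NA_real_)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratioTrim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * sumTrim) + 1; hiS <- n + 1 - loS
  rl <- rank(logR); rs <- rank(absE)
  keep <- rl >= loL & rl <= hiL & rs >= loS & rs <= hiS
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (is.na(f)) f <- 0
  2^f
}

#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Computes per-sample scaling factors by the trimmed mean of M-values
#' method: the reference sample is the column whose 75th-percentile CPM is
#' closest to the mean of those percentiles; each sample's factor is the
#' precision-weighted mean of doubly trimmed log2 count ratios against the
#' reference (trim `logratio_trim` on M-values, `abs_expr_trim` on
#' A-values), over regions positive in both libraries; factors are rescaled
#' to geometric mean 1. Effective library size = library size x factor.
#'
#' @param counts count matrix (regions x samples) or
#'   [MethylExperiment-class]; at least 2 samples.
#' @param cfg a [DmrTestConfig()] (trim constants).
#' @return A list of class `NormalizationResult` with elements `factors`
#'   (named, geometric mean 1), `lib_size`, `effective_lib_size`, and
#'   `ref_sample`.
#' @export
tmmFactors <- function(counts, cfg = DmrTestConfig()) {
  counts <- .asCountMatrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  libSize <- colSums(counts)
  if (any(libSize <= 0)) stop("library sizes must be positive")
  if (!any(apply(counts > 0, 1, all)))
    stop("no region has positive counts in all samples")
  f75 <- .factorQuantile(counts, libSize)
  refIdx <- which.min(abs(f75 - mean(f75)))
  ref <- counts[, refIdx]
  factors <- vapply(seq_len(ncol(counts)), function(j) {
    shared <- counts[, j] > 0 & ref > 0
    if (!any(shared))
      stop("sample '", colnames(counts)[j],
           "' shares no positive region with the reference")
    .tmmPair(counts[, j], ref, libSize[j], libSize[refIdx],
             cfg$logratio_trim, cfg$abs_expr_trim)
  }, numeric(1))
  factors <- factors / exp(mean(log(factors)))
  names(factors) <- colnames(counts)
  structure(list(factors = factors, lib_size = libSize,
                 effective_lib_size = libSize * factors,
                 ref_sample = colnames(counts)[refIdx]),
            class = "NormalizationResult")
}

#' Counts per million against effective library sizes
#'
#' @param counts count matrix or [MethylExperiment-class].
#' @param norm a `NormalizationResult` from [tmmFactors()] matching the
#'   samples of `counts`.
#' @return numeric matrix: `counts / effective library size * 1e6`.
#' @export
cpm <- function(counts, norm) {
  counts <- .asCountMatrix(counts)
  if (!identical(colnames(counts), names(norm$factors)))
    stop("sample sets of counts and normalization result differ")
  sweep(counts, 2, norm$effective_lib_size, "/") * 1e6
}

#' Filter regions by minimum CPM support
#'
#' Keeps a region iff its CPM exceeds `cpm_threshold` (strictly) in at
#' least `min_samples_cpm` samples — the minimum-expression rule applied
#' before the animal GLM analysis.
#'
#' @param cpmMatrix matrix of CPM values from [cpm()].
#' @param cfg a [DmrTestConfig()].
#' @return character vector of retained region ids (rownames).
#' @export
filterRegions <- function(cpmMatrix, cfg = DmrTestConfig()) {
  keep <- rowSums(cpmMatrix > cfg$cpm_threshold) >= cfg$min_samples_cpm
  rownames(cpmMatrix)[keep]
}
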