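# Enrichment of DMRs in feature tracks (repeat classes, genomic features,
# CpG islands, chromatin states), per-cluster tissue/state z-score
# profiles, tissue assignment and grouping of ccDMRs.

#' Configuration for feature/state enrichment
#'
#' @param method `"fisher"` (2x2 table of DMR status x track overlap over
#'   the tested-region universe; the default) or
#'   `"placement_permutation"` (random draws of equally many regions from
#'   the universe).
#' @param n_placements random placements/draws for permutation nulls
#'   (default 1000, minimum 100).
#' @param activation_states chromatin states treated as activation marks
#'   when assigning tissues; defaults to the active-TSS, flanking-TSS,
#'   strong-transcription, enhancer and genic-enhancer states of the
#'   common 15-state model.
#' @param k_groups number of ccDMR groups to cut (default 4).
#' @param linkage agglomeration method for grouping (default
#'   `"average"`).
#' @param seed integer seed for placements.
#' @return A named list of class `EnrichConfig`.
#' @export
EnrichConfig <- function(method = c("fisher", "placement_permutation"),
                         n_placements = 1000,
                         activation_states = c("TssA", "TssFlnk", "Tx",
                                               "EnhG", "Enh"),
                         k_groups = 4, linkage = "average", seed = 1) {
  method <- match.arg(method)
  stopifnot(n_placements >= 100, length(activation_states) >= 1,
            k_groups >= 1)
  structure(list(method = method, n_placements = n_placements,
                 activation_states = activation_states,
                 k_groups = k_groups, linkage = linkage, seed = seed),
            class = "EnrichConfig")
}

#' Enrichment or depletion of DMRs in a feature track
#'
#' Fisher mode: 2x2 table of (DMR vs non-DMR region of the universe) x
#' (overlaps the track by >= 1 bp vs not); two-sided Fisher exact p; the
#' reported odds ratio is the sample odds ratio, > 1 meaning enrichment.
#' Permutation mode: observed number of DMRs overlapping the track versus
#' the same count for `n_placements` random draws of equally many regions
#' from the universe; z-score and two-sided empirical p.
#'
#' @param dmrIds character vector of DMR region ids, a subset of the
#'   universe's names.
#' @param universe [RegionSet-class] of all tested regions (named).
#' @param track [RegionSet-class] of the feature.
#' @param cfg an [EnrichConfig()].
#' @return list: `odds_ratio`, `p`, `label`
#'   (`"enriched"`/`"depleted"`/`"none"`), `table` (fisher mode) or
#'   `z`/`observed` (permutation mode). Degenerate tables give `p = 1`
#'   and `OR = NA`.
#' @export
dmrFeatureEnrichment <- function(dmrIds, universe, track,
                                 cfg = EnrichConfig()) {
  uniNames <- regionNames(universe)
  if (is.null(uniNames)) stop("universe must be named")
  if (!all(dmrIds %in% uniNames))
    stop("dmrIds must be a subset of the universe")
  h <- harmonizeSeqlevels(granges(universe, use.mcols = FALSE),
                          granges(track, use.mcols = FALSE))
  hitsTrack <- countOverlaps(h[[1L]], h[[2L]], ignore.strand = TRUE) > 0
  isDmr <- uniNames %in% dmrIds
  if (cfg$method == "fisher") {
    tab <- table(factor(isDmr, c(TRUE, FALSE)),
                 factor(hitsTrack, c(TRUE, FALSE)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      logMsg("degenerate 2x2 table for feature enrichment")
      return(list(odds_ratio = NA_real_, p = 1, label = "none", table = tab))
    }
    orHat <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    p <- stats::fisher.test(tab)$p.value
    label <- if (is.nan(orHat) || orHat == 1) "none"
             else if (orHat > 1) "enriched" else "depleted"
    list(odds_ratio = orHat, p = p, label = label, table = tab)
  } else {
    observed <- sum(hitsTrack & isDmr)
    nDmr <- sum(isDmr)
    set.seed(deriveSeed(cfg$seed, "feature_permutation"))
    null <- vapply(seq_len(cfg$n_placements), function(b)
      sum(hitsTrack[sample.int(length(uniNames), nDmr)]), numeric(1))
    sdNull <- stats::sd(null)
    if (!is.finite(sdNull) || sdNull == 0) {
      logMsg("constant permutation null; z undefined")
      return(list(odds_ratio = NA_real_, p = 1, label = "none",
                  z = NA_real_, observed = observed))
    }
    z <- (observed - mean(null)) / sdNull
    B <- cfg$n_placements
    pUp <- (1 + sum(null >= observed)) / (B + 1)
    pDn <- (1 + sum(null <= observed)) / (B + 1)
    p <- min(1, 2 * min(pUp, pDn))
    list(odds_ratio = NA_real_, p = p,
         label = if (z > 0) "enriched" else if (z < 0) "depleted" else "none",
         z = z, observed = observed)
  }
}

#' Enrichment of DMRs across a list of feature tracks
#'
#' @param dmrIds,universe,cfg as in [dmrFeatureEnrichment()].
#' @param tracks named list of [RegionSet-class] feature tracks.
#' @return data.frame: `feature`, `odds_ratio`, `p`, `label`.
#' @export
featureEnrichmentTable <- function(dmrIds, universe, tracks,
                                   cfg = EnrichConfig()) {
  rows <- lapply(names(tracks), function(nm) {
    r <- dmrFeatureEnrichment(dmrIds, universe, tracks[[nm]], cfg)
    data.frame(feature = nm, odds_ratio = r$odds_ratio, p = r$p,
               label = r$label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-cluster chromatin-state z-score profiles
#'
#' For every cluster and every (tissue, state) track, the observed overlap
#' fraction (overlapped bp / cluster span bp) is compared to a null built
#' from `n_placements` random placements of a length-matched interval
#' uniformly on the same chromosome. `z = (obs - mean_null) / sd_null`,
#' with `z = 0` when the null is constant. The same placements are reused
#' across tracks for a given cluster.
#'
#' @param ccdmrs a [ClusterSet-class].
#' @param stateTracks named list of [RegionSet-class] tracks, names
#'   `"<tissue>__<state>"`.
#' @param genome a [GenomeModel-class] covering the cluster chromosomes.
#' @param cfg an [EnrichConfig()].
#' @return matrix of z-scores, clusters x tracks, with an attribute
#'   `obs_frac` (observed overlap fractions).
#' @export
stateZscoreProfile <- function(ccdmrs, stateTracks, genome,
                               cfg = EnrichConfig()) {
  sp <- clusterSpans(ccdmrs)
  if (!length(sp)) stop("empty cluster set")
  chrom <- as.character(seqnames(sp))
  s0 <- start(sp) - 1L
  e0 <- end(sp)
  len <- e0 - s0
  cl <- chromLengths(genome)
  if (any(!chrom %in% names(cl)))
    stop("cluster chromosome absent from genome model")
  if (any(len > cl[chrom]))
    stop("cluster span exceeds chromosome length")
  covFunsList <- lapply(stateTracks, trackCoverageFuns)
  set.seed(deriveSeed(cfg$seed, "state_placements"))
  B <- cfg$n_placements
  placements <- lapply(seq_along(sp), function(i) {
    L <- cl[chrom[i]]
    floor(stats::runif(B, 0, L - len[i] + 1))
  })
  z <- matrix(0, length(sp), length(stateTracks),
              dimnames = list(mcols(sp)$id, names(stateTracks)))
  obsFrac <- z
  for (j in seq_along(stateTracks)) {
    covFuns <- covFunsList[[j]]
    for (i in seq_along(sp)) {
      obs <- overlapBpOnChrom(covFuns, chrom[i], s0[i], e0[i]) / len[i]
      ps <- placements[[i]]
      nullFrac <- overlapBpOnChrom(covFuns, chrom[i], ps, ps + len[i]) / len[i]
      sdN <- stats::sd(nullFrac)
      obsFrac[i, j] <- obs
      z[i, j] <- if (!is.finite(sdN) || sdN <= .Machine$double.eps) 0
                 else (obs - mean(nullFrac)) / sdN
    }
  }
  attr(z, "obs_frac") <- obsFrac
  z
}

#' Assign each cluster to its most activated tissue
#'
#' Per cluster, each tissue's score is the sum of z-scores over the
#' configured activation states; the assigned tissue is the argmax, ties
#' broken by the canonical (sorted) tissue order and flagged ambiguous.
#'
#' @param profile z-score matrix from [stateZscoreProfile()] with
#'   `"<tissue>__<state>"` column names.
#' @param cfg an [EnrichConfig()].
#' @return data.frame: `cluster_id`, `tissue`, `score`, `ambiguous`.
#' @export
assignTissue <- function(profile, cfg = EnrichConfig()) {
  parts <- strsplit(colnames(profile), "__", fixed = TRUE)
  tissue <- vapply(parts, `[[`, "", 1L)
  state <- vapply(parts, `[[`, "", 2L)
  bad <- setdiff(cfg$activation_states, unique(state))
  if (length(bad))
    stop("activation states not present in profile: ",
         paste(bad, collapse = ", "))
  act <- state %in% cfg$activation_states
  tissues <- sort(unique(tissue))
  scores <- vapply(tissues, function(tt)
    rowSums(profile[, act & tissue == tt, drop = FALSE]),
    numeric(nrow(profile)))
  scores <- matrix(scores, nrow = nrow(profile),
                   dimnames = list(rownames(profile), tissues))
  best <- apply(scores, 1, which.max)  # first maximum = canonical order
  nMax <- apply(scores, 1, function(r) sum(r == max(r)))
  data.frame(cluster_id = rownames(profile), tissue = tissues[best],
             score = scores[cbind(seq_len(nrow(scores)), best)],
             ambiguous = nMax > 1L, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Group ccDMRs by similarity of their state profiles
#'
#' Agglomerative clustering (Euclidean distance on the z-profiles, linkage
#' from the configuration) cut to exactly `k_groups` groups.
#'
#' @param profile z-score matrix from [stateZscoreProfile()].
#' @param cfg an [EnrichConfig()].
#' @return data.frame: `cluster_id`, `group` (1..k).
#' @export
groupClusters <- function(profile, cfg = EnrichConfig()) {
  if (nrow(profile) < cfg$k_groups)
    stop("fewer clusters (", nrow(profile), ") than k_groups (",
         cfg$k_groups, "); choose a smaller k")
  hc <- stats::hclust(stats::dist(profile), method = cfg$linkage)
  grp <- stats::cutree(hc, k = cfg$k_groups)
  data.frame(cluster_id = rownames(profile), group = unname(grp),
             stringsAsFactors = FALSE)
}
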