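# Seeded synthetic-data generator emulating the count structure of a
# MeDIP-seq methylome study: genomes, peak regions with planted spatially
# clustered DMRs, gene models with a planted GO term, feature and
# chromatin-state tracks, a cross-assembly block map, and negative
# binomial count matrices for a discordant-twin design and two-group
# animal designs with immunoprecipitation pools.

#' Configuration of the synthetic study
#'
#' Defaults mirror the emulated study design: 9 discordant (MZD) and 9
#' concordant (MZC) twin pairs; mouse groups of 6 CT / 10 RCF (F0) and
#' 5 CT / 7 RCF (F1) with 6 immunoprecipitation pools; planted DMR
#' clusters whose members lie within 10 kb of each other; an 81%/19%
#' hyper/hypo split of planted effect directions.
#'
#' @param seed integer; drives every random draw downstream.
#' @param n_chroms,chrom_length genome geometry (bp).
#' @param n_regions total number of methylation peak regions.
#' @param region_len_mean,region_len_sd peak length distribution (bp,
#'   truncated at 50).
#' @param n_mzd_pairs,n_mzc_pairs twin pairs per type.
#' @param mouse_group_sizes named counts for `F0_CT`, `F0_RCF`, `F1_CT`,
#'   `F1_RCF`.
#' @param n_pools immunoprecipitation pools (animals assigned
#'   round-robin).
#' @param pool_effect_sd sd (log2) of the per-pool, per-region
#'   multiplicative batch effect.
#' @param baseline_mean expected counts per region per sample.
#' @param nb_dispersion negative binomial dispersion `alpha`
#'   (`var = mu + alpha * mu^2`), one global value.
#' @param libsize_cv coefficient of variation of library-size factors.
#' @param planted_cluster_count,dmrs_per_cluster planted cluster geometry.
#' @param cluster_span maximum gap between consecutive planted DMRs (bp,
#'   <= 10000 so the clustering stage can recover them).
#' @param effect_log2fc magnitude of the planted log2 effect.
#' @param pair_effect_sd sd (log2) of the shared per-pair random effect
#'   (twin design).
#' @param frac_hyper fraction of planted effects that are positive
#'   (hypermethylated in responders / RCF).
#' @param n_genes background gene count (planted-term genes are added on
#'   top, one per planted cluster).
#' @param n_go_terms background GO terms.
#' @param planted_go_term id of the planted term.
#' @param planted_tissue tissue whose activation-state tracks are laid
#'   over the planted cluster spans.
#' @param n_state_tissues,n_states_per_tissue chromatin-state track grid
#'   (12 tissues x 15 states by default).
#' @param map_coverage fraction of the source genome covered by chain
#'   blocks.
#' @return A named list of class `SimulationConfig`.
#' @export
SimulationConfig <- function(seed = 1, n_chroms = 4, chrom_length = 3e7,
                             n_regions = 20000, region_len_mean = 500,
                             region_len_sd = 150, n_mzd_pairs = 9,
                             n_mzc_pairs = 9,
                             mouse_group_sizes = c(F0_CT = 6, F0_RCF = 10,
                                                   F1_CT = 5, F1_RCF = 7),
                             n_pools = 6, pool_effect_sd = 0.15,
                             baseline_mean = 50, nb_dispersion = 0.1,
                             libsize_cv = 0.2, planted_cluster_count = 60,
                             dmrs_per_cluster = 4, cluster_span = 10000,
                             effect_log2fc = 1.5, pair_effect_sd = 0.25,
                             frac_hyper = 0.81, n_genes = 2000,
                             n_go_terms = 50,
                             planted_go_term = "GO:SYNPLANT",
                             planted_tissue = "ESC", n_state_tissues = 12,
                             n_states_per_tissue = 15, map_coverage = 0.5) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_length > 0, cfg$n_regions >= 1,
            cfg$n_mzd_pairs >= 2, cfg$n_mzc_pairs >= 0,
            all(cfg$mouse_group_sizes >= 2), cfg$n_pools >= 1,
            cfg$baseline_mean > 0, cfg$nb_dispersion >= 0,
            cfg$libsize_cv >= 0, cfg$planted_cluster_count >= 0,
            cfg$dmrs_per_cluster >= 1, cfg$cluster_span > 0,
            cfg$cluster_span <= 10000,
            cfg$frac_hyper >= 0, cfg$frac_hyper <= 1,
            cfg$map_coverage >= 0, cfg$map_coverage <= 1,
            cfg$n_state_tissues >= 1, cfg$n_states_per_tissue >= 1)
  structure(cfg, class = "SimulationConfig")
}

.tissueNames <- c("ESC", "Brain", "Blood", "Liver", "Heart", "Lung",
                  "Kidney", "Muscle", "Skin", "Gut", "Thymus", "Spleen")
.stateNames <- c("TssA", "TssFlnk", "TxFlnk", "Tx", "TxWk", "EnhG", "Enh",
                 "ZNF_Rpts", "Het", "TssBiv", "BivFlnk", "EnhBiv",
                 "ReprPC", "ReprPCWk", "Quies")

# Coalesce overlapping/bookended intervals in plain vectors (0-based
# half-open); cheap path for track generation, where building and
# re-validating S4 containers per track would dominate the run time.
.coalesce <- function(chrom, start, end) {
  o <- order(chrom, start, end)
  chrom <- chrom[o]; start <- start[o]; end <- end[o]
  n <- length(start)
  if (n <= 1L)
    return(data.frame(chrom = chrom, start = start, end = end))
  grp <- integer(n); g <- 0L
  runmax <- -Inf
  for (i in seq_len(n)) {
    if (i == 1L || chrom[i] != chrom[i - 1L] || start[i] > runmax) {
      g <- g + 1L
      runmax <- end[i]
    } else runmax <- max(runmax, end[i])
    grp[i] <- g
  }
  data.frame(chrom = chrom[!duplicated(grp)],
             start = tapply(start, grp, min)[as.character(unique(grp))],
             end = tapply(end, grp, max)[as.character(unique(grp))],
             row.names = NULL)
}

# Random interval track covering roughly `coverage` of the genome.
.randomTrack <- function(genome, coverage, meanLen, assemblyLabel) {
  cl <- chromLengths(genome)
  total <- sum(cl)
  nIv <- max(1L, round(coverage * total / meanLen))
  chrom <- sample(names(cl), nIv, replace = TRUE, prob = cl / total)
  len <- pmax(100, round(stats::rexp(nIv, 1 / meanLen)))
  len <- pmin(len, cl[chrom] - 1)
  st <- floor(stats::runif(nIv, 0, cl[chrom] - len))
  m <- .coalesce(chrom, st, st + len)
  RegionSet(m$chrom, m$start, m$end, assemblyLabel)
}

#' Simulate a genome, annotations, tracks, chain map and planted truth
#'
#' Lays out `n_regions` non-overlapping methylation peak regions across
#' the chromosomes, embedding `planted_cluster_count` clusters of
#' `dmrs_per_cluster` peaks whose consecutive gaps are below 10 kb while
#' the gaps to flanking background peaks exceed 10 kb (so the planted
#' clusters are exactly recoverable at the clustering stage's default
#' radius). Gene models, a flat GO map with one planted term whose genes
#' sit within 100 kb of the planted cluster spans (one per cluster),
#' repeat/feature tracks, a tissue-by-state chromatin track grid with the
#' planted tissue's activation states laid over the planted spans, and a
#' monotone cross-assembly block map covering `map_coverage` of the
#' genome are generated alongside. Identical configurations (and seeds)
#' give identical output.
#'
#' @param config a [SimulationConfig()].
#' @return list with elements `genome`, `dst_genome`, `peaks`, `genes`,
#'   `go_map` (data.frame `term`, `gene`, `ontology`, `name`),
#'   `feature_tracks`, `state_tracks` (named lists of
#'   [RegionSet-class]), `chain` (a [ChainMap-class]) and `truth`
#'   (planted DMR ids with true log2 fold changes, planted cluster spans,
#'   planted GO term).
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  asm <- "synthA"; dstAsm <- "synthB"
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  genome <- GenomeModel(asm, stats::setNames(rep(cfg$chrom_length,
                                                 cfg$n_chroms), chroms))
  # feasibility before sampling: mean footprint must fit comfortably
  perChrom <- ceiling(cfg$n_regions / cfg$n_chroms)
  meanGap <- 2500
  if (perChrom * (cfg$region_len_mean + meanGap) > 0.95 * cfg$chrom_length)
    stop("infeasible geometry: ", cfg$n_regions, " regions of mean length ",
         cfg$region_len_mean, " cannot fit ", cfg$n_chroms,
         " chromosome(s) of ", cfg$chrom_length, " bp")
  nPlanted <- cfg$planted_cluster_count * cfg$dmrs_per_cluster
  if (nPlanted > cfg$n_regions)
    stop("more planted DMRs than regions")
  set.seed(deriveSeed(cfg$seed, "genome"))
  # distribute regions and planted clusters across chromosomes
  nPerChrom <- diff(round(seq(0, cfg$n_regions, length.out = cfg$n_chroms + 1)))
  clChrom <- rep(seq_len(cfg$n_chroms),
                 length.out = cfg$planted_cluster_count)
  chromTab <- vector("list", cfg$n_chroms)
  plantedSpans <- list()
  flankGap <- function(n) 10001 + floor(stats::rexp(n, 1 / 5000))
  intraGapMax <- min(cfg$cluster_span, 9999)
  for (ci in seq_len(cfg$n_chroms)) {
    nCl <- sum(clChrom == ci)
    nBg <- nPerChrom[ci] - nCl * cfg$dmrs_per_cluster
    if (nBg < 0) stop("infeasible geometry: planted clusters exceed regions")
    # unit sequence: background peaks (0) and planted clusters (1..nCl)
    units <- c(rep(0L, nBg), seq_len(nCl))
    units <- units[sample.int(length(units))]
    # expand to peak-level records
    peakUnit <- rep(units, ifelse(units == 0L, 1L, cfg$dmrs_per_cluster))
    n <- length(peakUnit)
    if (n == 0L) { chromTab[ci] <- list(NULL); next }
    isPlanted <- peakUnit > 0L
    isClusterStart <- isPlanted & c(TRUE, peakUnit[-n] != peakUnit[-1L])
    isClusterEnd <- isPlanted & c(peakUnit[-n] != peakUnit[-1L], TRUE)
    prevIsClusterEnd <- c(FALSE, isClusterEnd[-n])
    needFlank <- isClusterStart | prevIsClusterEnd
    gap <- numeric(n)
    gap[needFlank] <- flankGap(sum(needFlank))
    intra <- isPlanted & !isClusterStart
    gap[intra] <- floor(stats::runif(sum(intra), 200, intraGapMax))
    bgGapIdx <- !needFlank & !intra
    gap[bgGapIdx] <- round(stats::rlnorm(sum(bgGapIdx), log(2000), 1))
    len <- pmax(50, round(stats::rnorm(n, cfg$region_len_mean,
                                       cfg$region_len_sd)))
    starts <- floor(stats::runif(1, 0, 5000)) + cumsum(gap) +
      c(0, cumsum(len)[-n])
    ends <- starts + len
    if (max(ends) > cfg$chrom_length)
      stop("infeasible geometry: layout overflows ", chroms[ci])
    for (k in seq_len(nCl)) {
      ix <- which(peakUnit == k)
      plantedSpans[[length(plantedSpans) + 1L]] <-
        data.frame(chrom = chroms[ci], start = starts[ix[1L]],
                   end = ends[ix[length(ix)]])
    }
    chromTab[[ci]] <- data.frame(chrom = chroms[ci], start = starts,
                                 end = ends, planted = isPlanted)
  }
  peaksDf <- do.call(rbind, chromTab)
  o <- order(peaksDf$chrom, peaksDf$start)
  peaksDf <- peaksDf[o, ]
  peaksDf$name <- sprintf("peak_%06d", seq_len(nrow(peaksDf)))
  peaks <- RegionSet(peaksDf$chrom, peaksDf$start, peaksDf$end, asm,
                     name = peaksDf$name, genome = genome)
  plantedIds <- peaksDf$name[peaksDf$planted]
  # planted effect signs: frac_hyper positive
  sgn <- ifelse(stats::runif(length(plantedIds)) < cfg$frac_hyper, 1, -1)
  plantedDmrs <- data.frame(region_id = plantedIds,
                            log2fc = sgn * cfg$effect_log2fc,
                            stringsAsFactors = FALSE)
  spansDf <- do.call(rbind, plantedSpans)
  if (is.null(spansDf))
    spansDf <- data.frame(chrom = character(), start = numeric(),
                          end = numeric())
  spansDf <- spansDf[order(spansDf$chrom, spansDf$start), , drop = FALSE]
  if (nrow(spansDf))
    spansDf$cluster <- sprintf("planted_%03d", seq_len(nrow(spansDf)))
  # genes: background + one planted-term gene near each planted span
  gChrom <- sample(chroms, cfg$n_genes, replace = TRUE)
  gLen <- round(stats::runif(cfg$n_genes, 2000, 20000))
  gStart <- floor(stats::runif(cfg$n_genes, 0, cfg$chrom_length - gLen))
  geneDf <- data.frame(chrom = gChrom, start = gStart, end = gStart + gLen,
                       stringsAsFactors = FALSE)
  plantedGenes <- character(0)
  if (nrow(spansDf)) {
    pgLen <- round(stats::runif(nrow(spansDf), 2000, 10000))
    pgStart <- pmin(spansDf$end + round(stats::runif(nrow(spansDf),
                                                     1000, 50000)),
                    cfg$chrom_length - pgLen)
    geneDf <- rbind(geneDf,
                    data.frame(chrom = spansDf$chrom, start = pgStart,
                               end = pgStart + pgLen,
                               stringsAsFactors = FALSE))
    plantedGenes <- sprintf("gene_%05d",
                            cfg$n_genes + seq_len(nrow(spansDf)))
  }
  geneDf$name <- sprintf("gene_%05d", seq_len(nrow(geneDf)))
  genes <- RegionSet(geneDf$chrom, geneDf$start, geneDf$end, asm,
                     name = geneDf$name, genome = genome)
  # flat GO map: background terms over background genes + the planted term
  bgGenes <- geneDf$name[seq_len(cfg$n_genes)]
  goRows <- lapply(seq_len(cfg$n_go_terms), function(t) {
    sz <- sample(5:40, 1L)
    data.frame(term = sprintf("GO:SYN%04d", t),
               gene = sample(bgGenes, sz),
               stringsAsFactors = FALSE)
  })
  goDf <- do.call(rbind, goRows)
  if (length(plantedGenes))
    goDf <- rbind(goDf, data.frame(term = cfg$planted_go_term,
                                   gene = plantedGenes,
                                   stringsAsFactors = FALSE))
  goDf$ontology <- "BP"
  goDf$name <- paste0("synthetic term ", goDf$term)
  # feature tracks
  featureNames <- c("LTR", "LINE", "SINE", "satellite", "simple_repeat",
                    "low_complexity", "exon", "intron", "TSS_flank",
                    "CpG_island")
  featureTracks <- stats::setNames(lapply(featureNames, function(nm)
    .randomTrack(genome, 0.03, 3000, asm)), featureNames)
  # chromatin state tracks: tissue x state grid
  tissues <- rep_len(.tissueNames, cfg$n_state_tissues)
  states <- rep_len(.stateNames, cfg$n_states_per_tissue)
  stateTracks <- list()
  activation <- c("TssA", "TssFlnk", "Tx", "EnhG", "Enh")
  for (tt in tissues) for (ss in states) {
    tr <- .randomTrack(genome, 0.02, 4000, asm)
    if (tt == cfg$planted_tissue && ss %in% activation && nrow(spansDf)) {
      planted <- RegionSet(spansDf$chrom, spansDf$start, spansDf$end, asm)
      tr <- mergeRegions(tr, planted)
    }
    stateTracks[[paste0(tt, "__", ss)]] <- tr
  }
  # destination genome + monotone chain blocks
  dstGenome <- GenomeModel(dstAsm,
    stats::setNames(rep(round(cfg$chrom_length * 1.5), cfg$n_chroms),
                    chroms))
  blocks <- list()
  if (cfg$map_coverage > 0) {
    for (ci in seq_len(cfg$n_chroms)) {
      srcCur <- floor(stats::runif(1, 0, 20000))
      dstCur <- floor(stats::runif(1, 0, 20000))
      meanLenB <- 20000
      meanGapB <- meanLenB * (1 / cfg$map_coverage - 1)
      while (TRUE) {
        len <- round(stats::runif(1, 5000, 2 * meanLenB - 5000))
        if (srcCur + len > cfg$chrom_length ||
            dstCur + len > chromLengths(dstGenome)[ci]) break
        blocks[[length(blocks) + 1L]] <-
          data.frame(src_chrom = chroms[ci], src_start = srcCur,
                     src_end = srcCur + len, dst_chrom = chroms[ci],
                     dst_start = dstCur, dst_end = dstCur + len,
                     stringsAsFactors = FALSE)
        srcGap <- if (meanGapB > 0) round(stats::rexp(1, 1 / meanGapB)) else 0
        dstGap <- srcGap + round(stats::rexp(1, 1 / 2000))
        srcCur <- srcCur + len + srcGap
        dstCur <- dstCur + len + dstGap
      }
    }
  }
  blocksDf <- if (length(blocks)) do.call(rbind, blocks)
              else data.frame(src_chrom = character(), src_start = numeric(),
                              src_end = numeric(), dst_chrom = character(),
                              dst_start = numeric(), dst_end = numeric())
  chain <- ChainMap(blocksDf, asm, dstAsm, minMatch = 0.1)
  truth <- list(planted_dmrs = plantedDmrs,
                planted_cluster_spans = spansDf,
                planted_go_term = cfg$planted_go_term,
                planted_genes = plantedGenes,
                planted_tissue = cfg$planted_tissue)
  list(genome = genome, dst_genome = dstGenome, peaks = peaks,
       genes = genes, go_map = goDf, feature_tracks = featureTracks,
       state_tracks = stateTracks, chain = chain, truth = truth)
}

.lognormFactors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, -sdl^2 / 2, sdl)
}

.drawCounts <- function(mu, alpha) {
  n <- length(mu)
  if (alpha <= 0) stats::rpois(n, mu)
  else stats::rnbinom(n, size = 1 / alpha, mu = mu)
}

#' Simulate a count matrix for one experimental design
#'
#' Counts are negative binomial with `var = mu + alpha * mu^2` and
#' `log2 mu = log2(baseline) + random effect + group effect on planted
#' DMRs + log2(library factor)`. The twin design emits paired
#' responder/non-responder columns sharing a per-pair random effect (MZC
#' pairs are a true null: both members share identical expected values);
#' the mouse designs assign animals round-robin to `n_pools`
#' immunoprecipitation pools with a per-pool, per-region multiplicative
#' effect.
#'
#' @param config a [SimulationConfig()].
#' @param designKind `"twin"`, `"mouse_F0"` or `"mouse_F1"`.
#' @param sim output of [simulateGenome()] run on the same configuration
#'   (supplies peaks and planted truth).
#' @param effectLog2fc optional override of the planted effect magnitude
#'   (signs are kept from the truth); `NULL` uses the truth values.
#' @return A [MethylExperiment-class]; `colData` carries the design plus
#'   the true library-size factors (`true_sf`).
#' @export
simulateCounts <- function(config, designKind = c("twin", "mouse_F0",
                                                  "mouse_F1"),
                           sim, effectLog2fc = NULL) {
  designKind <- match.arg(designKind)
  cfg <- config
  peaks <- sim$peaks
  truth <- sim$truth
  ids <- regionNames(peaks)
  nReg <- length(ids)
  set.seed(deriveSeed(cfg$seed, paste0("counts_", designKind)))
  baseline <- stats::rgamma(nReg, shape = 4, rate = 4 / cfg$baseline_mean)
  plantedIdx <- match(truth$planted_dmrs$region_id, ids)
  lfc <- truth$planted_dmrs$log2fc
  if (!is.null(effectLog2fc)) lfc <- sign(lfc) * effectLog2fc
  alpha <- cfg$nb_dispersion
  if (designKind == "twin") {
    nPairs <- cfg$n_mzd_pairs + cfg$n_mzc_pairs
    pairIds <- c(sprintf("MZD%02d", seq_len(cfg$n_mzd_pairs)),
                 sprintf("MZC%02d", seq_len(cfg$n_mzc_pairs)))
    pairType <- rep(c("MZD", "MZC"), c(cfg$n_mzd_pairs, cfg$n_mzc_pairs))
    samples <- as.vector(t(cbind(paste0(pairIds, "_1"),
                                 paste0(pairIds, "_2"))))
    sf <- .lognormFactors(length(samples), cfg$libsize_cv)
    names(sf) <- samples
    counts <- matrix(0L, nReg, length(samples),
                     dimnames = list(ids, samples))
    for (k in seq_len(nPairs)) {
      pairEff <- 2^stats::rnorm(nReg, 0, cfg$pair_effect_sd)
      muBase <- baseline * pairEff
      mu1 <- muBase  # member 1: responder (MZD) or first member (MZC)
      if (pairType[k] == "MZD" && length(plantedIdx))
        mu1[plantedIdx] <- mu1[plantedIdx] * 2^lfc
      s1 <- samples[2 * k - 1]; s2 <- samples[2 * k]
      counts[, s1] <- .drawCounts(mu1 * sf[s1], alpha)
      counts[, s2] <- .drawCounts(muBase * sf[s2], alpha)
    }
    design <- data.frame(
      sample = samples, organism = "human",
      group = rep(c("responder", "nonresponder"), nPairs),
      pair_id = rep(pairIds, each = 2),
      pair_type = rep(pairType, each = 2),
      ip_pool = NA_character_, generation = NA_character_,
      true_sf = unname(sf), stringsAsFactors = FALSE)
    design$group[design$pair_type == "MZC"] <- "nonresponder"
  } else {
    gen <- if (designKind == "mouse_F0") "F0" else "F1"
    nCT <- cfg$mouse_group_sizes[[paste0(gen, "_CT")]]
    nRCF <- cfg$mouse_group_sizes[[paste0(gen, "_RCF")]]
    samples <- c(sprintf("%s_CT_%02d", gen, seq_len(nCT)),
                 sprintf("%s_RCF_%02d", gen, seq_len(nRCF)))
    group <- rep(c("CT", "RCF"), c(nCT, nRCF))
    pools <- sprintf("pool_%d",
                     ((seq_along(samples) - 1L) %% cfg$n_pools) + 1L)
    sf <- .lognormFactors(length(samples), cfg$libsize_cv)
    names(sf) <- samples
    nPoolLevels <- length(unique(pools))
    poolEff <- matrix(2^stats::rnorm(nReg * nPoolLevels, 0,
                                     cfg$pool_effect_sd),
                      nReg, nPoolLevels,
                      dimnames = list(NULL, unique(pools)))
    counts <- matrix(0L, nReg, length(samples),
                     dimnames = list(ids, samples))
    for (j in seq_along(samples)) {
      mu <- baseline * poolEff[, pools[j]]
      if (group[j] == "RCF" && length(plantedIdx))
        mu[plantedIdx] <- mu[plantedIdx] * 2^lfc
      counts[, j] <- .drawCounts(mu * sf[j], alpha)
    }
    design <- data.frame(
      sample = samples, organism = "mouse", group = group,
      pair_id = NA_character_, pair_type = NA_character_,
      ip_pool = pools, generation = gen, true_sf = unname(sf),
      stringsAsFactors = FALSE)
  }
  me <- MethylExperiment(counts, design, peaks)
  colnames(me) <- design$sample
  me
}

#' Write a simulated bundle to disk
#'
#' Emits `peaks.bed`, `genes.bed`, `go_map.tsv`, `chain_map.tsv`,
#' `truth.json`, `tracks/<name>.bed`, and for each requested design
#' `counts_<kind>.tsv` plus `design_<kind>.tsv`. All writers are
#' deterministic, so identical configurations produce byte-identical
#' files.
#'
#' @param sim output of [simulateGenome()].
#' @param dir output directory (created if needed).
#' @param experiments list of [MethylExperiment-class] objects named by
#'   design kind, e.g. from [simulateCounts()].
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir, experiments = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "tracks"), showWarnings = FALSE)
  writeBed(sim$peaks, file.path(dir, "peaks.bed"))
  writeBed(sim$genes, file.path(dir, "genes.bed"))
  writeTsv(sim$go_map, file.path(dir, "go_map.tsv"))
  writeTsv(chainBlocks(sim$chain), file.path(dir, "chain_map.tsv"),
           coordComment = TRUE)
  for (nm in names(sim$feature_tracks))
    writeBed(sim$feature_tracks[[nm]],
             file.path(dir, "tracks", paste0(nm, ".bed")))
  for (nm in names(sim$state_tracks))
    writeBed(sim$state_tracks[[nm]],
             file.path(dir, "tracks", paste0(nm, ".bed")))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (nm in names(experiments)) {
    me <- experiments[[nm]]
    writeCountsTsv(methCounts(me), file.path(dir, paste0("counts_", nm,
                                                         ".tsv")))
    writeTsv(studyDesign(me), file.path(dir, paste0("design_", nm, ".tsv")))
  }
  invisible(dir)
}
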