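# Cross-species cluster conservation: lift regions through a simplified
# block map with the minimum-mapped-fraction rule, intersect with the
# other species' ccDMRs, and attach a placement-permutation p-value to the
# conserved-cluster count.

#' Read a chain-like block map from TSV
#'
#' Expects the six columns `src_chrom`, `src_start`, `src_end`,
#' `dst_chrom`, `dst_start`, `dst_end` (0-based half-open).
#'
#' @param path TSV path.
#' @param srcAssembly,dstAssembly assembly labels.
#' @param minMatch minimum mapped fraction (default 0.1).
#' @return A [ChainMap-class].
#' @export
readChainMap <- function(path, srcAssembly, dstAssembly, minMatch = 0.1) {
  ChainMap(readTsv(path), srcAssembly, dstAssembly, minMatch)
}

#' Lift regions to another assembly through a block map
#'
#' For each region, the bases covered by source blocks are counted; if the
#' covered fraction is below `minMatch` the region is unmapped. Otherwise
#' the destination interval is the `[min, max)` hull of the images of the
#' mapped bases, required to land on one destination chromosome (else
#' unmapped with reason `"split"`). Regions on chromosomes without any
#' block are unmapped with reason `"no_chain"`.
#'
#' @param regions a named [RegionSet-class] on the chain's source
#'   assembly.
#' @param chain a [ChainMap-class].
#' @return list with `mapped` (a [RegionSet-class] on the destination
#'   assembly, names preserved) and `unmapped` (data.frame `region_id`,
#'   `reason`).
#' @export
liftover <- function(regions, chain) {
  stopifnot(is(regions, "RegionSet"), is(chain, "ChainMap"))
  if (assembly(regions) != chain@srcAssembly)
    stop("regions are on ", assembly(regions), ", chain maps from ",
         chain@srcAssembly)
  b <- chain@blocks
  gr <- granges(regions, use.mcols = FALSE)
  ids <- regionNames(regions)
  if (is.null(ids)) ids <- paste0("region_", seq_along(gr))
  chrom <- as.character(seqnames(gr))
  s0 <- start(gr) - 1L; e0 <- end(gr)
  byChrom <- split(seq_len(nrow(b)), b$src_chrom)
  outChrom <- character(0); outStart <- numeric(0); outEnd <- numeric(0)
  outName <- character(0)
  unmapped <- data.frame(region_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  drop <- function(id, reason)
    unmapped <<- rbind(unmapped,
                       data.frame(region_id = id, reason = reason,
                                  stringsAsFactors = FALSE))
  for (i in seq_along(gr)) {
    rows <- byChrom[[chrom[i]]]
    if (is.null(rows)) { drop(ids[i], "no_chain"); next }
    bb <- b[rows, , drop = FALSE]
    ovS <- pmax(bb$src_start, s0[i])
    ovE <- pmin(bb$src_end, e0[i])
    hit <- ovE > ovS
    mapped <- sum(pmax(0, ovE - ovS))
    if (mapped / (e0[i] - s0[i]) < chain@minMatch) {
      drop(ids[i], if (mapped == 0 && !any(hit)) "below_min_match"
                   else "below_min_match")
      next
    }
    bb <- bb[hit, , drop = FALSE]
    ovS <- ovS[hit]; ovE <- ovE[hit]
    if (length(unique(bb$dst_chrom)) != 1L) { drop(ids[i], "split"); next }
    imgS <- bb$dst_start + (ovS - bb$src_start)
    imgE <- bb$dst_start + (ovE - bb$src_start)
    outChrom <- c(outChrom, bb$dst_chrom[1L])
    outStart <- c(outStart, min(imgS))
    outEnd <- c(outEnd, max(imgE))
    outName <- c(outName, ids[i])
  }
  mappedSet <- RegionSet(outChrom, outStart, outEnd, chain@dstAssembly,
                         name = outName)
  list(mapped = mappedSet, unmapped = unmapped)
}

#' Conserved clusters between mapped and native ccDMRs
#'
#' Intersects the lifted clusters of one species with the ccDMR spans of
#' the other (>= 1 bp, `intersectBed` semantics). The number of conserved
#' regions is the number of distinct intersection intervals; one lifted
#' cluster overlapping several native clusters therefore yields several
#' conserved regions but one hit.
#'
#' @param humanMapped a named [RegionSet-class] of lifted cluster spans on
#'   the destination assembly.
#' @param mouseCcdmrs a [ClusterSet-class] or [RegionSet-class] of native
#'   ccDMR spans on the same assembly.
#' @return list: `pairs` (data.frame `human_id`, `mouse_id`,
#'   `overlap_bp`), `n_conserved`, `n_human_ccdmrs_hit`.
#' @export
conservedClusters <- function(humanMapped, mouseCcdmrs) {
  if (is(mouseCcdmrs, "ClusterSet"))
    mouseCcdmrs <- clustersAsRegionSet(mouseCcdmrs)
  if (assembly(humanMapped) != assembly(mouseCcdmrs))
    stop("assembly mismatch: ", assembly(humanMapped), " vs ",
         assembly(mouseCcdmrs))
  oj <- overlapJoin(humanMapped, mouseCcdmrs, minFracA = 0)
  pairs <- data.frame(human_id = oj$a_name, mouse_id = oj$b_name,
                      overlap_bp = oj$overlap_bp, stringsAsFactors = FALSE)
  list(pairs = pairs, n_conserved = nrow(pairs),
       n_human_ccdmrs_hit = length(unique(pairs$human_id)))
}

#' Placement-permutation p-value for the conserved-cluster count
#'
#' Null: each lifted cluster is relocated uniformly at random on its own
#' chromosome (length preserved) and the conserved-region count is
#' recomputed; `p = (1 + #\{null >= observed\}) / (B + 1)`, one-sided for
#' excess overlap.
#'
#' @param humanMapped named [RegionSet-class] of lifted cluster spans.
#' @param mouseCcdmrs [ClusterSet-class] or [RegionSet-class] of native
#'   ccDMR spans.
#' @param genome [GenomeModel-class] of the destination assembly.
#' @param B number of permutations (>= 100).
#' @param seed integer seed.
#' @return list: `p`, `observed`, `null` (vector of null counts), `B`,
#'   `seed`.
#' @export
overlapPermutationP <- function(humanMapped, mouseCcdmrs, genome, B = 999,
                                seed = 1) {
  stopifnot(B >= 100)
  if (is(mouseCcdmrs, "ClusterSet"))
    mouseCcdmrs <- clustersAsRegionSet(mouseCcdmrs)
  observed <- conservedClusters(humanMapped, mouseCcdmrs)$n_conserved
  gr <- granges(humanMapped, use.mcols = FALSE)
  chrom <- as.character(seqnames(gr))
  len <- width(gr)
  cl <- chromLengths(genome)
  if (any(!chrom %in% names(cl)))
    stop("cluster chromosome absent from genome model")
  if (any(len > cl[chrom]))
    stop("cluster longer than its chromosome")
  gm <- granges(mouseCcdmrs, use.mcols = FALSE)
  set.seed(deriveSeed(seed, "conserved_permutation"))
  # all B draws in one overlap query: placements are independent uniform
  # starts per cluster per draw, indexed by draw
  n <- length(gr)
  st0 <- floor(stats::runif(B * n, 0, rep(cl[chrom] - len + 1, B)))
  placed <- GRanges(factor(rep(chrom, B), levels = sort(unique(chrom))),
                    IRanges(st0 + 1, st0 + rep(len, B)))
  h <- harmonizeSeqlevels(placed, gm)
  hits <- findOverlaps(h[[1L]], h[[2L]], ignore.strand = TRUE)
  drawIdx <- (S4Vectors::queryHits(hits) - 1L) %/% n + 1L
  nullCounts <- tabulate(drawIdx, nbins = B)
  list(p = (1 + sum(nullCounts >= observed)) / (B + 1),
       observed = observed, null = nullCounts, B = B, seed = seed)
}

#' Run the cross-species conservation analysis
#'
#' Lifts the source-species ccDMR spans through the chain, intersects with
#' the destination-species ccDMRs, and attaches the permutation p-value.
#'
#' @param srcCcdmrs [ClusterSet-class] (or named [RegionSet-class]) on the
#'   chain's source assembly; alternatively supply `preMapped` to skip the
#'   lift-over.
#' @param chain a [ChainMap-class] (ignored when `preMapped` is given).
#' @param dstCcdmrs [ClusterSet-class] or [RegionSet-class] on the
#'   destination assembly.
#' @param dstGenome [GenomeModel-class] of the destination assembly.
#' @param B,seed permutation settings, see [overlapPermutationP()].
#' @param preMapped optional pre-mapped [RegionSet-class] (e.g. real
#'   lift-over output read with [readBed()]).
#' @return list: `mapped`, `unmapped`, `pairs`, `n_conserved`,
#'   `n_human_ccdmrs_hit`, `p`, `B`, `seed`.
#' @export
runCrossSpecies <- function(srcCcdmrs, chain, dstCcdmrs, dstGenome,
                            B = 999, seed = 1, preMapped = NULL) {
  if (is.null(preMapped)) {
    if (is(srcCcdmrs, "ClusterSet"))
      srcCcdmrs <- clustersAsRegionSet(srcCcdmrs)
    lift <- liftover(srcCcdmrs, chain)
  } else {
    lift <- list(mapped = preMapped,
                 unmapped = data.frame(region_id = character(),
                                       reason = character()))
  }
  cons <- conservedClusters(lift$mapped, dstCcdmrs)
  perm <- overlapPermutationP(lift$mapped, dstCcdmrs, dstGenome, B = B,
                              seed = seed)
  c(lift, cons, list(p = perm$p, B = B, seed = seed))
}
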