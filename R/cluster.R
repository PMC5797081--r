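# Density-based clustering of methylated regions along the genome and
# selection of clusters containing significant DMRs (ccDMRs).

#' Configuration for genomic density-based clustering
#'
#' @param eps neighbourhood radius in bp (default 10000). The distance
#'   comparison is inclusive (`d <= eps`), the common DBSCAN convention.
#' @param min_pts minimum neighbourhood size (counting the point itself)
#'   for a core point; default 2, at which the core/border distinction
#'   collapses and the result equals connected components of the eps-gap
#'   graph.
#' @param distance `"gap"` (genomic gap between regions, 0 when
#'   overlapping; the default) or `"midpoint"` (distance between region
#'   midpoints, provided for sensitivity analysis).
#' @param ccdmr_p p-value threshold below which a member DMR makes its
#'   cluster a ccDMR (strict `<`, default 0.001).
#' @return A named list of class `ClusterConfig`.
#' @export
ClusterConfig <- function(eps = 10000, min_pts = 2,
                          distance = c("gap", "midpoint"), ccdmr_p = 0.001) {
  distance <- match.arg(distance)
  stopifnot(eps > 0, min_pts >= 1)
  structure(list(eps = eps, min_pts = min_pts, distance = distance,
                 ccdmr_p = ccdmr_p), class = "ClusterConfig")
}

#' DBSCAN over genomic regions
#'
#' Runs DBSCAN independently per chromosome with inter-region distance
#' `d(r, s) = max(0, max(r.start, s.start) - min(r.end, s.end))` (gap
#' distance; 0 for overlapping regions) or midpoint distance. Core points
#' have at least `min_pts` regions (themselves included) within `eps`
#' (inclusive); clusters are the connected components of core points, with
#' border points attached to the cluster of their leftmost core neighbour.
#' With `min_pts = 2` this equals the connected components of the graph
#' linking regions at distance `<= eps`, isolated regions being noise, and
#' is independent of processing order. Cluster ids are assigned in
#' (chromosome, leftmost start) order.
#'
#' @param regions a named [RegionSet-class].
#' @param cfg a [ClusterConfig()].
#' @return A [ClusterSet-class]; empty input gives an empty set.
#' @export
dbscanGenomic <- function(regions, cfg = ClusterConfig()) {
  stopifnot(is(regions, "RegionSet"))
  gr <- granges(regions, use.mcols = FALSE)
  ids <- regionNames(regions)
  if (is.null(ids)) ids <- paste0("region_", seq_along(gr))
  n <- length(gr)
  if (n == 0L)
    return(new("ClusterSet", assembly = assembly(regions),
               spans = GRanges(), members = list(), noise = character()))
  if (cfg$distance == "gap") {
    hits <- findOverlaps(gr, gr, maxgap = cfg$eps, ignore.strand = TRUE)
  } else {
    mid <- floor((start(gr) + end(gr)) / 2)
    pts <- GRanges(seqnames(gr), IRanges(mid, mid))
    hits <- findOverlaps(pts, pts, maxgap = cfg$eps - 1L, ignore.strand = TRUE)
  }
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  nbrCount <- tabulate(qh, nbins = n)  # includes self
  core <- nbrCount >= cfg$min_pts
  # components over core-core edges
  lab <- integer(n)  # 0 = unassigned
  edge <- core[qh] & core[sh] & qh < sh
  if (any(core)) {
    coreIdx <- which(core)
    g <- igraph::make_empty_graph(n = length(coreIdx), directed = FALSE)
    if (any(edge)) {
      remap <- integer(n); remap[coreIdx] <- seq_along(coreIdx)
      g <- igraph::add_edges(g, rbind(remap[qh[edge]], remap[sh[edge]]))
    }
    comp <- igraph::components(g)$membership
    lab[coreIdx] <- comp
  }
  # border points: non-core with a core neighbour; attach to leftmost such
  borderCand <- which(!core & nbrCount > 1L)
  for (i in borderCand) {
    nb <- sh[qh == i & sh != i]
    nb <- nb[core[nb]]
    if (length(nb)) lab[i] <- lab[min(nb)]
  }
  noise <- ids[lab == 0L]
  clustersIdx <- split(which(lab > 0L), lab[lab > 0L])
  if (!length(clustersIdx))
    return(new("ClusterSet", assembly = assembly(regions),
               spans = GRanges(), members = list(), noise = noise))
  spanChrom <- vapply(clustersIdx, function(ix)
    as.character(seqnames(gr))[ix[1L]], "")
  spanStart <- vapply(clustersIdx, function(ix) min(start(gr)[ix]), numeric(1))
  spanEnd <- vapply(clustersIdx, function(ix) max(end(gr)[ix]), numeric(1))
  o <- order(spanChrom, spanStart, spanEnd)
  clustersIdx <- clustersIdx[o]
  spanChrom <- spanChrom[o]; spanStart <- spanStart[o]; spanEnd <- spanEnd[o]
  cid <- sprintf("cluster_%04d", seq_along(clustersIdx))
  spans <- GRanges(factor(spanChrom, levels = sort(unique(spanChrom))),
                   IRanges(spanStart, spanEnd))
  mcols(spans)$id <- cid
  mcols(spans)$nMembers <- unname(lengths(clustersIdx))
  mcols(spans)$sizeBp <- width(spans)
  mcols(spans)$minP <- NA_real_
  mcols(spans)$containsSignificant <- NA
  members <- stats::setNames(lapply(clustersIdx, function(ix) ids[ix]), cid)
  new("ClusterSet", assembly = assembly(regions), spans = spans,
      members = members, noise = noise)
}

#' Select clusters containing at least one significant DMR (ccDMRs)
#'
#' Keeps clusters with at least one member region at `p < ccdmr_p`
#' (strict). Regions missing from the DMR table count as non-significant.
#' Sets `minP` and `containsSignificant` on the retained clusters.
#'
#' @param clusters a [ClusterSet-class].
#' @param dmr data.frame with columns `region_id` and `p` (e.g. from
#'   [twinDmrTest()] or [mouseDmrGlm()]).
#' @param cfg a [ClusterConfig()].
#' @return A [ClusterSet-class] subset of the input; idempotent.
#' @export
selectCcdmrs <- function(clusters, dmr, cfg = ClusterConfig()) {
  stopifnot(is(clusters, "ClusterSet"))
  pmap <- stats::setNames(dmr$p, dmr$region_id)
  minP <- vapply(clusters@members, function(mem) {
    pv <- pmap[mem]
    pv <- pv[!is.na(pv)]
    if (length(pv)) min(pv) else NA_real_
  }, numeric(1))
  keep <- !is.na(minP) & minP < cfg$ccdmr_p
  spans <- clusters@spans[keep]
  if (length(spans)) {
    mcols(spans)$minP <- unname(minP[keep])
    mcols(spans)$containsSignificant <- TRUE
  }
  new("ClusterSet", assembly = clusters@assembly, spans = spans,
      members = clusters@members[keep], noise = clusters@noise)
}

#' Summary statistics of a cluster set
#'
#' @param clusters a [ClusterSet-class].
#' @return list with `n_clusters`, `median_size_bp` (mean of the two
#'   middle values for even counts), `mean_size_bp`, and
#'   `member_count_table`. All `NA` for an empty set.
#' @export
clusterStats <- function(clusters) {
  stopifnot(is(clusters, "ClusterSet"))
  if (!length(clusters))
    return(list(n_clusters = 0L, median_size_bp = NA_real_,
                mean_size_bp = NA_real_, member_count_table = table(integer())))
  sz <- mcols(clusters@spans)$sizeBp
  list(n_clusters = length(clusters),
       median_size_bp = stats::median(sz),
       mean_size_bp = mean(sz),
       member_count_table = table(mcols(clusters@spans)$nMembers))
}

#' Convert cluster spans to a RegionSet
#'
#' @param clusters a [ClusterSet-class].
#' @return A [RegionSet-class] of cluster spans named by cluster id.
#' @export
clustersAsRegionSet <- function(clusters) {
  sp <- clusters@spans
  if (!length(sp))
    return(RegionSet(character(), numeric(), numeric(), clusters@assembly))
  RegionSet(as.character(seqnames(sp)), start(sp) - 1L, end(sp),
            clusters@assembly, name = mcols(sp)$id)
}
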