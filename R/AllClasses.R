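#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges granges seqnames start end width strand
#'   findOverlaps countOverlaps pintersect reduce sort
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlevels seqlevels<- seqlengths seqlengths<- seqinfo
NULL

#' GenomeModel: assembly label plus chromosome lengths
#'
#' A minimal genome description used to clip windows, validate coordinates
#' and draw random placements. Lengths are in base pairs.
#'
#' @slot assembly single assembly label, e.g. `"hg19"` or `"synthA"`.
#' @slot chromLengths named numeric vector of chromosome lengths (bp).
#' @exportClass GenomeModel
setClass("GenomeModel",
  representation(assembly = "character", chromLengths = "numeric"))

setValidity("GenomeModel", function(object) {
  msg <- NULL
  if (length(object@assembly) != 1L || !nzchar(object@assembly))
    msg <- c(msg, "assembly must be a single non-empty string")
  cl <- object@chromLengths
  if (length(cl) == 0L || is.null(names(cl)) || any(!nzchar(names(cl))))
    msg <- c(msg, "chromLengths must be a named vector")
  if (anyDuplicated(names(cl)))
    msg <- c(msg, "chromosome names must be unique")
  if (any(!is.finite(cl)) || any(cl <= 0))
    msg <- c(msg, "chromosome lengths must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenomeModel
#'
#' @param assembly assembly label.
#' @param chromLengths named numeric vector of chromosome lengths in bp.
#' @return A [GenomeModel-class] object.
#' @examples
#' GenomeModel("toy", c(chr1 = 1e6, chr2 = 5e5))
#' @export
GenomeModel <- function(assembly, chromLengths) {
  new("GenomeModel", assembly = assembly,
      chromLengths = structure(as.numeric(chromLengths),
                               names = names(chromLengths)))
}

#' RegionSet: a sorted set of genomic regions on one assembly
#'
#' Wraps a [GenomicRanges::GRanges] (1-based internally, as usual for
#' Bioconductor) together with an assembly label. All user-facing
#' coordinates (constructors, BED input/output, printed tables) follow the
#' BED convention: 0-based, half-open. Regions are kept sorted by
#' (chromosome, start, end); region names, when present, must be unique.
#' Chromosome names are matched by exact string equality; no "chr" prefix
#' normalization is attempted.
#'
#' @slot assembly assembly label.
#' @slot granges the underlying `GRanges`; metadata columns may carry
#'   `name` and `score`.
#' @exportClass RegionSet
setClass("RegionSet",
  representation(assembly = "character", granges = "GRanges"))

setValidity("RegionSet", function(object) {
  msg <- NULL
  if (length(object@assembly) != 1L || !nzchar(object@assembly))
    msg <- c(msg, "assembly must be a single non-empty string")
  gr <- object@granges
  if (length(gr)) {
    if (any(width(gr) < 1L))
      msg <- c(msg, "all regions must satisfy start < end")
    o <- order(as.integer(seqnames(gr)), start(gr), end(gr))
    if (!identical(o, seq_along(gr)))
      msg <- c(msg, "regions must be sorted by (chrom, start, end)")
    nm <- regionNames(object)
    if (!is.null(nm)) {
      nm <- nm[!is.na(nm)]
      if (anyDuplicated(nm))
        msg <- c(msg, "region names must be unique when present")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a RegionSet from BED-style coordinates
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open coordinates (BED convention).
#' @param assembly assembly label.
#' @param name optional region identifiers (unique).
#' @param score optional numeric scores.
#' @param strand optional strand (`"+"`, `"-"`, `"."`/`"*"`); carried but
#'   ignored by every analysis in this package.
#' @param genome optional [GenomeModel-class]; when given, coordinates are
#'   validated against chromosome lengths.
#' @return A [RegionSet-class], sorted by (chrom, start, end).
#' @examples
#' RegionSet(c("chr1", "chr1"), c(0, 500), c(100, 700), "toy")
#' @export
RegionSet <- function(chrom, start, end, assembly, name = NULL, score = NULL,
                      strand = NULL, genome = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)) || any(start != floor(start)) ||
      any(end != floor(end)))
    stop("start/end must be integral")
  if (any(start < 0) || any(start >= end))
    stop("invalid interval: need 0 <= start < end")
  lev <- sort(unique(chrom))
  if (!is.null(genome)) {
    unknown <- setdiff(lev, names(chromLengths(genome)))
    if (length(unknown))
      stop("chromosomes absent from genome model: ",
           paste(unknown, collapse = ", "))
    if (any(end > chromLengths(genome)[chrom]))
      stop("interval end exceeds chromosome length")
  }
  if (is.null(strand)) strand <- rep("*", length(chrom))
  strand <- ifelse(strand == ".", "*", strand)
  gr <- GRanges(factor(chrom, levels = lev),
                IRanges(start + 1, end),
                strand = rep(strand, length.out = length(chrom)))
  if (!is.null(name)) {
    if (anyDuplicated(name[!is.na(name)]))
      stop("region names must be unique")
    mcols(gr)$name <- as.character(name)
  }
  if (!is.null(score)) mcols(gr)$score <- as.numeric(score)
  if (!is.null(genome)) {
    sl <- chromLengths(genome)[lev]
    seqlengths(gr) <- sl
  }
  gr <- gr[order(as.integer(seqnames(gr)), start(gr), end(gr))]
  new("RegionSet", assembly = assembly, granges = gr)
}

#' ClusterSet: genomic clusters of methylated regions
#'
#' Output of [dbscanGenomic()]. Each cluster is a genomic span
#' `[min member start, max member end)` on a single chromosome, with its
#' member region identifiers and, after [selectCcdmrs()], the smallest
#' member DMR p-value and a significance flag.
#'
#' @slot assembly assembly label.
#' @slot spans `GRanges` of cluster spans with metadata columns `id`,
#'   `nMembers`, `sizeBp`, `minP`, `containsSignificant`.
#' @slot members named list: cluster id -> character vector of member
#'   region ids.
#' @slot noise character vector of region ids classified as noise.
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(assembly = "character", spans = "GRanges",
                 members = "list", noise = "character"))

setValidity("ClusterSet", function(object) {
  msg <- NULL
  sp <- object@spans
  if (length(sp) != length(object@members))
    msg <- c(msg, "spans and members must be parallel")
  if (length(sp) && !identical(mcols(sp)$id, names(object@members)))
    msg <- c(msg, "member list names must match cluster ids")
  if (length(sp) && any(mcols(sp)$sizeBp != width(sp)))
    msg <- c(msg, "sizeBp must equal span width")
  if (is.null(msg)) TRUE else msg
})

#' MethylExperiment: region-by-sample methylation counts with study design
#'
#' Extends [SummarizedExperiment::RangedSummarizedExperiment]. The single
#' assay `"counts"` holds non-negative integer read counts over merged
#' methylation peak regions; `rowRanges` carry the regions and `colData`
#' the study design (organism, group, and for twins `pair_id`/`pair_type`,
#' for animals `ip_pool`/`generation`).
#'
#' @exportClass MethylExperiment
setClass("MethylExperiment", contains = "RangedSummarizedExperiment")

setValidity("MethylExperiment", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
    if (anyDuplicated(colnames(cnt))) msg <- c(msg, "sample ids must be unique")
    if (anyDuplicated(rownames(cnt))) msg <- c(msg, "region ids must be unique")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("organism", "group")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste("colData lacks column(s):", paste(miss, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' Construct a MethylExperiment
#'
#' @param counts integer matrix (regions x samples) with unique dimnames.
#' @param design data.frame of per-sample metadata, one row per column of
#'   `counts`; must contain `organism` and `group`.
#' @param regions [RegionSet-class] parallel to the rows of `counts`
#'   (matched by region name).
#' @return A [MethylExperiment-class].
#' @export
MethylExperiment <- function(counts, design, regions) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  nm <- regionNames(regions)
  if (is.null(nm)) stop("regions must be named")
  if (is.null(rownames(counts))) rownames(counts) <- nm
  idx <- match(rownames(counts), nm)
  if (any(is.na(idx))) stop("count rows absent from region set")
  rr <- granges(regions)[idx]
  names(rr) <- rownames(counts)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowRanges = rr,
    colData = S4Vectors::DataFrame(design, row.names = colnames(counts)))
  new("MethylExperiment", se)
}

#' ChainMap: simplified cross-assembly block map
#'
#' A set of ungapped, co-linear, strand-preserving alignment blocks mapping
#' intervals on a source assembly to equal-length intervals on a destination
#' assembly, with a minimum mapped-fraction rule (the `minMatch` semantics
#' of coordinate lift-over: a region maps only if at least that fraction of
#' its bases is covered by blocks). Coordinates are 0-based half-open.
#'
#' @slot srcAssembly,dstAssembly assembly labels.
#' @slot blocks data.frame with columns `src_chrom`, `src_start`,
#'   `src_end`, `dst_chrom`, `dst_start`, `dst_end`.
#' @slot minMatch minimum fraction of a region's bases that must be
#'   covered by blocks for it to map (default 0.1).
#' @exportClass ChainMap
setClass("ChainMap",
  representation(srcAssembly = "character", dstAssembly = "character",
                 blocks = "data.frame", minMatch = "numeric"))

setValidity("ChainMap", function(object) {
  msg <- NULL
  b <- object@blocks
  need <- c("src_chrom", "src_start", "src_end",
            "dst_chrom", "dst_start", "dst_end")
  if (!all(need %in% colnames(b)))
    return(paste("blocks must have columns:", paste(need, collapse = ", ")))
  if (nrow(b)) {
    if (any(b$src_end - b$src_start != b$dst_end - b$dst_start))
      msg <- c(msg, "src and dst block lengths must be equal")
    if (any(b$src_start < 0) || any(b$src_start >= b$src_end))
      msg <- c(msg, "invalid src block coordinates")
    o <- order(b$src_chrom, b$src_start)
    bo <- b[o, ]
    same <- bo$src_chrom[-1] == bo$src_chrom[-nrow(bo)]
    if (any(same & bo$src_start[-1] < bo$src_end[-nrow(bo)]))
      msg <- c(msg, "src blocks must be non-overlapping")
  }
  if (object@minMatch < 0 || object@minMatch > 1)
    msg <- c(msg, "minMatch must be in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Construct a ChainMap
#'
#' @param blocks data.frame of block coordinates (0-based half-open), see
#'   [ChainMap-class].
#' @param srcAssembly,dstAssembly assembly labels.
#' @param minMatch minimum mapped fraction, default 0.1.
#' @return A [ChainMap-class].
#' @export
ChainMap <- function(blocks, srcAssembly, dstAssembly, minMatch = 0.1) {
  blocks <- as.data.frame(blocks)
  if (nrow(blocks))
    blocks <- blocks[order(blocks$src_chrom, blocks$src_start), , drop = FALSE]
  rownames(blocks) <- NULL
  new("ChainMap", srcAssembly = srcAssembly, dstAssembly = dstAssembly,
      blocks = blocks, minMatch = minMatch)
}
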