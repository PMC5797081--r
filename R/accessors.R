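#' Accessors for RegionSet
#'
#' `assembly()` returns the assembly label, `granges()` the underlying
#' `GRanges` (1-based, Bioconductor convention), `regionNames()` the region
#' identifiers (or `NULL`), and `asBedFrame()` a BED-style data.frame with
#' 0-based half-open coordinates.
#'
#' @param x a [RegionSet-class].
#' @name RegionSet-accessors
NULL

#' @rdname RegionSet-accessors
#' @export
setMethod("assembly", "RegionSet", function(x) x@assembly)

#' @rdname RegionSet-accessors
#' @param use.names,use.mcols passed through for compatibility with the
#'   `GenomicRanges` generic.
#' @param ... ignored.
#' @importMethodsFrom GenomicRanges granges
#' @export
setMethod("granges", "RegionSet",
  function(x, use.names = TRUE, use.mcols = TRUE, ...) {
    gr <- x@granges
    if (!use.mcols) mcols(gr) <- NULL
    gr
  })

#' @rdname RegionSet-accessors
#' @export
setMethod("regionNames", "RegionSet", function(x) {
  nm <- mcols(x@granges)$name
  if (is.null(nm)) NULL else as.character(nm)
})

#' @rdname RegionSet-accessors
#' @export
setMethod("length", "RegionSet", function(x) length(x@granges))

#' @rdname RegionSet-accessors
#' @export
asBedFrame <- function(x) {
  stopifnot(is(x, "RegionSet"))
  gr <- x@granges
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(mcols(gr)$name)) df$name <- mcols(gr)$name
  if (!is.null(mcols(gr)$score)) df$score <- mcols(gr)$score
  st <- as.character(strand(gr))
  if (any(st != "*")) df$strand <- ifelse(st == "*", ".", st)
  df
}

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet on", object@assembly, "with", length(object), "regions over",
      length(seqlevels(object@granges)), "chromosome(s)\n")
  if (length(object)) {
    n <- min(length(object), 4L)
    print(utils::head(asBedFrame(object), n))
    if (length(object) > n) cat("...\n")
  }
})

#' Accessors for GenomeModel
#'
#' @param x a [GenomeModel-class].
#' @name GenomeModel-accessors
NULL

#' @rdname GenomeModel-accessors
#' @export
setMethod("assembly", "GenomeModel", function(x) x@assembly)

#' @rdname GenomeModel-accessors
#' @export
setMethod("chromLengths", "GenomeModel", function(x) x@chromLengths)

setMethod("show", "GenomeModel", function(object) {
  cat("GenomeModel", object@assembly, "-", length(object@chromLengths),
      "chromosome(s),", format(sum(object@chromLengths), big.mark = ","),
      "bp total\n")
})

#' Accessors for ClusterSet
#'
#' `clusterSpans()` returns the cluster span `GRanges` (metadata columns
#' `id`, `nMembers`, `sizeBp`, `minP`, `containsSignificant`),
#' `clusterMembers()` the named list of member region ids, and
#' `noiseRegions()` the ids of regions not assigned to any cluster.
#'
#' @param x a [ClusterSet-class].
#' @name ClusterSet-accessors
NULL

#' @rdname ClusterSet-accessors
#' @export
setMethod("assembly", "ClusterSet", function(x) x@assembly)

#' @rdname ClusterSet-accessors
#' @export
setMethod("clusterSpans", "ClusterSet", function(x) x@spans)

#' @rdname ClusterSet-accessors
#' @export
setMethod("clusterMembers", "ClusterSet", function(x) x@members)

#' @rdname ClusterSet-accessors
#' @export
setMethod("noiseRegions", "ClusterSet", function(x) x@noise)

#' @rdname ClusterSet-accessors
#' @export
setMethod("length", "ClusterSet", function(x) length(x@spans))

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet on", object@assembly, "with", length(object),
      "cluster(s) and", length(object@noise), "noise region(s)\n")
  if (length(object)) {
    sz <- mcols(object@spans)$sizeBp
    cat("  median span:", stats::median(sz), "bp; members per cluster:",
        paste(range(mcols(object@spans)$nMembers), collapse = "-"), "\n")
  }
})

#' Accessors for ChainMap
#'
#' @param x a [ChainMap-class].
#' @name ChainMap-accessors
NULL

#' @rdname ChainMap-accessors
#' @export
setMethod("chainBlocks", "ChainMap", function(x) x@blocks)

setMethod("show", "ChainMap", function(object) {
  cat("ChainMap", object@srcAssembly, "->", object@dstAssembly, "with",
      nrow(object@blocks), "block(s), minMatch =", object@minMatch, "\n")
})

#' Extract the counts assay of a MethylExperiment
#'
#' @param x a [MethylExperiment-class].
#' @return integer matrix of counts.
#' @export
methCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' Extract the study design of a MethylExperiment
#'
#' @param x a [MethylExperiment-class].
#' @return data.frame of per-sample design metadata.
#' @export
studyDesign <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}
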