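#' @rdname RegionSet-accessors
#' @export
setGeneric("assembly", function(x) standardGeneric("assembly"))

#' @rdname RegionSet-accessors
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' @rdname GenomeModel-accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname ClusterSet-accessors
#' @export
setGeneric("clusterSpans", function(x) standardGeneric("clusterSpans"))

#' @rdname ClusterSet-accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname ClusterSet-accessors
#' @export
setGeneric("noiseRegions", function(x) standardGeneric("noiseRegions"))

#' @rdname ChainMap-accessors
#' @export
setGeneric("chainBlocks", function(x) standardGeneric("chainBlocks"))
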