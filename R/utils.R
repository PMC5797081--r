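# Shared helpers: deterministic sub-seed derivation, TSV readers/writers,
# and fast covered-bases lookups against a fixed interval track.

#' Derive a deterministic sub-seed from a global seed and a stage tag
#'
#' Every source of randomness in the package draws its seed through this
#' function so that a single global seed reproduces a whole analysis while
#' distinct stages get decorrelated streams. The result is always a valid
#' 32-bit R integer.
#'
#' @param seed integer global seed.
#' @param tag character stage label.
#' @return integer seed.
#' @export
deriveSeed <- function(seed, tag) {
  codes <- utf8ToInt(tag)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919 + 1) %% 2147483647)
}

tsvHeaderComment <- "# coordinates: 0-based, half-open (BED convention)"

writeTsv <- function(df, path, coordComment = FALSE) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (coordComment) writeLines(tsvHeaderComment, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a region-by-sample count matrix from TSV
#'
#' First column must hold region ids; remaining columns one sample each.
#'
#' @param path TSV file path.
#' @return integer matrix with region ids as rownames.
#' @export
readCountsTsv <- function(path) {
  df <- readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a count matrix as TSV
#'
#' @param counts matrix with region-id rownames and sample-id colnames.
#' @param path output path.
#' @export
writeCountsTsv <- function(counts, path) {
  df <- data.frame(region_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeTsv(df, path)
}

# Cumulative-coverage lookup for one chromosome of a merged track.
# starts/ends are 0-based half-open, sorted, disjoint. Returns a function
# computing covered bases in [0, x) for vector x.
coverageLookup <- function(starts, ends) {
  cum <- c(0, cumsum(ends - starts))
  force(starts); force(ends)
  function(x) {
    i <- findInterval(x, starts)
    res <- cum[i + 1L]
    straddle <- i > 0L
    if (any(straddle)) {
      ii <- i[straddle]
      res[straddle] <- res[straddle] - pmax(0, ends[ii] - x[straddle])
    }
    res
  }
}

# Covered bp of query intervals [s, e) (0-based) against a RegionSet track;
# track is reduced first. Vectorized over queries on a single chromosome.
trackCoverageFuns <- function(track) {
  gr <- reduce(granges(track, use.mcols = FALSE), ignore.strand = TRUE)
  byChrom <- split(gr, as.character(seqnames(gr)))
  lapply(byChrom, function(g) coverageLookup(start(g) - 1L, end(g)))
}

overlapBpOnChrom <- function(covFuns, chrom, s, e) {
  f <- covFuns[[chrom]]
  if (is.null(f)) return(numeric(length(s)))
  f(e) - f(s)
}

logMsg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose))
    message(format(Sys.time(), "%H:%M:%S"), " | ", ...)
}
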