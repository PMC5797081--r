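# Interval substrate: BED IO, merging, overlap and windowed joins.
# All user-facing coordinates are 0-based half-open (BED convention);
# the GRanges held inside a RegionSet are 1-based as usual.

# put two GRanges on the union of their seqlevels so cross-set overlap
# queries do not warn when one chromosome is absent from either side
harmonizeSeqlevels <- function(ga, gb) {
  lev <- sort(union(seqlevels(ga), seqlevels(gb)))
  relevel <- function(g)
    GRanges(factor(as.character(seqnames(g)), levels = lev),
            IRanges::ranges(g), strand = strand(g))
  list(relevel(ga), relevel(gb))
}

regionSetFromGRanges <- function(gr, assembly) {
  lev <- sort(unique(as.character(seqnames(gr))))
  sl <- seqlengths(gr)
  gr <- GRanges(factor(as.character(seqnames(gr)), levels = lev),
                IRanges::ranges(gr), strand = strand(gr),
                mcols(gr))
  if (!all(is.na(sl))) {
    keep <- sl[lev]
    if (!any(is.na(keep))) seqlengths(gr) <- keep
  }
  gr <- gr[order(as.integer(seqnames(gr)), start(gr), end(gr))]
  new("RegionSet", assembly = assembly, granges = gr)
}

#' Read a BED3/BED6 file into a RegionSet
#'
#' Tab-separated, 0-based half-open records. Columns beyond the first three
#' are kept as `name`, `score` and strand. Lines starting with `#`,
#' `track` or `browser` are skipped. Malformed records (fewer than three
#' fields, non-integer coordinates, start >= end) raise an error naming the
#' offending line.
#'
#' @param path path to an existing BED file.
#' @param assembly assembly label attached to the result.
#' @param genome optional [GenomeModel-class] used to validate coordinates.
#' @return A sorted [RegionSet-class].
#' @seealso [writeBed()]
#' @export
readBed <- function(path, assembly, genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !grepl("^(#|track\\b|browser\\b)", lines)
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (!length(lines))
    return(RegionSet(character(), numeric(), numeric(), assembly))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED parse error at line ", lineno[which(nf < 3L)[1L]],
         ": fewer than 3 tab-separated fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad))
    stop("BED parse error at line ", lineno[which(bad)[1L]],
         ": non-integer coordinates")
  bad <- start < 0 | start >= end
  if (any(bad))
    stop("BED parse error at line ", lineno[which(bad)[1L]],
         ": requires 0 <= start < end")
  name <- if (any(nf >= 4L))
    vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_, "")
  score <- if (any(nf >= 5L))
    suppressWarnings(as.numeric(vapply(fields,
      function(f) if (length(f) >= 5L) f[[5L]] else NA_character_, "")))
  strand <- if (any(nf >= 6L))
    vapply(fields, function(f) if (length(f) >= 6L) f[[6L]] else ".", "")
  RegionSet(chrom, start, end, assembly, name = name, score = score,
            strand = strand, genome = genome)
}

#' Write a RegionSet as BED
#'
#' Emits 0-based half-open records in the set's deterministic sorted order.
#'
#' @param x a [RegionSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(x, path) {
  df <- asBedFrame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge one or more RegionSets into a union of coalesced regions
#'
#' Overlapping or bookended (gap 0) regions are coalesced, matching the
#' default behaviour of `bedtools merge` on the union of the inputs. Base
#' coverage of the union is preserved. All inputs must share one assembly.
#'
#' @param ... one or more [RegionSet-class] objects.
#' @return A sorted [RegionSet-class] of disjoint regions.
#' @examples
#' a <- RegionSet("chr1", 0, 100, "toy")
#' b <- RegionSet("chr1", 100, 200, "toy")
#' asBedFrame(mergeRegions(a, b))  # one region [0, 200)
#' @export
mergeRegions <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !is(sets[[1L]], "RegionSet"))
    sets <- sets[[1L]]
  stopifnot(length(sets) >= 1L, all(vapply(sets, is, TRUE, "RegionSet")))
  asm <- unique(vapply(sets, assembly, ""))
  if (length(asm) != 1L)
    stop("cannot merge RegionSets from different assemblies: ",
         paste(asm, collapse = ", "))
  grl <- lapply(sets, function(s) granges(s, use.mcols = FALSE))
  lev <- sort(unique(unlist(lapply(grl, function(g) as.character(seqnames(g))))))
  grl <- lapply(grl, function(g) {
    GRanges(factor(as.character(seqnames(g)), levels = lev), IRanges::ranges(g))
  })
  combined <- do.call(c, grl)
  merged <- reduce(combined, min.gapwidth = 1L, ignore.strand = TRUE)
  regionSetFromGRanges(merged, asm)
}

#' Overlap join between two RegionSets
#'
#' Reports every pair of regions overlapping by at least one base whose
#' overlap covers at least `minFracA` of the `a`-region (the semantics of
#' `intersectBed -f`). Half-open convention: touching regions do not
#' overlap.
#'
#' @param a,b [RegionSet-class] objects on the same assembly.
#' @param minFracA minimum overlap / length(a-region), in `[0, 1]`.
#' @return data.frame with columns `a_index`, `b_index`, `a_name`,
#'   `b_name`, `overlap_bp`, ordered by (`a_index`, `b_index`).
#' @export
overlapJoin <- function(a, b, minFracA = 0) {
  stopifnot(is(a, "RegionSet"), is(b, "RegionSet"))
  if (assembly(a) != assembly(b))
    stop("assembly mismatch: ", assembly(a), " vs ", assembly(b))
  if (minFracA < 0 || minFracA > 1)
    stop("minFracA must be in [0, 1]")
  h <- harmonizeSeqlevels(granges(a, use.mcols = FALSE),
                          granges(b, use.mcols = FALSE))
  ga <- h[[1L]]; gb <- h[[2L]]
  hits <- findOverlaps(ga, gb, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (length(qi)) {
    ov <- width(pintersect(ga[qi], gb[si]))
    keep <- ov >= 1 & ov / width(ga)[qi] >= minFracA
    qi <- qi[keep]; si <- si[keep]; ov <- ov[keep]
  } else ov <- integer()
  o <- order(qi, si)
  nmA <- regionNames(a); nmB <- regionNames(b)
  data.frame(a_index = qi[o], b_index = si[o],
             a_name = if (is.null(nmA)) NA_character_ else nmA[qi[o]],
             b_name = if (is.null(nmB)) NA_character_ else nmB[si[o]],
             overlap_bp = ov[o], stringsAsFactors = FALSE)
}

#' Assign genes to regions within a flanking window
#'
#' Gene `g` is assigned to region `r` iff `g` overlaps the half-open window
#' `[r.start - flank, r.end + flank)`, clipped at 0 and at the chromosome
#' length when known. With `flank = 0` this reduces to pure overlap.
#'
#' @param regions,genes [RegionSet-class] objects on the same assembly;
#'   `genes` should be named.
#' @param flank window size in bp on each side (>= 0).
#' @return named list: region id -> sorted character vector of gene names.
#' @export
windowJoin <- function(regions, genes, flank) {
  stopifnot(is(regions, "RegionSet"), is(genes, "RegionSet"))
  if (assembly(regions) != assembly(genes))
    stop("assembly mismatch")
  stopifnot(flank >= 0)
  gr <- granges(regions, use.mcols = FALSE)
  newStart <- pmax(1, start(gr) - flank)
  newEnd <- end(gr) + flank
  sl <- seqlengths(gr)
  if (!all(is.na(sl))) {
    lim <- sl[as.character(seqnames(gr))]
    newEnd <- ifelse(is.na(lim), newEnd, pmin(newEnd, lim))
  }
  win <- GRanges(seqnames(gr), IRanges(newStart, newEnd))
  h <- harmonizeSeqlevels(win, granges(genes, use.mcols = FALSE))
  hits <- findOverlaps(h[[1L]], h[[2L]], ignore.strand = TRUE)
  rid <- regionNames(regions)
  if (is.null(rid)) rid <- paste0("region_", seq_along(gr))
  gid <- regionNames(genes)
  if (is.null(gid)) gid <- paste0("gene_", seq_len(length(genes)))
  out <- split(gid[S4Vectors::subjectHits(hits)],
               rid[S4Vectors::queryHits(hits)])
  out <- lapply(out, function(v) sort(unique(v)))
  # preserve region order, include empty assignments
  res <- stats::setNames(vector("list", length(rid)), rid)
  res[names(out)] <- out
  res[vapply(res, is.null, TRUE)] <- list(character())
  res
}

#' Total bases covered by a RegionSet
#'
#' @param x a [RegionSet-class].
#' @return numeric, total covered bp (overlaps counted once).
#' @export
coveredBases <- function(x) {
  stopifnot(is(x, "RegionSet"))
  sum(width(reduce(granges(x, use.mcols = FALSE), ignore.strand = TRUE)))
}
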