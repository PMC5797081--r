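# Shared fixtures and independent brute-force oracles used across tests.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# small region set builder (0-based half-open)
rs <- function(chrom, start, end, assembly = "toy", name = NULL, ...) {
  RegionSet(chrom, start, end, assembly, name = name, ...)
}

# random region set on a couple of chromosomes, possibly overlapping
randomRegions <- function(n, chromLen = 1e5, nChrom = 2, maxLen = 500,
                          named = TRUE) {
  chrom <- paste0("chr", sample.int(nChrom, n, replace = TRUE))
  st <- floor(runif(n, 0, chromLen - maxLen))
  len <- pmax(1, floor(runif(n, 1, maxLen)))
  nm <- if (named) sprintf("r%04d", seq_len(n)) else NULL
  rs(chrom, st, st + len, name = nm)
}

# per-base boolean-array coverage oracle (chromosomes <= 1e5 bp)
coverageOracle <- function(regionSets, chromLen = 1e5) {
  cover <- list()
  for (s in regionSets) {
    df <- asBedFrame(s)
    for (i in seq_len(nrow(df))) {
      ch <- df$chrom[i]
      if (is.null(cover[[ch]])) cover[[ch]] <- logical(chromLen)
      cover[[ch]][(df$start[i] + 1):df$end[i]] <- TRUE
    }
  }
  sum(vapply(cover, sum, numeric(1)))
}

# brute-force O(n^2) connected components of the eps-gap graph
gapComponentsOracle <- function(regions, eps) {
  df <- asBedFrame(regions)
  n <- nrow(df)
  d <- pmax(0, outer(df$start, df$start, pmax) - outer(df$end, df$end, pmin))
  adj <- d <= eps & outer(df$chrom, df$chrom, "==")
  # components among nodes with >= 1 neighbour besides self
  lab <- rep(0L, n); g <- 0L
  hasNbr <- rowSums(adj) > 1
  for (i in seq_len(n)) {
    if (!hasNbr[i] || lab[i] != 0L) next
    g <- g + 1L
    frontier <- i
    while (length(frontier)) {
      lab[frontier] <- g
      nxt <- which(hasNbr & lab == 0L &
                     colSums(adj[frontier, , drop = FALSE]) > 0)
      frontier <- nxt
    }
  }
  list(labels = lab, noise = which(!hasNbr))
}

# exact one-sided rank-sum p by full enumeration of group assignments
wilcoxEnumOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vals <- c(x, y)
  r <- rank(vals)
  wObs <- sum(r[seq_len(nx)])
  combos <- utils::combn(nx + ny, nx)
  ws <- apply(combos, 2, function(ix) sum(r[ix]))
  mean(ws >= wObs)  # P(W >= observed) under random assignment
}

# exact hypergeometric upper tail by enumeration of all selections
hyperEnumOracle <- function(N, K, n, k) {
  sel <- utils::combn(N, n)
  inTerm <- seq_len(K)  # term genes are 1..K wlog
  ks <- apply(sel, 2, function(s) sum(s %in% inTerm))
  mean(ks >= k)
}

# small simulation config for fast tests
tinySimConfig <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chroms = 2, chrom_length = 6e6, n_regions = 1500,
         planted_cluster_count = 6, dmrs_per_cluster = 4, n_genes = 300,
         n_go_terms = 15, n_state_tissues = 2, n_states_per_tissue = 15,
         map_coverage = 0.5),
    list(...))
  do.call(SimulationConfig, args)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
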