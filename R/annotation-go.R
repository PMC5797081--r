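# Cluster-to-gene annotation and cluster-debiased GO enrichment:
# hypergeometric tests against a cluster-derived background,
# one-gene-per-cluster randomizations scored by the geometric mean of term
# ranks, and an empirical p-value from a background-resampling null.

#' Configuration for the GO enrichment stage
#'
#' @param window gene-assignment window in bp on each side of a cluster
#'   span (default 100000, the scale of chromatin contact domains).
#' @param n_randomizations number of one-gene-per-cluster randomizations
#'   (R, default 100).
#' @param n_shuffles number of null repetitions for the empirical p-value
#'   (B, default 1000).
#' @param seed integer seed for the randomizations.
#' @param export_p,export_min_genes,export_max_genes,export_top filters
#'   applied when exporting the semantic-similarity input list: p < 0.01,
#'   term gene count > 1 and < 50, top 50 terms per ontology.
#' @return A named list of class `GoConfig`.
#' @export
GoConfig <- function(window = 100000, n_randomizations = 100,
                     n_shuffles = 1000, seed = 1, export_p = 0.01,
                     export_min_genes = 1, export_max_genes = 50,
                     export_top = 50) {
  stopifnot(window >= 0, n_randomizations >= 1, n_shuffles >= 1)
  structure(list(window = window, n_randomizations = n_randomizations,
                 n_shuffles = n_shuffles, seed = seed, export_p = export_p,
                 export_min_genes = export_min_genes,
                 export_max_genes = export_max_genes,
                 export_top = export_top), class = "GoConfig")
}

#' Read a GO map from TSV
#'
#' Expects columns `term` and `gene`, optionally `ontology` and `name`.
#'
#' @param path TSV path.
#' @return A `GOMap`: named list of gene-id vectors with a `meta`
#'   attribute (data.frame of term metadata).
#' @export
readGoMap <- function(path) {
  df <- readTsv(path)
  stopifnot(all(c("term", "gene") %in% colnames(df)))
  goMap <- split(as.character(df$gene), as.character(df$term))
  goMap <- lapply(goMap, unique)
  meta <- unique(df[, intersect(c("term", "ontology", "name"), colnames(df)),
                    drop = FALSE])
  attr(goMap, "meta") <- meta
  goMap
}

#' Annotate ccDMR clusters with nearby genes
#'
#' Assigns to each cluster the genes overlapping its span or lying within
#' `window` bp upstream or downstream (delegating to [windowJoin()] on the
#' cluster spans).
#'
#' @param ccdmrs a [ClusterSet-class].
#' @param genes a named [RegionSet-class] of gene models.
#' @param cfg a [GoConfig()].
#' @return list with `cluster_genes` (cluster id -> gene vector) and
#'   `gene_list` (deduplicated union).
#' @export
annotateClusters <- function(ccdmrs, genes, cfg = GoConfig()) {
  spans <- clustersAsRegionSet(ccdmrs)
  cg <- windowJoin(spans, genes, flank = cfg$window)
  list(cluster_genes = cg, gene_list = sort(unique(unlist(cg))))
}

# Rank terms by ascending p, ties broken by descending overlap count then
# lexicographic term id; a strict total order, so ranks are unique.
.rankTerms <- function(p, k, term) {
  o <- order(p, -k, term)
  r <- integer(length(p))
  r[o] <- seq_along(o)
  r
}

#' Hypergeometric GO over-representation test
#'
#' For each term, tests over-representation of the selected genes with the
#' upper-tail hypergeometric probability `P(X >= k)` where `N` is the
#' background size, `K` the term size within the background, `n` the
#' selection size, and `k` the overlap. Term gene sets are intersected
#' with the background before testing; terms with no background gene are
#' dropped. Ranks order by ascending p with ties broken by descending `k`
#' then term id.
#'
#' @param selectedGenes character vector, a subset of `background`.
#' @param background character vector of background gene ids.
#' @param goMap named list: term id -> gene id vector.
#' @return data.frame: `term`, `k`, `n`, `K`, `N`, `p`, `rank`, sorted by
#'   rank.
#' @export
hypergeomGo <- function(selectedGenes, background, goMap) {
  selectedGenes <- unique(selectedGenes)
  background <- unique(background)
  if (!length(selectedGenes)) stop("empty gene selection")
  if (!all(selectedGenes %in% background))
    stop("selected genes must be a subset of the background")
  termGenes <- lapply(goMap, function(g) intersect(g, background))
  K <- lengths(termGenes)
  keep <- K > 0
  termGenes <- termGenes[keep]; K <- K[keep]
  N <- length(background)
  n <- length(selectedGenes)
  k <- vapply(termGenes, function(g) sum(selectedGenes %in% g), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = names(termGenes), k = unname(k), n = n,
                    K = unname(K), N = N, p = unname(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$rank <- .rankTerms(out$p, out$k, out$term)
  out[order(out$rank), , drop = FALSE]
}

# One scoring pass: draw one gene per cluster (from the supplied per-
# cluster gene pools), run the hypergeometric test, return the rank of
# every term in `termIds` (terms absent from the run get worst rank + 1).
.onePassRanks <- function(pools, background, goMap, termIds) {
  sel <- unique(vapply(pools, function(g)
    if (length(g) == 1L) g else sample(g, 1L), ""))
  tab <- hypergeomGo(sel, background, goMap)
  r <- tab$rank[match(termIds, tab$term)]
  r[is.na(r)] <- nrow(tab) + 1L
  r
}

#' Cluster-debiased GO scoring by geometric mean of ranks
#'
#' Genes in one cluster can be functionally related, which inflates
#' ordinary over-representation p-values. To debias, one gene is drawn
#' uniformly from each cluster's gene set, the hypergeometric test is run
#' on that selection, and each term's rank is recorded; over
#' `n_randomizations` repetitions the score of a term is the geometric
#' mean of its ranks (lower is better). Terms absent from a run receive
#' rank `(number of terms tested in that run) + 1`.
#'
#' @param clusterGenes named list: cluster id -> gene vector (clusters
#'   with no genes are skipped with a message).
#' @param background character vector of background gene ids.
#' @param goMap named list: term id -> gene vector.
#' @param cfg a [GoConfig()] (uses `n_randomizations` and `seed`).
#' @return data.frame: `term`, `score` (geometric mean rank), `mean_p`
#'   (arithmetic mean of per-run p-values, descriptive only), `K`,
#'   sorted by ascending score.
#' @export
debiasedGoScore <- function(clusterGenes, background, goMap,
                            cfg = GoConfig()) {
  empty <- lengths(clusterGenes) == 0L
  if (any(empty)) {
    logMsg("skipping ", sum(empty), " cluster(s) with no genes in reach")
    clusterGenes <- clusterGenes[!empty]
  }
  if (!length(clusterGenes)) stop("no cluster has any gene")
  background <- unique(background)
  termIds <- names(goMap)[vapply(goMap, function(g)
    length(intersect(g, background)) > 0, TRUE)]
  set.seed(deriveSeed(cfg$seed, "debiased_go"))
  R <- cfg$n_randomizations
  ranks <- matrix(NA_real_, length(termIds), R,
                  dimnames = list(termIds, NULL))
  for (r in seq_len(R))
    ranks[, r] <- .onePassRanks(clusterGenes, background, goMap, termIds)
  score <- exp(rowMeans(log(ranks)))
  K <- vapply(goMap[termIds], function(g)
    length(intersect(g, background)), integer(1))
  out <- data.frame(term = termIds, score = unname(score),
                    K = unname(K), stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$score, out$term), , drop = FALSE]
}

#' Empirical p-values for debiased GO scores
#'
#' The null distribution is built by repeating the full scoring procedure
#' with the gene-to-cluster geography broken: in each of `n_shuffles`
#' repetitions, every cluster's gene set is replaced by a size-matched
#' uniform draw from the whole background, and terms are rescored by the
#' same `n_randomizations` one-gene-per-cluster geometric-mean-rank rule.
#' Because the null repetitions replay the observed procedure exactly
#' (only with geography-free gene sets), observed and null scores are
#' exchangeable under the null and
#' `p = (1 + #\{null score <= observed\}) / (B + 1)` is uniform on its
#' attainable grid.
#'
#' @param observed data.frame from [debiasedGoScore()].
#' @param clusterGenes the cluster annotation that produced `observed`
#'   (cluster gene-set sizes are preserved in the null).
#' @param background,goMap as in [debiasedGoScore()].
#' @param cfg a [GoConfig()] (uses `n_shuffles`, `n_randomizations`,
#'   `seed`).
#' @return `observed` with an `empirical_p` column.
#' @export
empiricalGoP <- function(observed, clusterGenes, background, goMap,
                         cfg = GoConfig()) {
  sizes <- lengths(clusterGenes)
  sizes <- sizes[sizes > 0L]
  if (!length(sizes)) stop("no cluster has any gene")
  background <- unique(background)
  termIds <- observed$term
  # precompute term membership matrix over the background for speed
  bgIndex <- stats::setNames(seq_along(background), background)
  memb <- lapply(goMap[termIds], function(g)
    unname(bgIndex[intersect(g, background)]))
  K <- lengths(memb)
  N <- length(background)
  membMat <- matrix(FALSE, length(termIds), N)
  for (i in seq_along(memb)) membMat[i, memb[[i]]] <- TRUE
  sizes <- pmin(unname(sizes), N)
  set.seed(deriveSeed(cfg$seed, "empirical_go"))
  B <- cfg$n_shuffles
  R <- if (all(sizes == 1L)) 1L else cfg$n_randomizations
  exceed <- numeric(length(termIds))
  for (b in seq_len(B)) {
    pools <- lapply(sizes, function(s) sample.int(N, s))
    logRankSum <- numeric(length(termIds))
    for (r in seq_len(R)) {
      selIdx <- unique(vapply(pools, function(p)
        if (length(p) == 1L) p else p[sample.int(length(p), 1L)],
        integer(1)))
      k <- as.integer(rowSums(membMat[, selIdx, drop = FALSE]))
      p <- stats::phyper(k - 1, K, N - K, length(selIdx), lower.tail = FALSE)
      rk <- .rankTerms(p, k, termIds)
      logRankSum <- logRankSum + log(rk)
    }
    nullScore <- exp(logRankSum / R)
    exceed <- exceed + (nullScore <= observed$score)
  }
  observed$empirical_p <- (1 + exceed) / (B + 1)
  observed
}

#' Export the semantic-similarity input list
#'
#' Applies the stated export filters — hypergeometric p < `export_p` on
#' the full-selection test, term gene count within
#' (`export_min_genes`, `export_max_genes`) exclusive, top `export_top`
#' terms per ontology by debiased score — and writes term id plus ranking
#' score, the input format of semantic-similarity visualization tools.
#'
#' @param scored data.frame from [debiasedGoScore()] (optionally with
#'   `empirical_p`).
#' @param fullTest data.frame from [hypergeomGo()] on the full gene list.
#' @param goMeta data.frame of term metadata with columns `term` and
#'   optionally `ontology`.
#' @param path output path.
#' @param cfg a [GoConfig()].
#' @return the exported data.frame, invisibly.
#' @export
exportRevigoInput <- function(scored, fullTest, goMeta, path,
                              cfg = GoConfig()) {
  df <- merge(scored, fullTest[, c("term", "p", "k", "K")], by = "term")
  if (!is.null(goMeta) && "ontology" %in% colnames(goMeta))
    df$ontology <- goMeta$ontology[match(df$term, goMeta$term)]
  else df$ontology <- "BP"
  df <- df[df$p < cfg$export_p &
             df$K > cfg$export_min_genes & df$K < cfg$export_max_genes, ,
           drop = FALSE]
  df <- df[order(df$ontology, df$score, df$term), , drop = FALSE]
  df <- do.call(rbind, lapply(split(df, df$ontology), function(d)
    utils::head(d, cfg$export_top)))
  out <- data.frame(term = df$term, score = df$score,
                    stringsAsFactors = FALSE)
  writeTsv(out, path)
  invisible(out)
}
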