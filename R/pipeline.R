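# End-to-end orchestration from a single configuration: normalization,
# DMR testing, clustering, ccDMR selection, annotation/enrichment and
# (optionally) feature/state profiles, with a manifest recording
# parameters, seeds and output checksums.

#' Build and validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file holding one) with the
#' input paths, the experiment selector, stage parameters and a global
#' seed. Referenced paths are checked before any computation.
#'
#' @param config named list or path to a YAML file. Recognized fields:
#'   `experiment` (`"human_MZD"`, `"mouse_F0"`, `"mouse_F1"`), `counts`,
#'   `design`, `peaks`, `genes`, `go_map` (paths), optional `tracks_dir`,
#'   `chain_map`, `dst_ccdmrs`, `assembly`, `dst_assembly`,
#'   `chrom_lengths` (named list), `seed`, `output_dir`, and optional
#'   sub-lists `dmr`, `cluster`, `go`, `enrich` overriding the
#'   corresponding stage-configuration defaults.
#' @return validated configuration list of class `PipelineConfig`.
#' @export
PipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(experiment = "human_MZD", seed = 1,
                   output_dir = "methclust_out", assembly = "unknown")
  config <- utils::modifyList(defaults, config)
  if (!config$experiment %in% c("human_MZD", "mouse_F0", "mouse_F1"))
    stop("unknown experiment selector: ", config$experiment)
  required <- c("counts", "design", "peaks", "genes", "go_map")
  miss <- setdiff(required, names(config))
  if (length(miss))
    stop("configuration lacks required path(s): ",
         paste(miss, collapse = ", "))
  for (f in c(required, intersect(c("tracks_dir", "chain_map", "dst_ccdmrs"),
                                  names(config))))
    if (!file.exists(config[[f]]))
      stop("configured path does not exist: ", f, " = ", config[[f]])
  structure(config, class = c("PipelineConfig", "list"))
}

.stageCfg <- function(builder, overrides) {
  if (is.null(overrides)) builder() else do.call(builder, overrides)
}

#' Run the analysis pipeline end to end
#'
#' Stage order follows the analysis workflow: normalize, test DMRs
#' (twin or animal model by selector), cluster all peak regions, select
#' ccDMRs, annotate with genes, run the cluster-debiased GO enrichment,
#' and — when tracks are configured — the feature-track enrichment.
#' Every stage output is written under the output directory together with
#' a `manifest.json` recording parameters, seeds and MD5 checksums, so a
#' rerun with the same configuration is byte-identical.
#'
#' @param config a [PipelineConfig()] (or a list / YAML path accepted by
#'   it).
#' @param verbose emit progress messages.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  cfg <- PipelineConfig(config)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dmrCfg <- .stageCfg(DmrTestConfig, cfg$dmr)
  clCfg <- .stageCfg(ClusterConfig, cfg$cluster)
  goCfg <- .stageCfg(GoConfig, cfg$go)
  goCfg$seed <- deriveSeed(cfg$seed, "go_stage")
  enCfg <- .stageCfg(EnrichConfig, cfg$enrich)
  enCfg$seed <- deriveSeed(cfg$seed, "enrich_stage")
  manifest <- list(package_version = as.character(utils::packageVersion("methclust")),
                   experiment = cfg$experiment, seed = cfg$seed,
                   parameters = list(dmr = unclass(dmrCfg),
                                     cluster = unclass(clCfg),
                                     go = unclass(goCfg),
                                     enrich = unclass(enCfg)),
                   inputs = list(), stages = list(), outputs = list())
  for (f in c("counts", "design", "peaks", "genes", "go_map"))
    manifest$inputs[[f]] <- unname(tools::md5sum(cfg[[f]]))

  logMsg("reading inputs", verbose = verbose)
  peaks <- readBed(cfg$peaks, cfg$assembly)
  genes <- readBed(cfg$genes, cfg$assembly)
  counts <- readCountsTsv(cfg$counts)
  design <- readTsv(cfg$design)
  goMap <- readGoMap(cfg$go_map)
  me <- MethylExperiment(counts, design, peaks)
  colnames(me) <- design$sample

  logMsg("DMR stage (", cfg$experiment, ")", verbose = verbose)
  if (cfg$experiment == "human_MZD") {
    res <- twinDmrPipeline(me, dmrCfg)
  } else {
    res <- mouseDmrPipeline(me, dmrCfg)
  }
  dmr <- res$dmr
  writeTsv(data.frame(sample = names(res$norm$factors),
                      tmm_factor = unname(res$norm$factors),
                      lib_size = unname(res$norm$lib_size),
                      effective_lib_size = unname(res$norm$effective_lib_size)),
           file.path(out, "norm_factors.tsv"))
  bed <- asBedFrame(peaks)
  dmrOut <- cbind(bed[match(dmr$region_id, regionNames(peaks)),
                      c("chrom", "start", "end")], dmr)
  writeTsv(dmrOut, file.path(out, "dmr.tsv"), coordComment = TRUE)
  manifest$stages$dmr <- list(n_regions_tested = nrow(dmr),
                              n_significant = sum(dmr$significant))

  logMsg("clustering stage", verbose = verbose)
  clusters <- dbscanGenomic(peaks, clCfg)
  ccdmrs <- selectCcdmrs(clusters, dmr, clCfg)
  st <- clusterStats(ccdmrs)
  writeTsv(asBedFrame(clustersAsRegionSet(ccdmrs)),
           file.path(out, "clusters.bed"), coordComment = TRUE)
  writeTsv(data.frame(cluster_id = names(clusterMembers(ccdmrs)),
                      members = vapply(clusterMembers(ccdmrs),
                                       paste, "", collapse = ","),
                      min_p = mcols(clusterSpans(ccdmrs))$minP,
                      size_bp = mcols(clusterSpans(ccdmrs))$sizeBp),
           file.path(out, "clusters_members.tsv"))
  manifest$stages$cluster <- list(n_clusters = length(clusters),
                                  n_ccdmrs = length(ccdmrs),
                                  median_ccdmr_size_bp = st$median_size_bp)

  logMsg("annotation / GO stage", verbose = verbose)
  ann <- annotateClusters(ccdmrs, genes, goCfg)
  background <- sort(unique(unlist(
    annotateClusters(clusters, genes, goCfg)$cluster_genes)))
  enrichment <- NULL
  if (length(ann$gene_list) && length(background)) {
    fullTest <- hypergeomGo(ann$gene_list, background, goMap)
    scored <- debiasedGoScore(ann$cluster_genes, background, goMap, goCfg)
    scored <- empiricalGoP(scored, ann$cluster_genes, background, goMap,
                           goCfg)
    enrichment <- merge(scored, fullTest[, c("term", "p", "k")],
                        by = "term", sort = FALSE)
    enrichment <- enrichment[order(enrichment$score), ]
    writeTsv(enrichment, file.path(out, "enrichment.tsv"))
    exportRevigoInput(scored, fullTest, attr(goMap, "meta"),
                      file.path(out, "revigo_input.txt"), goCfg)
    manifest$stages$go <- list(n_terms = nrow(enrichment),
                               n_background_genes = length(background))
  } else {
    logMsg("no genes within reach of ccDMRs; enrichment skipped",
           verbose = verbose)
    manifest$stages$go <- list(n_terms = 0L)
  }

  if (!is.null(cfg$tracks_dir)) {
    logMsg("feature enrichment stage", verbose = verbose)
    files <- sort(list.files(cfg$tracks_dir, pattern = "\\.bed$",
                             full.names = TRUE))
    tracks <- stats::setNames(lapply(files, readBed, assembly = cfg$assembly),
                              sub("\\.bed$", "", basename(files)))
    isState <- grepl("__", names(tracks))
    dmrIds <- dmr$region_id[dmr$significant]
    if (any(!isState) && length(dmrIds)) {
      fe <- featureEnrichmentTable(dmrIds, peaks, tracks[!isState], enCfg)
      writeTsv(fe, file.path(out, "feature_enrichment.tsv"))
      manifest$stages$features <- list(n_tracks = sum(!isState))
    }
    if (any(isState) && length(ccdmrs) && !is.null(cfg$chrom_lengths)) {
      genome <- GenomeModel(cfg$assembly, unlist(cfg$chrom_lengths))
      z <- stateZscoreProfile(ccdmrs, tracks[isState], genome, enCfg)
      writeTsv(data.frame(cluster_id = rownames(z), z, check.names = FALSE),
               file.path(out, "state_z.tsv"))
      statesAvail <- unique(vapply(strsplit(colnames(z), "__", fixed = TRUE),
                                   `[[`, "", 2L))
      if (!all(enCfg$activation_states %in% statesAvail)) {
        logMsg("restricting activation states to those present in tracks",
               verbose = verbose)
        enCfg$activation_states <- intersect(enCfg$activation_states,
                                             statesAvail)
      }
      ta <- assignTissue(z, enCfg)
      writeTsv(ta, file.path(out, "tissue_assignment.tsv"))
      if (nrow(z) >= enCfg$k_groups)
        writeTsv(groupClusters(z, enCfg), file.path(out, "groups.tsv"))
      manifest$stages$states <- list(n_state_tracks = sum(isState))
    }
  }

  outFiles <- sort(list.files(out, full.names = TRUE, recursive = TRUE))
  outFiles <- outFiles[basename(outFiles) != "manifest.json"]
  manifest$outputs <- as.list(stats::setNames(unname(tools::md5sum(outFiles)),
                                              basename(outFiles)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logMsg("pipeline complete: ", out, verbose = verbose)
  invisible(manifest)
}
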