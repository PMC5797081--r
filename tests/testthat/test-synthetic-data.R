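# The synthetic-study generator: determinism, geometry of planted
# clusters, noise-model moments, and the planted effect size.

test_that("identical configurations give byte-identical artifacts", {
  cfg <- tinySimConfig(seed = 21)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  sim1 <- simulateGenome(cfg)
  me1 <- simulateCounts(cfg, "twin", sim1)
  writeSimulation(sim1, d1, list(twin = me1))
  sim2 <- simulateGenome(tinySimConfig(seed = 21))
  me2 <- simulateCounts(tinySimConfig(seed = 21), "twin", sim2)
  writeSimulation(sim2, d2, list(twin = me2))
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_identical(unname(h1), unname(h2))
  # a different seed changes the peaks
  sim3 <- simulateGenome(tinySimConfig(seed = 22))
  expect_false(identical(asBedFrame(sim1$peaks), asBedFrame(sim3$peaks)))
})

test_that("planted truth has the configured arithmetic and geometry", {
  cfg <- tinySimConfig(seed = 23, planted_cluster_count = 5,
                       dmrs_per_cluster = 4)
  sim <- simulateGenome(cfg)
  truth <- sim$truth
  expect_equal(nrow(truth$planted_dmrs), 20L)  # 5 clusters x 4 DMRs
  expect_equal(nrow(truth$planted_cluster_spans), 5L)
  expect_true(all(abs(truth$planted_dmrs$log2fc) == cfg$effect_log2fc))
  # every planted DMR lies inside exactly one planted span
  peaks <- asBedFrame(sim$peaks)
  pd <- peaks[match(truth$planted_dmrs$region_id, peaks$name), ]
  spans <- truth$planted_cluster_spans
  nHolders <- vapply(seq_len(nrow(pd)), function(i)
    sum(spans$chrom == pd$chrom[i] & spans$start <= pd$start[i] &
          spans$end >= pd$end[i]), numeric(1))
  expect_true(all(nHolders == 1))
  # peaks are non-overlapping after merge (layout is already disjoint)
  expect_equal(coveredBases(sim$peaks), coveredBases(mergeRegions(sim$peaks)))
  expect_equal(length(mergeRegions(sim$peaks)), length(sim$peaks))
  # planted-term genes sit within the annotation window of the spans
  genes <- asBedFrame(sim$genes)
  pg <- genes[match(truth$planted_genes, genes$name), ]
  for (i in seq_len(nrow(spans))) {
    near <- pg$chrom == spans$chrom[i] &
      pg$start < spans$end[i] + 1e5 & pg$end > spans$start[i] - 1e5
    expect_true(any(near))
  }
})

test_that("clustering the planted DMR positions alone recovers the truth", {
  cfg <- tinySimConfig(seed = 24)
  sim <- simulateGenome(cfg)
  peaks <- asBedFrame(sim$peaks)
  pd <- peaks[peaks$name %in% sim$truth$planted_dmrs$region_id, ]
  plantedOnly <- RegionSet(pd$chrom, pd$start, pd$end, "synthA",
                           name = pd$name)
  cl <- dbscanGenomic(plantedOnly, ClusterConfig(eps = 10000, min_pts = 2))
  expect_equal(length(cl), cfg$planted_cluster_count)
  expect_equal(length(noiseRegions(cl)), 0L)
  # spans match the recorded truth exactly
  spans <- asBedFrame(clustersAsRegionSet(cl))
  truthSpans <- sim$truth$planted_cluster_spans
  o <- order(truthSpans$chrom, truthSpans$start)
  expect_equal(spans$chrom, truthSpans$chrom[o])
  expect_equal(spans$start, truthSpans$start[o])
  expect_equal(spans$end, truthSpans$end[o])
})

test_that("counts match the NB variance law on non-DMR regions", {
  cfg <- tinySimConfig(seed = 25, n_regions = 20000, n_chroms = 4,
                       chrom_length = 3e7, planted_cluster_count = 0,
                       pair_effect_sd = 0, libsize_cv = 0)
  sim <- simulateGenome(cfg)
  me <- simulateCounts(cfg, "twin", sim)
  counts <- methCounts(me)
  # pooled moment check against var = mu + alpha mu^2, binned by mean
  mu <- rowMeans(counts)
  v <- apply(counts, 1, var)
  bins <- cut(mu, quantile(mu, seq(0, 1, 0.25)), include.lowest = TRUE)
  for (b in levels(bins)) {
    i <- bins == b
    expected <- mean(mu[i]) + cfg$nb_dispersion * mean(mu[i]^2)
    expect_equal(mean(v[i]), expected, tolerance = 0.1)
  }
})

test_that("the planted twin effect reproduces the configured fold change", {
  cfg <- tinySimConfig(seed = 26, baseline_mean = 50, effect_log2fc = 1.5,
                       planted_cluster_count = 25, n_regions = 3000,
                       frac_hyper = 1, pair_effect_sd = 0, libsize_cv = 0)
  sim <- simulateGenome(cfg)
  me <- simulateCounts(cfg, "twin", sim)
  counts <- methCounts(me)
  d <- studyDesign(me)
  planted <- sim$truth$planted_dmrs$region_id
  resp <- d$sample[d$pair_type == "MZD" & d$group == "responder"]
  nonr <- d$sample[d$pair_type == "MZD" & d$group == "nonresponder"]
  # 100 planted regions x 9 pairs of NB draws behind each mean: the
  # Monte-Carlo error of the pooled ratio is far below the 2^1.5 signal
  ratio <- mean(counts[planted, resp]) / mean(counts[planted, nonr])
  expect_equal(ratio, 2^1.5, tolerance = 0.05)
  # effect 0 collapses the ratio to 1
  meNull <- simulateCounts(cfg, "twin", sim, effectLog2fc = 0)
  cNull <- methCounts(meNull)
  expect_equal(mean(cNull[planted, resp]) / mean(cNull[planted, nonr]), 1,
               tolerance = 0.05)
  # MZC members share expected values: pooled ratio near 1 even with the
  # planted effect active
  mzc1 <- d$sample[d$pair_type == "MZC"][c(TRUE, FALSE)]
  mzc2 <- d$sample[d$pair_type == "MZC"][c(FALSE, TRUE)]
  expect_equal(mean(counts[planted, mzc1]) / mean(counts[planted, mzc2]), 1,
               tolerance = 0.05)
})

test_that("library-size factors and design frames follow the configuration", {
  cfg <- tinySimConfig(seed = 27, libsize_cv = 0)
  sim <- simulateGenome(cfg)
  me <- simulateCounts(cfg, "twin", sim)
  expect_true(all(studyDesign(me)$true_sf == 1))
  m0 <- simulateCounts(cfg, "mouse_F0", sim)
  d0 <- studyDesign(m0)
  expect_equal(sum(d0$group == "CT"), 6L)
  expect_equal(sum(d0$group == "RCF"), 10L)
  expect_equal(length(unique(d0$ip_pool)), 6L)
  m1 <- simulateCounts(cfg, "mouse_F1", sim)
  d1 <- studyDesign(m1)
  expect_equal(as.vector(table(d1$group)[c("CT", "RCF")]), c(5L, 7L))
  expect_error(simulateCounts(cfg, "fish", sim), "arg")
})

test_that("infeasible geometry is rejected before sampling", {
  expect_error(SimulationConfig(cluster_span = 20000), "cluster_span")
  cfgBad <- tinySimConfig(seed = 28, n_regions = 1500, chrom_length = 1e6)
  expect_error(simulateGenome(cfgBad), "infeasible")
})
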