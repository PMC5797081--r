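# Simplified lift-over, conserved-cluster intersection and the placement
# permutation p-value.

identityChain <- function(minMatch = 0.1) {
  ChainMap(data.frame(src_chrom = c("chr1", "chr1", "chr2"),
                      src_start = c(0, 50000, 0),
                      src_end = c(20000, 90000, 30000),
                      dst_chrom = c("chr1", "chr1", "chr2"),
                      dst_start = c(0, 50000, 0),
                      dst_end = c(20000, 90000, 30000)),
           "A", "B", minMatch = minMatch)
}

test_that("liftover maps, thresholds and splits per the minMatch rules", {
  # shifted destination block
  chain <- ChainMap(data.frame(src_chrom = "chr1", src_start = 1000,
                               src_end = 6000, dst_chrom = "chr7",
                               dst_start = 101000, dst_end = 106000),
                    "A", "B", minMatch = 0.1)
  # fully inside one block: image of identical length
  x <- rs("chr1", 2000, 3000, assembly = "A", name = "r1")
  out <- liftover(x, chain)
  expect_equal(asBedFrame(out$mapped),
               data.frame(chrom = "chr7", start = 102000, end = 103000,
                          name = "r1"))
  # 50 of 1000 bases covered (5%) is below minMatch 0.1
  y <- rs("chr1", 5950, 6950, assembly = "A", name = "r2")
  outY <- liftover(y, chain)
  expect_equal(length(outY$mapped), 0L)
  expect_equal(outY$unmapped$reason, "below_min_match")
  # straddling blocks that land on different chromosomes is a split
  chain2 <- ChainMap(data.frame(src_chrom = "chr1",
                                src_start = c(0, 1000),
                                src_end = c(1000, 2000),
                                dst_chrom = c("chrA", "chrB"),
                                dst_start = c(0, 0),
                                dst_end = c(1000, 1000)),
                     "A", "B", minMatch = 0.1)
  z <- rs("chr1", 500, 1500, assembly = "A", name = "r3")
  outZ <- liftover(z, chain2)
  expect_equal(outZ$unmapped$reason, "split")
  # chromosome with no blocks at all
  w <- rs("chrX", 0, 100, assembly = "A", name = "r4")
  expect_equal(liftover(w, chain)$unmapped$reason, "no_chain")
  # assembly mismatch refuses
  expect_error(liftover(rs("chr1", 0, 10, assembly = "B"), chain),
               "maps from")
})

test_that("identity-chain round trip and nesting/min_match properties", {
  chain <- identityChain()
  withr::local_seed(71)
  for (rep in 1:10) {
    st <- sample(0:85000, 5)
    x <- rs("chr1", st, st + 4000, assembly = "A",
            name = paste0("r", 1:5))
    out <- liftover(x, chain)
    if (length(out$mapped)) {
      dfIn <- asBedFrame(x); dfOut <- asBedFrame(out$mapped)
      m <- match(dfOut$name, dfIn$name)
      # on an identity chain the mapped hull is the covered part of the
      # input, hence contained in the input interval
      expect_true(all(dfOut$start >= dfIn$start[m] - 1e-9))
      expect_true(all(dfOut$end <= dfIn$end[m] + 1e-9))
      # fully-covered regions come back identical
      full <- dfIn$start[m] >= 0 & dfIn$start[m] >= 50000 &
        dfIn$end[m] <= 90000 | dfIn$end[m] <= 20000
      expect_equal(dfOut$start[full], dfIn$start[m][full])
      expect_equal(dfOut$end[full], dfIn$end[m][full])
    }
    # sub-region nesting whenever both map
    sub <- rs("chr1", st + 1000, st + 3000, assembly = "A",
              name = paste0("s", 1:5))
    outSub <- liftover(sub, chain)
    both <- intersect(sub("s", "r", regionNames(outSub$mapped) %||% character()),
                      regionNames(out$mapped) %||% character())
    if (length(both)) {
      big <- asBedFrame(out$mapped)
      small <- asBedFrame(outSub$mapped)
      for (id in both) {
        b <- big[big$name == id, ]
        s <- small[small$name == sub("r", "s", id), ]
        expect_gte(s$start, b$start)
        expect_lte(s$end, b$end)
      }
    }
  }
  # minMatch 0 maps every region touched by at least one block
  loose <- identityChain(minMatch = 0)
  touch <- rs("chr1", 19999, 45000, assembly = "A", name = "t")
  expect_equal(length(liftover(touch, loose)$mapped), 1L)
})

test_that("conservedClusters counts intersections and distinct hits", {
  human <- rs("chr1", c(0, 50000), c(10000, 60000), assembly = "B",
              name = c("h1", "h2"))
  # one human cluster overlapping two mouse clusters
  mouse <- rs("chr1", c(5000, 8000, 200000), c(7000, 12000, 210000),
              assembly = "B", name = c("m1", "m2", "m3"))
  out <- conservedClusters(human, mouse)
  expect_equal(out$n_conserved, 2L)
  expect_equal(out$n_human_ccdmrs_hit, 1L)
  # disjoint and identical sets
  expect_equal(conservedClusters(rs("chr2", 0, 10, assembly = "B",
                                    name = "hx"), mouse)$n_conserved, 0L)
  expect_equal(conservedClusters(mouse, mouse)$n_conserved, 3L)
  expect_error(conservedClusters(rs("chr1", 0, 1, assembly = "A",
                                    name = "h"), mouse), "mismatch")
})

test_that("permutation p attains its extremes and is monotone in overlap", {
  genome <- GenomeModel("B", c(chr1 = 1e6))
  mouse <- rs("chr1", seq(0, 9e5, by = 1e5), seq(0, 9e5, by = 1e5) + 1000,
              assembly = "B", name = paste0("m", 1:10))
  # saturated null: the mouse track covers the whole chromosome
  whole <- rs("chr1", 0, 1e6, assembly = "B", name = "mAll")
  human <- rs("chr1", c(100, 300000), c(5100, 305000), assembly = "B",
              name = c("h1", "h2"))
  permSat <- overlapPermutationP(human, whole, genome, B = 199, seed = 1)
  expect_equal(permSat$p, 1)
  # monotonicity: higher observed count can only lower p on fixed draws
  perm <- overlapPermutationP(human, mouse, genome, B = 199, seed = 2)
  pFor <- function(obs) (1 + sum(perm$null >= obs)) / (perm$B + 1)
  expect_true(all(diff(vapply(0:3, pFor, numeric(1))) <= 0))
  expect_error(overlapPermutationP(
    rs("chr1", 0, 2e6 - 1e5, assembly = "B", name = "big"),
    mouse, GenomeModel("B", c(chr1 = 1e6)), B = 199), "longer than")
})

test_that("permutation p is uniform under a random-placement null", {
  # the empirical p lives on the attainable grid of the overlap count;
  # a dense configuration keeps that grid fine enough for a KS check
  # against the continuous uniform
  withr::local_seed(72)
  genome <- GenomeModel("B", c(chr1 = 5e7))
  ms <- sort(sample.int(5e7 - 30000, 600))
  mouse <- rs("chr1", ms, ms + 30000, assembly = "B",
              name = paste0("m", 1:600))
  ps <- vapply(1:200, function(rep) {
    st <- sort(sample.int(5e7 - 20000, 300))
    human <- rs("chr1", st, st + 20000, assembly = "B",
                name = paste0("h", 1:300))
    overlapPermutationP(human, mouse, genome, B = 199, seed = 1000 + rep)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("a planted conserved configuration is detected end to end", {
  cfgSim <- tinySimConfig(seed = 77)
  sim <- simulateGenome(cfgSim)
  spans <- sim$truth$planted_cluster_spans
  human <- RegionSet(spans$chrom, spans$start, spans$end, "synthA",
                     name = spans$cluster)
  lift <- liftover(human, sim$chain)
  expect_gt(length(lift$mapped), 0L)
  # native ccDMRs at the lifted positions = a perfectly conserved setup
  mouseCc <- RegionSet(asBedFrame(lift$mapped)$chrom,
                       asBedFrame(lift$mapped)$start,
                       asBedFrame(lift$mapped)$end, "synthB",
                       name = paste0("mc", seq_len(length(lift$mapped))))
  res <- runCrossSpecies(human, sim$chain, mouseCc, sim$dst_genome,
                         B = 999, seed = 5)
  expect_equal(res$n_conserved, length(lift$mapped))
  expect_lte(res$p, 0.005)
  # map_coverage = 0 gives an empty chain and nothing maps
  simEmpty <- simulateGenome(tinySimConfig(seed = 78, map_coverage = 0))
  expect_equal(nrow(chainBlocks(simEmpty$chain)), 0L)
  liftEmpty <- liftover(human, simEmpty$chain)
  expect_equal(length(liftEmpty$mapped), 0L)
  expect_true(all(liftEmpty$unmapped$reason == "no_chain"))
})
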