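# Feature-track enrichment, chromatin-state z-profiles, tissue assignment
# and profile-based grouping.

makeUniverse <- function(n = 100, chromLen = 1e6) {
  st <- seq(0, by = chromLen %/% n, length.out = n)
  rs("chr1", st, st + 500, name = sprintf("u%03d", seq_len(n)))
}

test_that("fisher mode reproduces exact 2x2 arithmetic", {
  uni <- makeUniverse(200)
  df <- asBedFrame(uni)
  # track overlapping the first 100 universe regions
  track <- rs("chr1", df$start[1:100], df$end[1:100])
  # null association: 10 of first 100 and 10 of last 100 are DMRs
  dmrs <- c(df$name[1:10], df$name[101:110])
  out <- dmrFeatureEnrichment(dmrs, uni, track, EnrichConfig())
  expect_equal(out$odds_ratio, 1)
  expect_equal(out$p, 1)
  expect_equal(out$label, "none")
  # [[9,1],[1,9]] table: 10 DMRs, 9 overlap; 10 non-DMRs total in play
  uni2 <- makeUniverse(20)
  df2 <- asBedFrame(uni2)
  track2 <- rs("chr1", df2$start[c(1:9, 11)], df2$end[c(1:9, 11)])
  dmrs2 <- df2$name[1:10]
  out2 <- dmrFeatureEnrichment(dmrs2, uni2, track2, EnrichConfig())
  expect_equal(out2$odds_ratio, 81)
  expect_equal(out2$p, fisher.test(matrix(c(9, 1, 1, 9), 2))$p.value,
               tolerance = 1e-12)
  expect_equal(out2$p, 0.00115, tolerance = 0.01)
  expect_equal(out2$label, "enriched")
})

test_that("fisher mode matches the hypergeometric tail oracle for N <= 50", {
  withr::local_seed(61)
  for (rep in 1:15) {
    N <- sample(10:50, 1)
    uni <- makeUniverse(N)
    df <- asBedFrame(uni)
    inTrack <- sort(sample(N, sample(2:(N - 2), 1)))
    track <- rs("chr1", df$start[inTrack], df$end[inTrack])
    dmrs <- df$name[sample(N, sample(2:(N - 2), 1))]
    out <- dmrFeatureEnrichment(dmrs, uni, track, EnrichConfig())
    k <- sum(dmrs %in% df$name[inTrack])
    ref <- fisher.test(matrix(c(k, length(dmrs) - k,
                                length(inTrack) - k,
                                N - length(dmrs) - length(inTrack) + k),
                              2))$p.value
    expect_equal(out$p, ref, tolerance = 1e-12)
  }
})

test_that("degenerate tables and saturated permutation nulls are handled", {
  uni <- makeUniverse(30)
  df <- asBedFrame(uni)
  whole <- rs("chr1", 0, 1e6)  # covers every region
  out <- dmrFeatureEnrichment(df$name[1:5], uni, whole, EnrichConfig())
  expect_true(is.na(out$odds_ratio))
  expect_equal(out$p, 1)
  outP <- dmrFeatureEnrichment(df$name[1:5], uni, whole,
                               EnrichConfig(method = "placement_permutation",
                                            n_placements = 100))
  expect_true(is.na(out$odds_ratio))
  expect_equal(outP$p, 1)
})

test_that("permutation mode agrees with fisher mode in direction", {
  withr::local_seed(62)
  uni <- makeUniverse(200)
  df <- asBedFrame(uni)
  track <- rs("chr1", df$start[1:80], df$end[1:80])
  dmrs <- df$name[c(1:25, 190:194)]  # mostly inside the track
  fish <- dmrFeatureEnrichment(dmrs, uni, track, EnrichConfig())
  perm <- dmrFeatureEnrichment(dmrs, uni, track,
                               EnrichConfig(method = "placement_permutation",
                                            n_placements = 500, seed = 2))
  expect_equal(fish$label, "enriched")
  expect_equal(perm$label, "enriched")
  expect_lt(perm$p, 0.05)
})

makeProfileFixture <- function(nClusters = 6, seed = 63) {
  set.seed(seed)
  genome <- GenomeModel("toy", c(chr1 = 2e6))
  st <- seq(1e5, by = 3e5, length.out = nClusters)
  spans <- rs("chr1", st, st + 20000, name = sprintf("c%02d", 1:nClusters))
  cl <- new("ClusterSet", assembly = "toy",
            spans = {
              g <- granges(spans)
              mcols(g) <- NULL
              mcols(g)$id <- regionNames(spans)
              mcols(g)$nMembers <- 2L
              mcols(g)$sizeBp <- width(g)
              mcols(g)$minP <- 1e-4
              mcols(g)$containsSignificant <- TRUE
              g
            },
            members = setNames(lapply(1:nClusters, function(i) "x"),
                               regionNames(spans)),
            noise = character())
  list(genome = genome, clusters = cl, spans = spans)
}

test_that("state z-scores behave at the degenerate extremes", {
  fx <- makeProfileFixture()
  cfg <- EnrichConfig(n_placements = 200, seed = 3)
  full <- rs("chr1", 0, 2e6)                    # covers the chromosome
  empty <- rs("chr1", 1999000, 1999001)         # effectively unreachable
  sparse <- rs("chr1", 100000, 130000)          # covers cluster 1 only
  z <- stateZscoreProfile(fx$clusters,
                          list(T__full = full, T__none = empty,
                               T__sparse = sparse),
                          fx$genome, cfg)
  expect_equal(unname(z[, "T__full"]), rep(0, 6))  # obs = null = 1
  expect_equal(unname(z[1, "T__none"]), 0)
  expect_gt(z[1, "T__sparse"], 2)   # cluster inside the only interval
  expect_lt(z[3, "T__sparse"], 1)
})

test_that("z-profiles are invariant to a common translation", {
  fx <- makeProfileFixture()
  cfg <- EnrichConfig(n_placements = 300, seed = 4)
  track <- rs("chr1", c(100000, 700000), c(140000, 740000))
  z1 <- stateZscoreProfile(fx$clusters, list(A__TssA = track), fx$genome, cfg)
  # translate clusters and track by the same offset
  off <- 50000
  sp <- asBedFrame(fx$spans)
  cl2 <- fx$clusters
  g2 <- granges(rs(sp$chrom, sp$start + off, sp$end + off, name = sp$name))
  mcols(g2) <- mcols(clusterSpans(fx$clusters))
  cl2@spans <- g2
  track2 <- rs("chr1", c(100000, 700000) + off, c(140000, 740000) + off)
  z2 <- stateZscoreProfile(cl2, list(A__TssA = track2), fx$genome, cfg)
  expect_equal(unname(z1), unname(z2), tolerance = 0.3)  # same null law
})

test_that("null placements standardize z across clusters", {
  withr::local_seed(65)
  genome <- GenomeModel("toy", c(chr1 = 5e6))
  # many length-matched clusters placed uniformly at random
  n <- 400
  len <- 10000
  st <- floor(runif(n, 0, 5e6 - len))
  spans <- rs("chr1", sort(st), sort(st) + len, name = sprintf("c%03d", 1:n))
  g <- granges(spans); mcols(g) <- NULL
  mcols(g)$id <- regionNames(spans); mcols(g)$nMembers <- 2L
  mcols(g)$sizeBp <- width(g); mcols(g)$minP <- 1e-4
  mcols(g)$containsSignificant <- TRUE
  cl <- new("ClusterSet", assembly = "toy", spans = g,
            members = setNames(as.list(rep("x", n)), regionNames(spans)),
            noise = character())
  track <- rs("chr1", seq(0, 4.9e6, by = 1e5), seq(0, 4.9e6, by = 1e5) + 30000)
  z <- stateZscoreProfile(cl, list(T__TssA = track), genome,
                          EnrichConfig(n_placements = 300, seed = 5))
  expect_lt(abs(mean(z[, 1])), 0.15)
  expect_lt(abs(sd(z[, 1]) - 1), 0.15)
})

test_that("tissue assignment sums activation states and breaks ties canonically", {
  profile <- rbind(
    c1 = c(Brain__TssA = 2, Brain__Quies = 9, ESC__TssA = 1, ESC__Quies = 0),
    c2 = c(Brain__TssA = 0, Brain__Quies = 0, ESC__TssA = 0, ESC__Quies = 0))
  out <- assignTissue(profile, EnrichConfig(activation_states = "TssA"))
  expect_equal(out$tissue[out$cluster_id == "c1"], "Brain")  # 2 > 1; Quies ignored
  # all-zero profile falls to the first tissue in canonical order, flagged
  expect_equal(out$tissue[out$cluster_id == "c2"], "Brain")
  expect_true(out$ambiguous[out$cluster_id == "c2"])
  expect_false(out$ambiguous[out$cluster_id == "c1"])
  expect_error(assignTissue(profile, EnrichConfig(activation_states = "Enh")),
               "not present")
})

test_that("grouping recovers planted archetypes and is order-invariant", {
  withr::local_seed(66)
  arch <- matrix(rnorm(4 * 10, sd = 0.1), 4, 10) + 5 * diag(4)[, rep(1:4, length.out = 10)]
  prof <- arch[rep(1:4, each = 10), ] + matrix(rnorm(400, sd = 0.1), 40, 10)
  rownames(prof) <- sprintf("c%02d", 1:40)
  colnames(prof) <- paste0("T__S", 1:10)
  out <- groupClusters(prof, EnrichConfig(k_groups = 4))
  truthLab <- rep(1:4, each = 10)
  # adjusted-Rand-style check: partitions identical up to labels
  tab <- table(out$group, truthLab)
  expect_equal(sum(tab > 0), 4L)
  # shuffled input gives the same partition
  perm <- sample(40)
  out2 <- groupClusters(prof[perm, ], EnrichConfig(k_groups = 4))
  m <- match(out$cluster_id, out2$cluster_id)
  tab2 <- table(out$group, out2$group[m])
  expect_equal(sum(tab2 > 0), 4L)
  # k = 1 puts everything together; too-large k errors
  expect_equal(unique(groupClusters(prof, EnrichConfig(k_groups = 1))$group), 1L)
  expect_error(groupClusters(prof[1:3, ], EnrichConfig(k_groups = 4)),
               "smaller k")
})
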