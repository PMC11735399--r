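test_that("expected VAF follows the multiplicity relation and its domain", {
  expect_equal(expectedVAF(1, 1, 2), 0.5)
  expect_equal(expectedVAF(2, 0.5, 4), 1 / 3)
  expect_equal(expectedVAF(4, 1, 4), 1)      # all tumour copies mutated
  expect_equal(expectedVAF(3, 1, 3), 1)
  expect_error(expectedVAF(5, 0.5, 4), "multiplicity")
  expect_error(expectedVAF(1, 0, 2), "purity")
})

test_that("invalid simulator configurations name the offending field", {
  expect_error(simConfig(purityRange = c(0, 0.5)), "purityRange")
  expect_error(simConfig(meanDepth = 0), "meanDepth")
  expect_error(simConfig(wgdTruth = 3), "wgdTruth")
  expect_error(simConfig(nTruncal = -1), "nTruncal")
  expect_error(simConfig(noise = -0.1), "noise")
  expect_error(simConfig(scarTargets = list(foo = 1)), "scarTargets")
})

test_that("same config and seed give a byte-identical serialized case", {
  cfg <- simConfig(wgdTruth = 1, msaiEvents = 1, seed = 21)
  s1 <- simulateCase(cfg)
  s2 <- simulateCase(cfg)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  writeCase(s1$case, d1, truth = s1$truth)
  writeCase(s2$case, d2, truth = s2$truth)
  f1 <- sort(list.files(d1, full.names = TRUE))
  f2 <- sort(list.files(d2, full.names = TRUE))
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a simulated WGD footprint covers at least half the genome", {
  for (seed in c(3, 14, 27)) {
    sim <- simulateCase(simConfig(wgdTruth = 1, noise = 0, seed = seed))
    for (p in regions(sim$case))
      expect_gte(genomeFractionMajorGe(p, 2), 0.5)
    sim2 <- simulateCase(simConfig(wgdTruth = 2, noise = 0, seed = seed))
    for (p in regions(sim2$case))
      expect_gte(genomeFractionMajorGe(p, 3), 0.5)
  }
})

test_that("requested MSAI events appear in the truth with mirrored labels", {
  sim <- simulateCase(simConfig(msaiEvents = 2, noise = 0, seed = 5))
  expect_equal(nrow(sim$truth$msai), 2)
  for (h in sim$truth$msai$haplotypes) {
    labs <- sub(".*=", "", strsplit(h, ",")[[1]])
    expect_setequal(unique(labs), c("H1", "H2"))
  }
})

test_that("pooled read counts converge to the expected VAF", {
  ## >= 10,000 reads pooled over one region's truncal mutations
  cfg <- simConfig(nRegions = 1, purityRange = c(0.6, 0.6), meanDepth = 120,
                   nTruncal = 120, nSubclonalClusters = 0, seed = 31)
  sim <- simulateCase(cfg)
  cnt <- sim$case@mutCounts
  depth <- cnt$ref_count + cnt$alt_count
  expect_gte(sum(depth), 10000)
  pExp <- expectedVAF(1, 0.6, 2)
  pObs <- sum(cnt$alt_count) / sum(depth)
  se <- sqrt(pExp * (1 - pExp) / sum(depth))
  expect_lt(abs(pObs - pExp), 3 * se)
})

test_that("scar injection hits its targets exactly and rejects the infeasible", {
  flat <- flatProfile()
  expect_identical(injectScars(flat, list(lst = 0, tai = 0, hrd_loh = 0)),
                   flat)
  g <- toyGenome()
  p <- injectScars(flat, list(hrd_loh = 3))
  expect_equal(hrdLOHScore(p, g), 3)
  expect_equal(lstScore(p), 0)
  expect_equal(taiScore(p, g), 0)
  p2 <- injectScars(flat, list(tai = 2))
  expect_equal(taiScore(p2, g), 2)
  st <- segFrame(p2)
  tai <- st[st$M != st$m, ]
  expect_equal(nrow(tai), 2)
  cen <- centromeres(g)
  for (i in seq_len(nrow(tai))) {
    L <- chromLengths(g)[[tai$chrom[i]]]
    expect_true(tai$start[i] == 1 || tai$end[i] == L)   # telomere-bounded
    expect_false(tai$start[i] <= cen$start[cen$chrom == tai$chrom[i]] &&
                   tai$end[i] >= cen$end[cen$chrom == tai$chrom[i]])
  }
  ## more scar chromosomes than the toy genome has
  expect_error(injectScars(flat, list(hrd_loh = 6)), "capacity")
})

test_that("simulated cases honour exact scar targets in every region", {
  g <- toyGenome()
  for (seed in c(2, 9)) {
    tg <- list(lst = 3, tai = 2, hrd_loh = 1)
    sim <- simulateCase(simConfig(scarTargets = tg, noise = 0, seed = seed,
                                  wgdTruth = seed %% 2))
    for (p in regions(sim$case)) {
      expect_equal(lstScore(p), tg$lst)
      expect_equal(taiScore(p, g), tg$tai)
      expect_equal(hrdLOHScore(p, g), tg$hrd_loh)
    }
  }
})
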