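test_that("genome fractions are length-weighted and monotone in k", {
  p <- chromProfile(c(60, 40), major = c(2, 1), minor = c(1, 1))
  expect_equal(genomeFractionMajorGe(p, 0), 1)
  expect_equal(genomeFractionMajorGe(p, 2), 0.6)
  f <- vapply(0:6, function(k) genomeFractionMajorGe(p, k), numeric(1))
  expect_true(all(diff(f) <= 0))
  allTwo <- flatProfile(2, 1)
  expect_equal(genomeFractionMajorGe(allTwo, 2), 1)
  expect_error(genomeFractionMajorGe(RegionProfile("E",
    data.frame(chrom = "chrX", start = 1, end = 10, cn_major = 1,
               cn_minor = 1)), 2), "empty")
})

test_that("the WGD rule is inclusive at 50% and distinguishes 0/1/2 events", {
  expect_equal(nWGD(callWGD(flatProfile(2, 1))), 1L)   # uniform 2+1
  expect_equal(nWGD(callWGD(flatProfile(1, 1))), 0L)   # uniform 1+1
  ## major CN 3 over exactly half the genome, 2+1 elsewhere -> two events
  half <- chromProfile(c(50, 50), major = c(3, 2), minor = c(1, 1))
  gd <- callWGD(half)
  expect_equal(nWGD(gd), 2L)
  expect_equal(gd@fracMajorGe3, 0.5)
  expect_true(gd@borderline)
  ## just under the threshold stays at the lower call
  under <- chromProfile(c(49, 51), major = c(2, 1), minor = c(1, 1))
  expect_equal(nWGD(callWGD(under)), 0L)
})

test_that("sex chromosomes are excluded from fractions unless asked", {
  p <- RegionProfile("R1", data.frame(
    chrom = c("chr1", "chrX"), start = 1, end = c(100e6, 100e6),
    cn_major = c(2, 1), cn_minor = c(1, 0)))
  expect_equal(genomeFractionMajorGe(p, 2), 1)
  expect_equal(genomeFractionMajorGe(p, 2, excludeSex = FALSE), 0.5)
})

test_that("weighted ploidy averages total CN by segment length", {
  expect_equal(weightedPloidy(flatProfile(1, 1)), 2)
  expect_equal(weightedPloidy(flatProfile(2, 2)), 4)
  p <- chromProfile(c(50, 50), major = c(2, 1), minor = c(2, 1))
  expect_equal(weightedPloidy(p), 3)
})

test_that("harmonized segmentation is a fixed point preserving all summaries", {
  a <- RegionProfile("A", data.frame(chrom = "chr1", start = c(1, 50e6 + 1),
    end = c(50e6, 100e6), cn_major = c(2, 1), cn_minor = c(1, 1)))
  b <- RegionProfile("B", data.frame(chrom = "chr1", start = c(1, 30e6 + 1),
    end = c(30e6, 100e6), cn_major = c(3, 2), cn_minor = c(0, 1)))
  h <- harmonizeSegmentation(list(a, b))
  bp <- lapply(h, function(p) BiocGenerics::start(cnSegments(p)))
  expect_identical(bp[[1]], bp[[2]])
  expect_equal(sort(bp[[1]]), sort(c(1, 30e6 + 1, 50e6 + 1)))
  ## single region: unchanged
  expect_equal(segFrame(harmonizeSegmentation(list(a))[[1]]), segFrame(a))
  ## idempotence
  h2 <- harmonizeSegmentation(h)
  expect_equal(lapply(h2, segFrame), lapply(h, segFrame))
  ## preserved summaries, checked per region against the originals
  for (i in 1:2) {
    orig <- list(a, b)[[i]]
    expect_equal(weightedPloidy(h[[i]]), weightedPloidy(orig))
    for (k in 0:3)
      expect_equal(genomeFractionMajorGe(h[[i]], k),
                   genomeFractionMajorGe(orig, k))
    expect_equal(sum(BiocGenerics::width(cnSegments(h[[i]]))),
                 sum(BiocGenerics::width(cnSegments(orig))))
  }
  ## random profiles: harmonization never changes the scores either
  for (seed in c(4, 17)) {
    ps <- list(randomProfile(seed), randomProfile(seed + 100))
    chroms <- intersect(unique(segFrame(ps[[1]])$chrom),
                        unique(segFrame(ps[[2]])$chrom))
    ps <- lapply(ps, function(p) {
      st <- segFrame(p)
      st <- st[st$chrom %in% chroms, ]
      RegionProfile(regionID(p), data.frame(chrom = st$chrom,
        start = st$start, end = st$end, cn_major = st$M, cn_minor = st$m))
    })
    h <- harmonizeSegmentation(ps)
    for (i in seq_along(ps))
      expect_equal(weightedPloidy(h[[i]]), weightedPloidy(ps[[i]]))
  }
  expect_error(harmonizeSegmentation(list(a, flatProfile())),
               "inconsistent chromosome sets")
})
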