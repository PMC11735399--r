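test_that("LST counts large flanked transitions, with smoothing", {
  expect_equal(lstScore(flatProfile()), 0)
  ## 12 | 15 | 11 Mb with a CN step at both internal breakpoints
  p <- chromProfile(c(12, 15, 11), major = c(1, 2, 1), minor = c(1, 1, 1))
  expect_equal(lstScore(p), 2)
  expect_equal(oracleLST(p), 2)
  ## a 1 Mb sliver inserted mid-segment is smoothed away
  p2 <- chromProfile(c(12, 7, 1, 7, 11), major = c(1, 2, 2, 2, 1),
                     minor = c(1, 1, 2, 1, 1))
  expect_equal(lstScore(p2), 2)
  expect_equal(oracleLST(p2), 2)
  ## short flank defeats the count
  p3 <- chromProfile(c(8, 92), major = c(2, 1), minor = c(1, 1))
  expect_equal(lstScore(p3), 0)
})

test_that("TAI requires a telomere, spares the centromere, excludes whole-chromosome", {
  g <- toyGenome()
  expect_equal(taiScore(flatProfile(), g), 0)
  p <- chromProfile(c(30, 70), major = c(2, 1), minor = c(1, 1))
  expect_equal(taiScore(p, g), 1)
  whole <- chromProfile(100, 2, 1)
  expect_equal(taiScore(whole, g), 0)
  expect_equal(oracleTAI(whole), 0)
  ## imbalance spanning the whole centromere from a telomere is excluded
  crossing <- chromProfile(c(60, 40), major = c(2, 1), minor = c(1, 1))
  expect_equal(taiScore(crossing, g), 0)
  ## interior imbalance never counts
  interior <- chromProfile(c(20, 20, 60), major = c(1, 2, 1),
                           minor = c(1, 1, 1))
  expect_equal(taiScore(interior, g), 0)
  expect_error(taiScore(chromProfile(120, 2, 1), g), "beyond")
})

test_that("HRD-LOH counts long non-whole-chromosome LOH segments", {
  g <- toyGenome()
  expect_equal(hrdLOHScore(flatProfile(), g), 0)
  p <- chromProfile(c(40, 20, 40), major = c(1, 1, 1), minor = c(1, 0, 1))
  expect_equal(hrdLOHScore(p, g), 1)
  whole <- chromProfile(100, 1, 0)
  expect_equal(hrdLOHScore(whole, g), 0)
  short <- chromProfile(c(40, 14, 46), major = 1, minor = c(1, 0, 1))
  expect_equal(hrdLOHScore(short, g), 0)   # 14 Mb < 15 Mb threshold
})

test_that("wGII measures ploidy-relative deviation per chromosome", {
  expect_equal(wgii(flatProfile(1, 1)), 0)
  expect_equal(wgii(flatProfile(2, 2)), 0)  # flat tetraploid, not 'all gained'
  lens <- chromLengths(toyGenome())
  seg <- data.frame(chrom = names(lens), start = 1, end = lens,
                    cn_major = c(3, 1, 1, 1, 1), cn_minor = 1)
  expect_equal(wgii(RegionProfile("R1", seg)), 0.2)
})

test_that("all scores match the brute-force oracles on random profiles", {
  ## spot check here; the 1,000-profile sweep runs in the acceptance suite
  g <- toyGenome()
  for (seed in 1:50) {
    p <- randomProfile(seed)
    expect_identical(lstScore(p), oracleLST(p), label = paste("lst", seed))
    expect_identical(taiScore(p, g), oracleTAI(p),
                     label = paste("tai", seed))
    expect_identical(hrdLOHScore(p, g), oracleHRDLOH(p),
                     label = paste("loh", seed))
    expect_equal(wgii(p), oracleWGII(p), label = paste("wgii", seed))
  }
})

test_that("scores are invariant to splitting segments with identical CN", {
  g <- toyGenome()
  splitSegs <- function(p, seed) {
    set.seed(seed)
    st <- segFrame(p)
    rows <- lapply(seq_len(nrow(st)), function(i) {
      w <- st$end[i] - st$start[i] + 1
      if (w < 4 || runif(1) < 0.5) return(st[i, ])
      cut <- st$start[i] + sample.int(w - 2, 1)
      rbind(data.frame(chrom = st$chrom[i], start = st$start[i], end = cut,
                       M = st$M[i], m = st$m[i]),
            data.frame(chrom = st$chrom[i], start = cut + 1, end = st$end[i],
                       M = st$M[i], m = st$m[i]))
    })
    df <- do.call(rbind, rows)
    RegionProfile(regionID(p), data.frame(chrom = df$chrom, start = df$start,
      end = df$end, cn_major = df$M, cn_minor = df$m))
  }
  for (seed in c(3, 11, 25)) {
    p <- randomProfile(seed)
    q <- splitSegs(p, seed + 1)
    expect_identical(lstScore(q), lstScore(p))
    expect_identical(taiScore(q, g), taiScore(p, g))
    expect_identical(hrdLOHScore(q, g), hrdLOHScore(p, g))
    expect_equal(wgii(q), wgii(p))
  }
})

test_that("wGII is invariant under uniform copy-number doubling", {
  for (seed in c(2, 9, 30)) {
    p <- randomProfile(seed)
    st <- segFrame(p)
    doubled <- RegionProfile(regionID(p), data.frame(chrom = st$chrom,
      start = st$start, end = st$end, cn_major = 2 * st$M,
      cn_minor = 2 * st$m))
    expect_equal(wgii(doubled), wgii(p))
  }
})

test_that("permutation bands behave at the degenerate extremes", {
  ## constant scores: observed 0, P = 1
  res <- permutationCorrelation(rep(2, 8), rep(c(0, 1), 4), nPerm = 99,
                                seed = 1)
  expect_equal(res$observed, 0)
  expect_equal(res$p, 1)
  ## perfect separation: observed exceeds every sampled permutation, so P
  ## sits at the add-one floor (groups large enough that no permutation
  ## reproduces the observed split)
  x <- c(1:12, 101:112)
  grp <- rep(c(0, 1), each = 12)
  res2 <- permutationCorrelation(x, grp, nPerm = 999, seed = 1)
  expect_equal(res2$p, 0.001)
  res3 <- permutationCorrelation(x, grp, nPerm = 999, seed = 1)
  expect_identical(res2$null_q95, res3$null_q95)  # seed determinism
  expect_error(permutationCorrelation(1:4, rep(1, 4), nPerm = 9),
               "two groups")
  res4 <- permutationCorrelation(x, grp, nPerm = 99, seed = 2,
                                 statistic = "spearman")
  expect_gt(res4$observed, 0.8)  # maximal given the tied binary ranks
})
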