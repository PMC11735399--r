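test_that("mutation copy number inverts the VAF relation", {
  expect_equal(mutationCopyNumber(0.5, 1, 2), 1)
  expect_equal(mutationCopyNumber(1 / 3, 0.5, 4), 2)
  expect_equal(mutationCopyNumber(0, 0.7, 3), 0)
  ## round trip with expectedVAF across a grid
  for (m in 1:3) for (rho in c(0.3, 0.6, 1)) for (T in 3:5)
    expect_equal(mutationCopyNumber(expectedVAF(m, rho, T), rho, T), m)
  expect_error(mutationCopyNumber(0.5, 0, 2), "purity")
})

test_that("multiplicity rounding is ties-to-even and clamped", {
  expect_equal(roundMultiplicity(1.5, 4), 2L)
  expect_equal(roundMultiplicity(2.5, 4), 2L)  # banker's rounding
  expect_equal(roundMultiplicity(0.2, 4), 1L)  # clamp up for present mutations
  expect_equal(roundMultiplicity(9.7, 4), 4L)  # clamp to total CN
})

test_that("clonality follows the trunk CI overlap rule with the 0.9 floor", {
  trunk <- list(mean = 0.97, low = 0.92, high = 1.0)
  expect_equal(classifyClonality(list(mean = 0.95, low = 0.85, high = 1.0),
                                 trunk), "clonal")
  expect_equal(classifyClonality(list(mean = 0.3, low = 0.2, high = 0.4),
                                 trunk), "subclonal")
  expect_equal(classifyClonality(list(mean = 0, low = 0, high = 0), trunk),
               "absent")
  ## the floor binds: trunk CI [0.5, 1] acts as [0.9, 1]
  looseTrunk <- list(mean = 0.9, low = 0.5, high = 1.0)
  expect_equal(classifyClonality(list(mean = 0.7, low = 0.6, high = 0.85),
                                 looseTrunk), "subclonal")
  expect_equal(classifyClonality(list(mean = 0.92, low = 0.88, high = 0.95),
                                 looseTrunk), "clonal")
  expect_error(classifyClonality(list(mean = 1), trunk), "mean")
})

test_that("the clonal/subclonal/absent partition is exhaustive and exclusive", {
  trunk <- list(mean = 0.97, low = 0.92, high = 1.0)
  set.seed(8)
  for (i in 1:200) {
    mn <- runif(1, 0, 1.1)
    lo <- max(0, mn - runif(1, 0, 0.3))
    hi <- mn + runif(1, 0, 0.3)
    lab <- classifyClonality(list(mean = mn, low = lo, high = hi), trunk)
    expect_true(lab %in% c("clonal", "subclonal", "absent"))
    if (mn == 0) expect_false(lab == "subclonal")
  }
})

test_that("early/late timing follows the WGD-ploidy rule", {
  expect_equal(timeMutationVsWGD(2, 2, 1L), "early")
  expect_equal(timeMutationVsWGD(1, 2, 1L), "late")
  expect_equal(timeMutationVsWGD(2, 2, 0L), "not_applicable")
  expect_equal(timeMutationVsWGD(1, 1, 1L), "not_applicable")  # lost locus
  expect_equal(timeMutationVsWGD(4, 4, 2L), "early")
  gd <- callWGD(flatProfile(2, 2))
  expect_equal(timeMutationVsWGD(2, 2, gd), "early")
  expect_error(timeMutationVsWGD(5, 2, 1L, cnTotal = 4), "exceeds")
})

test_that("case-level clonality is invariant to region order", {
  sim <- simulateCase(simConfig(wgdTruth = 1, seed = 44))
  cs <- estimateClusterCCF(sim$case, seed = 1)
  cl1 <- caseClonality(cs)
  csRev <- cs
  csRev@regions <- rev(cs@regions)
  cl2 <- caseClonality(csRev)
  expect_identical(cl1$byCluster, cl2$byCluster)
})

test_that("noise-free pure cases recover clonality and timing exactly", {
  for (seed in c(12, 33)) {
    sim <- simulateCase(simConfig(wgdTruth = 1, noise = 0,
                                  purityRange = c(1, 1), seed = seed))
    cs <- estimateClusterCCF(sim$case, seed = 1)
    tm <- timeMutations(cs, 1L)
    truth <- sim$truth$mutations
    cmp <- merge(tm, truth, by = "mut_id")
    expect_identical(cmp$clonality.x, cmp$clonality.y)
    clonal <- cmp$clonality.y == "clonal"
    expect_identical(cmp$timing.x[clonal], cmp$timing.y[clonal])
    expect_identical(cmp$multiplicity.x[clonal],
                     as.integer(cmp$multiplicity.y[clonal]))
  }
})
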