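test_that("site enumeration matches a brute-force oracle exactly", {
  ## a handful here; the full 100-CDS sweep runs in the acceptance suite
  for (seed in 1:10) {
    cds <- randomCDS(sample(5:30, 1), seed)
    sp <- if (seed %% 2) uniformSpectrum() else randomSpectrum(seed)
    expect_equal(expectedNSCounts(cds, sp),
                 oracleNSCounts(cds, spectrumRates(sp)), tolerance = 1e-12)
  }
})

test_that("a spectrum concentrated on an absent class yields zero rates", {
  cds <- "AAAAAAAAA"  # contexts AAA only (with wrap-around)
  rates <- setNames(rep(0, 96), trinucClasses())
  rates["C[C>T]C"] <- 1
  sp <- spectrumModel(rates)
  expect_equal(unname(expectedNSCounts(cds, sp)), c(0, 0))
})

test_that("expected-rate ratios are invariant to spectrum rescaling", {
  cds <- randomCDS(40, 7)
  r <- setNames(stats::rgamma(96, 2), trinucClasses())
  a <- expectedNSCounts(cds, spectrumModel(r))
  b <- expectedNSCounts(cds, spectrumModel(r * 37.5))
  expect_equal(a[["n_exp"]] / a[["s_exp"]], b[["n_exp"]] / b[["s_exp"]])
})

test_that("enumeration rejects malformed coding sequences", {
  expect_error(enumerateSites("ATGA"), "multiple of 3")
  expect_error(enumerateSites("ATGNNN"), "alphabet")
  expect_error(enumerateSites("ATGTAAGGG"), "premature stop")
})

test_that("dN/dS is 1 for counts proportional to expectation and scales", {
  genes <- toyGeneSet(nGenes = 1, nCodons = 120, seed = 5)
  e <- expectedNSCounts(genes[[1]])
  ## build observed mutations exactly proportional to the expected rates
  k <- 20
  nObs <- round(k * e[["n_exp"]])
  sObs <- round(k * e[["s_exp"]])
  muts <- data.frame(consequence = c(rep("missense", nObs),
                                     rep("synonymous", sObs)))
  res <- dndsEstimate(muts, genes = genes)
  expect_equal(res$dnds, (nObs / e[["n_exp"]]) / (sObs / e[["s_exp"]]))
  expect_equal(res$dnds, 1, tolerance = 0.01)  # rounding of counts only
  expect_true(res$ci_low <= res$dnds && res$dnds <= res$ci_high)
  ## doubling only the non-synonymous counts doubles the point estimate
  muts2 <- data.frame(consequence = c(rep("missense", 2 * nObs),
                                      rep("synonymous", sObs)))
  res2 <- dndsEstimate(muts2, genes = genes)
  expect_equal(res2$dnds / res$dnds, 2, tolerance = 1e-9)
  ## degenerate inputs are errors, not silent zeros
  expect_error(dndsEstimate(muts[0, , drop = FALSE], genes = genes),
               "no mutations")
})

test_that("zero synonymous observations flag an infinite upper bound", {
  genes <- toyGeneSet(nGenes = 1, nCodons = 60, seed = 2)
  muts <- data.frame(consequence = rep("missense", 10))
  res <- dndsEstimate(muts, genes = genes)
  expect_identical(res$flag, "s_obs=0")
  expect_equal(res$ci_high, Inf)
})

test_that("strata are estimated independently and labelled", {
  genes <- toyGeneSet(nGenes = 1, nCodons = 100, seed = 3)
  m <- simulateNeutralMutations(genes, nMut = 120, seed = 5)
  strata <- rep(c("clonal_early", "clonal_late"), 60)
  res <- dndsEstimate(m, strata = strata, genes = genes)
  expect_setequal(res$stratum, c("clonal_early", "clonal_late"))
  expect_equal(res$n_obs + res$s_obs, c(60L, 60L))
})

test_that("chi-squared enrichment matches the closed form and its symmetry", {
  expect_equal(enrichmentTest(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  t2 <- matrix(c(20, 0, 0, 20), 2)
  expect_equal(enrichmentTest(t2)$statistic, 40)
  expect_equal(enrichmentTest(t2)$statistic, oracleChi2(t2))
  set.seed(9)
  for (i in 1:20) {
    t <- matrix(sample(1:40, 4, replace = TRUE), 2)
    expect_equal(enrichmentTest(t)$statistic, oracleChi2(t),
                 tolerance = 1e-12)
    expect_equal(enrichmentTest(t[2:1, ])$statistic,
                 enrichmentTest(t)$statistic, tolerance = 1e-12)
  }
  expect_error(enrichmentTest(matrix(c(0, 0, 5, 5), 2)), "margin")
  expect_type(enrichmentTest(t2, method = "fisher")$p.value, "double")
})
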