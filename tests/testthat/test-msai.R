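test_that("SNP phasing assigns mirrored regions to opposite haplotypes", {
  baf <- cbind(A = c(0.8, 0.2, 0.8), B = c(0.8, 0.2, 0.8))
  ph <- phaseSNPs(baf, minSnps = 3)
  expect_identical(unname(ph$haplotype), c("H1", "H1"))
  baf2 <- cbind(A = c(0.8, 0.2, 0.8), B = c(0.2, 0.8, 0.2))
  ph2 <- phaseSNPs(baf2, minSnps = 3)
  expect_identical(unname(ph2$haplotype[c("A", "B")]), c("H1", "H2"))
  ## balanced region stays unassigned
  baf3 <- cbind(A = c(0.8, 0.2, 0.8), C = c(0.5, 0.5, 0.5))
  ph3 <- phaseSNPs(baf3, minSnps = 3)
  expect_true(is.na(ph3$haplotype[["C"]]))
  ## no imbalance anywhere is a no-signal result, not an error
  ph4 <- phaseSNPs(cbind(A = rep(0.5, 5), B = rep(0.5, 5)))
  expect_identical(ph4$status, "no_signal")
  ph5 <- phaseSNPs(baf2, minSnps = 10)
  expect_identical(ph5$status, "insufficient_snps")
})

test_that("haplotype labels form a consistent two-colouring under flips", {
  set.seed(6)
  n <- 20
  hapTruth <- c(A = 1, B = 2, C = 1, D = 2)
  base <- ifelse(runif(n) > 0.5, 0.8, 0.2)  # shared per-SNP major pattern
  baf <- sapply(hapTruth, function(h) if (h == 2) 1 - base else base)
  ph <- phaseSNPs(baf, minSnps = 5)
  mirrored <- outer(ph$haplotype, ph$haplotype, "!=")
  truthMir <- outer(hapTruth, hapTruth, "!=")
  expect_identical(unname(mirrored), unname(truthMir))
})

test_that("injected mirrored events are recovered; shared losses are not", {
  sim <- simulateCase(simConfig(msaiEvents = 2, noise = 0, seed = 7,
                                purityRange = c(0.5, 0.8)))
  ev <- detectMSAI(sim$case)
  expect_equal(nrow(ev), 2)
  expect_identical(ev$class, rep("loss/LOH", 2))
  expect_equal(ev$start, sim$truth$msai$start)
  expect_identical(ev$regions, sim$truth$msai$haplotypes)
  expect_true(all(nzchar(ev$cytobands)))
  ## a case with only shared (same-haplotype) SCNAs yields nothing
  sim0 <- simulateCase(simConfig(msaiEvents = 0, noise = 0, seed = 8))
  expect_equal(nrow(detectMSAI(sim0$case)), 0)
})

test_that("region order does not change the detected event set", {
  sim <- simulateCase(simConfig(msaiEvents = 1, noise = 0, seed = 13,
                                purityRange = c(0.5, 0.8)))
  ev1 <- detectMSAI(sim$case)
  shuffled <- sim$case
  shuffled@regions <- rev(shuffled@regions)
  ev2 <- detectMSAI(shuffled)
  expect_equal(ev1[c("chrom", "start", "end", "class")],
               ev2[c("chrom", "start", "end", "class")])
  ## membership of the mirrored set is preserved even if H1/H2 swap
  split1 <- sort(strsplit(ev1$regions, ",")[[1]])
  split2 <- sort(strsplit(ev2$regions, ",")[[1]])
  r1 <- sub("=.*", "", split1)
  expect_identical(r1, sub("=.*", "", split2))
})

test_that("per-cytoband rates count each tumour once", {
  bands <- toyCytobands()
  ev <- data.frame(chrom = "chr1", start = 1e6, end = 12e6,
                   class = "loss/LOH", regions = "R1=H1,R2=H2",
                   n_snps = 10L, mean_dev = 0.2, cytobands = "1p5,1p4")
  cohort <- list(T1 = ev, T2 = ev[0, ], T3 = ev, T4 = ev[0, ],
                 T5 = ev, T6 = ev[0, ], T7 = ev[0, ], T8 = ev[0, ],
                 T9 = ev[0, ], T10 = ev[0, ])
  rates <- cytobandMSAIRate(cohort, bands)
  expect_equal(rates$proportion[rates$band == "1p5"], 0.3)
  ## the event spans two bands and increments both
  expect_equal(rates$proportion[rates$band == "1p4"], 0.3)
  expect_equal(sum(rates$proportion > 0), 2)
  ## empty cohort events give all-zero proportions
  none <- cytobandMSAIRate(lapply(cohort, function(x) x[0, ]), bands)
  expect_true(all(none$proportion == 0))
  expect_error(cytobandMSAIRate(list(), bands), "empty")
})

test_that("empirical P respects the add-one floor and reproducibility", {
  bands <- toyCytobands()
  ev <- data.frame(chrom = "chr1", start = 1e6, end = 3e6,
                   class = "loss/LOH", regions = "R1=H1,R2=H2",
                   n_snps = 10L, mean_dev = 0.2, cytobands = "1p5")
  cohort <- lapply(1:8, function(i) ev)
  names(cohort) <- paste0("T", 1:8)
  res <- msaiEmpiricalP(cohort, bands, band = "1p5", nPerm = 99, seed = 3)
  expect_gte(res$p, 1 / 100)
  expect_lte(res$p, 1)
  res2 <- msaiEmpiricalP(cohort, bands, band = "1p5", nPerm = 99, seed = 3)
  expect_identical(res$p, res2$p)
  ## observed proportion 0 gives P = 1
  empty <- lapply(cohort, function(x) x[0, ])
  resE <- msaiEmpiricalP(empty, bands, band = "2q3", nPerm = 49, seed = 1)
  expect_equal(resE$p, 1)
  expect_error(msaiEmpiricalP(cohort, bands, band = "nope", nPerm = 9),
               "unknown cytoband")
})
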