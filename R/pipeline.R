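## End-to-end cohort pipeline: simulate or load -> purity floor -> WGD ->
## clonality/timing -> dN/dS -> MSAI -> scars -> permutation statistics ->
## JSON + TSV report.

#' Build a pipeline configuration
#'
#' Either \code{inputDir} (a directory of per-tumour case sub-directories
#' as written by \code{\link{writeCase}}) or \code{simulate} (a list of
#' \code{\link{simulateCohort}} arguments, e.g.
#' \code{list(nTumours = 20, nRegions = 3)}) must be given.
#'
#' @param inputDir Cohort input directory, or NULL to simulate.
#' @param simulate List of arguments for \code{\link{simulateCohort}}.
#' @param outputDir Where stage outputs and the report are written.
#' @param seed Master seed; recorded in the report for provenance.
#' @param minPurity Purity floor below which regions are excluded
#'   (default 0.10).
#' @param wgdThreshold Genome fraction for the WGD rule (default 0.5).
#' @param aiThreshold,minSnps MSAI phasing parameters.
#' @param nPerm Permutations for empirical P values and confidence bands.
#' @param band Cytoband(s) whose empirical P is highlighted in the report;
#'   NULL highlights the band with the highest MSAI proportion.
#' @return A validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(inputDir = NULL,
                           simulate = list(nTumours = 20, nRegions = 3),
                           outputDir = tempfile("tumourEvo_run_"),
                           seed = 1, minPurity = 0.10, wgdThreshold = 0.5,
                           aiThreshold = 0.08, minSnps = 5, nPerm = 199,
                           band = NULL) {
  cfg <- list(inputDir = inputDir, simulate = simulate,
              outputDir = outputDir, seed = as.integer(seed),
              minPurity = minPurity, wgdThreshold = wgdThreshold,
              aiThreshold = aiThreshold, minSnps = minSnps,
              nPerm = as.integer(nPerm), band = band)
  if (is.null(cfg$inputDir) && is.null(cfg$simulate))
    stop("one of 'inputDir' or 'simulate' is required")
  if (cfg$minPurity < 0 || cfg$minPurity > 1)
    stop("'minPurity' must be a fraction")
  if (cfg$wgdThreshold <= 0 || cfg$wgdThreshold > 1)
    stop("'wgdThreshold' must be in (0, 1]")
  if (cfg$nPerm < 1) stop("'nPerm' must be >= 1")
  class(cfg) <- "PipelineConfig"
  cfg
}

## stable hash of the analysis-relevant configuration (the output location
## does not change results, so it is not part of the provenance hash)
.configHash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outputDir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full cohort pipeline
#'
#' Loads or simulates a cohort, applies the purity floor, and runs every
#' analysis stage, writing per-stage TSV tables and a JSON report into
#' \code{config$outputDir}. The run is deterministic given the
#' configuration and seed: repeating it yields byte-identical reports.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @return The cohort report (list), invisibly; the same content is in
#'   \code{<outputDir>/report.json}.
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(simulate = list(nTumours = 4), nPerm = 49, seed = 2)
#' rep <- runPipeline(cfg)
#' rep$cohort$wgd_prevalence
#' }
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  exclusions <- data.frame(tumour = character(), region = character(),
                           purity = numeric(), stringsAsFactors = FALSE)

  ## ---- load or simulate --------------------------------------------------
  if (!is.null(config$inputDir)) {
    dirs <- list.dirs(config$inputDir, recursive = FALSE)
    if (!length(dirs)) stop("no case directories under ", config$inputDir)
    loaded <- lapply(dirs, function(d) {
      res <- readCase(d, minPurity = config$minPurity)
      if (length(res$excluded)) {
        pur <- setNames(res$truth$purity, names(res$truth$purity))
        exclusions <<- rbind(exclusions, data.frame(
          tumour = tumourID(res$case), region = res$excluded,
          purity = NA_real_, stringsAsFactors = FALSE))
      }
      res
    })
    cases <- lapply(loaded, `[[`, "case")
    truths <- lapply(loaded, `[[`, "truth")
  } else {
    simArgs <- config$simulate
    simArgs$seed <- config$seed
    sims <- do.call(simulateCohort, simArgs)
    cases <- lapply(sims, `[[`, "case")
    truths <- lapply(sims, `[[`, "truth")
    ## purity floor also applies to simulated regions
    kept <- lapply(cases, function(cs) {
      drop <- vapply(cs@regions, function(r) purity(r) < config$minPurity,
                     logical(1))
      if (any(drop)) {
        exclusions <<- rbind(exclusions, data.frame(
          tumour = tumourID(cs),
          region = vapply(cs@regions[drop], regionID, character(1)),
          purity = vapply(cs@regions[drop], purity, numeric(1)),
          stringsAsFactors = FALSE))
        keep <- vapply(cs@regions, function(r)
          purity(r) >= config$minPurity, logical(1))
        cs@regions <- cs@regions[keep]
        kr <- vapply(cs@regions, regionID, character(1))
        cs@mutCounts <- cs@mutCounts[cs@mutCounts$region %in% kr, ]
        cs@snps <- cs@snps[cs@snps$region %in% kr, ]
      }
      cs
    })
    cases <- kept
  }
  names(cases) <- vapply(cases, tumourID, character(1))
  names(truths) <- names(cases)

  genome <- cases[[1]]@genome
  bands <- toyCytobands(genome)

  ## ---- per-tumour stages -------------------------------------------------
  wgdRows <- list(); timingTabs <- list(); scarRows <- list()
  eventsByTumour <- vector("list", length(cases))
  names(eventsByTumour) <- names(cases)
  for (tid in names(cases)) {
    cs <- cases[[tid]]
    gd <- callWGD(cs, threshold = config$wgdThreshold)
    wgdRows[[tid]] <- data.frame(
      tumour = tid, region = names(gd$perRegion),
      n_wgd = vapply(gd$perRegion, nWGD, integer(1)),
      frac_major_ge2 = vapply(gd$perRegion, function(g) g@fracMajorGe2,
                              numeric(1)),
      consensus = gd$consensus,
      histology = if (is.null(cs@meta$histology)) NA else cs@meta$histology,
      stringsAsFactors = FALSE)
    cs <- estimateClusterCCF(cs, seed = config$seed)
    tm <- timeMutations(cs, gd$consensus)
    if (nrow(tm)) tm <- cbind(tumour = tid, tm)
    timingTabs[[tid]] <- tm
    sc <- do.call(rbind, lapply(cs@regions, scarScores, annotation = genome))
    scarRows[[tid]] <- cbind(tumour = tid, sc)
    eventsByTumour[[tid]] <- detectMSAI(cs, bands,
                                        aiThreshold = config$aiThreshold,
                                        minSnps = config$minSnps)
    cases[[tid]] <- cs
  }
  wgdTab <- do.call(rbind, wgdRows)
  timingTab <- do.call(rbind, timingTabs)
  scarTab <- do.call(rbind, scarRows)
  rownames(wgdTab) <- rownames(scarTab) <- NULL
  if (!is.null(timingTab)) rownames(timingTab) <- NULL

  ## ---- cohort-level statistics ------------------------------------------
  perTumour <- unique(wgdTab[c("tumour", "consensus", "histology")])
  prevalence <- lapply(split(perTumour, perTumour$histology), function(d)
    mean(d$consensus >= 1))
  enrich <- NULL
  t22 <- table(factor(perTumour$consensus >= 1, levels = c(FALSE, TRUE)),
               factor(perTumour$histology, levels = c("LUAD", "LUSC")))
  if (all(rowSums(t22) > 0) && all(colSums(t22) > 0))
    enrich <- enrichmentTest(as.matrix(t22))

  dndsTab <- NULL
  if (!is.null(timingTab) && nrow(timingTab)) {
    mutMeta <- do.call(rbind, lapply(names(cases), function(tid) {
      mm <- cases[[tid]]@mutations
      if (nrow(mm)) cbind(tumour = tid, mm) else NULL
    }))
    key <- paste(timingTab$tumour, timingTab$mut_id)
    mkey <- paste(mutMeta$tumour, mutMeta$mut_id)
    mutMeta <- mutMeta[match(key, mkey), ]
    strata <- ifelse(timingTab$clonality == "clonal" &
                       timingTab$timing == "early", "clonal_early",
              ifelse(timingTab$clonality == "clonal" &
                       timingTab$timing == "late", "clonal_late",
              ifelse(timingTab$clonality == "subclonal", "subclonal",
                     "clonal_untimed")))
    dndsTab <- rbind(
      dndsEstimate(mutMeta, strata = strata),
      dndsEstimate(mutMeta, strata = rep("all", nrow(mutMeta))))
  }

  msaiRates <- cytobandMSAIRate(eventsByTumour, bands)
  msaiP <- msaiEmpiricalP(eventsByTumour, bands, band = NULL,
                          nPerm = config$nPerm, seed = config$seed,
                          genome = genome)
  highlight <- config$band
  if (is.null(highlight) && any(msaiRates$proportion > 0))
    highlight <- msaiRates$band[which.max(msaiRates$proportion)]

  wgiiByTumour <- vapply(split(scarTab$wgii, scarTab$tumour), mean,
                         numeric(1))
  permCor <- NULL
  hist2 <- perTumour$histology[match(names(wgiiByTumour), perTumour$tumour)]
  if (length(unique(hist2)) == 2 && min(table(hist2)) >= 2)
    permCor <- permutationCorrelation(wgiiByTumour, hist2 == "LUSC",
                                      nPerm = config$nPerm,
                                      seed = config$seed)

  ## ---- report ------------------------------------------------------------
  simTruthPrev <- if (!all(vapply(truths, is.null, logical(1))))
    mean(vapply(truths, function(t) t$wgd >= 1, logical(1))) else NULL
  report <- list(
    provenance = list(package = "tumourEvo",
                      version = as.character(utils::packageVersion("tumourEvo")),
                      seed = config$seed, config_hash = .configHash(config)),
    exclusions = exclusions,
    tumours = perTumour,
    cohort = list(
      n_tumours = nrow(perTumour),
      wgd_prevalence_overall = mean(perTumour$consensus >= 1),
      wgd_prevalence = prevalence,
      wgd_prevalence_truth = simTruthPrev,
      wgd_histology_enrichment = enrich,
      msai_highlight_band = highlight,
      msai_highlight_p = if (!is.null(highlight))
        msaiP$p[msaiP$band == highlight] else NULL,
      wgii_permutation = permCor),
    dnds = dndsTab,
    msai_rates = msaiRates[msaiRates$proportion > 0, ],
    msai_p = msaiP[msaiP$observed > 0, ])

  .writeTsv(wgdTab, file.path(config$outputDir, "wgd.tsv"))
  if (!is.null(timingTab))
    .writeTsv(timingTab, file.path(config$outputDir, "timing.tsv"))
  .writeTsv(scarTab, file.path(config$outputDir, "scars.tsv"))
  if (!is.null(dndsTab))
    .writeTsv(dndsTab, file.path(config$outputDir, "dnds.tsv"))
  .writeTsv(msaiRates, file.path(config$outputDir, "msai_rates.tsv"))
  evTab <- do.call(rbind, lapply(names(eventsByTumour), function(tid) {
    ev <- eventsByTumour[[tid]]
    if (nrow(ev)) cbind(tumour = tid, ev) else NULL
  }))
  if (!is.null(evTab))
    .writeTsv(evTab, file.path(config$outputDir, "msai_events.tsv"))
  jsonlite::write_json(report, file.path(config$outputDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null", pretty = TRUE, force = TRUE)
  invisible(report)
}
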