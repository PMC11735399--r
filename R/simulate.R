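## Multi-region tumour simulator with complete ground truth.
##
## The genome is modelled at 1 Mb resolution on haplotype-specific copy
## number matrices (bins x regions), then compressed to segments. WGD is an
## exact duplication of the pre-WGD profile; early truncal mutations are
## duplicated with it, late ones are not. MSAI events are losses of opposite
## parental haplotypes in disjoint region groups. Scar targets are engineered
## with shapes that each contribute exactly their own score and nothing else.

#' Expected variant allele fraction of a mutation
#'
#' The standard multiplicity relation underlying cancer cell fraction
#' estimates: a mutation present on \code{multiplicity} of
#' \code{cnTotalTumour} tumour copies in a sample of purity \code{purity}
#' (with \code{cnNormal} copies in contaminating normal cells) has expected
#' VAF \code{m * p / (p * T + (1 - p) * cnNormal)}.
#'
#' @param multiplicity Mutant copies per cancer cell (1..\code{cnTotalTumour}).
#' @param purity Sample purity in (0, 1].
#' @param cnTotalTumour Total tumour copy number at the locus (>= 1).
#' @param cnNormal Normal-cell copy number (default 2).
#' @return Expected VAF in (0, 1].
#' @examples
#' expectedVAF(1, 1, 2)        # 0.5
#' expectedVAF(2, 0.5, 4)      # 1/3
#' @seealso \code{\link{mutationCopyNumber}} for the inverse relation.
#' @export
expectedVAF <- function(multiplicity, purity, cnTotalTumour, cnNormal = 2) {
  if (any(purity <= 0 | purity > 1)) stop("'purity' must be in (0, 1]")
  if (any(cnTotalTumour < 1)) stop("'cnTotalTumour' must be >= 1")
  if (any(multiplicity < 1) || any(multiplicity > cnTotalTumour))
    stop("'multiplicity' must lie in [1, cnTotalTumour]")
  multiplicity * purity / (purity * cnTotalTumour + (1 - purity) * cnNormal)
}

## ---- scar injection planning -------------------------------------------

## Shapes on a 100 Mb chromosome (1 Mb bins), designed so that each scar
## contributes exactly its own count and zero counts of the other two:
##  - hrd_loh: LOH over bins 1-92 (92% of the chromosome: > 15 Mb, spans the
##    centromere so it is not a TAI, < 95% so not whole-chromosome, and its
##    single breakpoint has an 8 Mb flank so it is not an LST)
##  - tai: allelic imbalance over a telomeric 8 Mb (no LOH; 8 Mb flank
##    defeats the 10 Mb LST rule); up to two per chromosome (both telomeres)
##  - lst: balanced doubled-CN blocks with >= 10 Mb flanks; an interior
##    block adds 2 breakpoints, a telomeric block adds 1
.scarChromCapacity <- c(hrd_loh = 1L, tai = 2L, lst = 8L)

.planScarInjection <- function(targets, annotation, exclude = character()) {
  targets <- targets[vapply(targets, function(x) x > 0, logical(1))]
  bad <- setdiff(names(targets), c("lst", "tai", "hrd_loh"))
  if (length(bad)) stop("unknown scar target(s): ", paste(bad, collapse = ", "))
  lens <- chromLengths(annotation)
  pool <- setdiff(names(lens), exclude)
  pool <- pool[lens[pool] == 100e6]
  plan <- list()
  for (type in c("hrd_loh", "tai", "lst")) {
    left <- if (is.null(targets[[type]])) 0L else as.integer(targets[[type]])
    while (left > 0L) {
      if (!length(pool))
        stop("scar targets exceed genome capacity (not enough free 100 Mb chromosomes)")
      take <- min(left, .scarChromCapacity[[type]])
      plan[[length(plan) + 1L]] <- list(chrom = pool[1], type = type,
                                        count = take)
      pool <- pool[-1]
      left <- left - take
    }
  }
  list(plan = plan, chroms = vapply(plan, `[[`, character(1), "chrom"))
}

## Mb-resolution shape rows for one scar chromosome, relative to a balanced
## background (bgA, bgB) haplotype state. Returns data.frame(startBin,
## endBin, cnA, cnB); uncovered bins keep the background.
.scarShapeBins <- function(type, count, bgA, bgB) {
  if (type == "hrd_loh") {
    return(data.frame(startBin = 1L, endBin = 92L,
                      cnA = max(bgA, bgB), cnB = 0L))
  }
  if (type == "tai") {
    rows <- data.frame(startBin = 1L, endBin = 8L, cnA = bgA + 1L, cnB = bgB)
    if (count >= 2L)
      rows <- rbind(rows, data.frame(startBin = 93L, endBin = 100L,
                                     cnA = bgA + 1L, cnB = bgB))
    return(rows)
  }
  if (type == "lst") {
    if (bgA != bgB)
      stop("scar targets exceed genome capacity (LST blocks need a balanced background)")
    interior <- list(c(35L, 46L), c(57L, 68L), c(79L, 90L), c(13L, 24L))
    rows <- NULL
    left <- count
    if (left %% 2L == 1L) {
      rows <- data.frame(startBin = 1L, endBin = 12L,
                         cnA = 2L * bgA, cnB = 2L * bgB)
      left <- left - 1L
      interior <- interior[1:3]  # keep the 13-24 slot clear of the telomere
    }
    i <- 1L
    while (left > 0L) {
      blk <- interior[[i]]
      rows <- rbind(rows, data.frame(startBin = blk[1], endBin = blk[2],
                                     cnA = 2L * bgA, cnB = 2L * bgB))
      left <- left - 2L
      i <- i + 1L
    }
    return(rows)
  }
  stop("unknown scar type: ", type)
}

#' Engineer exact scar counts into a copy-number profile
#'
#' Rewrites whole (currently uniform) chromosomes of the profile with
#' copy-number shapes that score exactly the requested LST / TAI / HRD-LOH
#' counts under the default thresholds, and contribute nothing to the other
#' two scores. Intended as a fixture generator: on a noise-free profile the
#' scorers recover the targets exactly.
#'
#' @param profile A \linkS4class{RegionProfile} whose target chromosomes are
#'   uniform (one segment) and 100 Mb long.
#' @param targets Named list with any of \code{lst}, \code{tai},
#'   \code{hrd_loh} (non-negative counts).
#' @param annotation A \linkS4class{GenomeAnnotation}.
#' @return A new \linkS4class{RegionProfile}; unchanged if all targets are 0.
#' @examples
#' flat <- RegionProfile("R1", data.frame(chrom = paste0("chr", 1:5),
#'   start = 1, end = 100e6, cn_major = 1, cn_minor = 1))
#' p <- injectScars(flat, list(hrd_loh = 2, tai = 1), toyGenome())
#' hrdLOHScore(p, toyGenome())  # 2
#' @export
injectScars <- function(profile, targets, annotation = toyGenome()) {
  if (any(unlist(targets) < 0)) stop("scar targets must be >= 0")
  if (!length(targets) || all(unlist(targets) == 0)) return(profile)
  st <- .mergeIdentical(.segTable(profile))
  lens <- chromLengths(annotation)
  perChrom <- split(st, st$chrom)
  uniform <- vapply(perChrom, function(d)
    nrow(d) == 1 && d$start == 1 && d$end == lens[[d$chrom]], logical(1))
  busy <- names(uniform)[!uniform]
  plan <- .planScarInjection(targets, annotation, exclude = busy)
  for (entry in plan$plan) {
    d <- perChrom[[entry$chrom]]
    bgM <- d$cnMajor; bgm <- d$cnMinor
    shape <- .scarShapeBins(entry$type, entry$count, bgM, bgm)
    rows <- data.frame(chrom = entry$chrom,
                       start = (shape$startBin - 1) * 1e6 + 1,
                       end = shape$endBin * 1e6,
                       cnMajor = pmax(shape$cnA, shape$cnB),
                       cnMinor = pmin(shape$cnA, shape$cnB))
    rows <- rows[order(rows$start), , drop = FALSE]
    ## fill uncovered stretches with the background state
    gapStart <- c(1, rows$end + 1)
    gapEnd <- c(rows$start - 1, lens[[entry$chrom]])
    keep <- gapStart <= gapEnd
    if (any(keep))
      rows <- rbind(rows, data.frame(chrom = entry$chrom,
                                     start = gapStart[keep],
                                     end = gapEnd[keep], cnMajor = bgM,
                                     cnMinor = bgm))
    rows <- rows[order(rows$start), ]
    rows$width <- rows$end - rows$start + 1
    perChrom[[entry$chrom]] <- rows[c("chrom", "start", "end", "width",
                                      "cnMajor", "cnMinor")]
  }
  out <- do.call(rbind, perChrom)
  RegionProfile(profile@regionID,
                data.frame(chrom = out$chrom, start = out$start,
                           end = out$end, cn_major = out$cnMajor,
                           cn_minor = out$cnMinor), profile@purity)
}

## ---- the simulator ------------------------------------------------------

#' Simulate a multi-region tumour case with ground truth
#'
#' Generates one tumour: clonal copy-number structure with 0/1/2 WGD events
#' (major CN >= 2 over >= 50\% of the genome whenever a WGD is simulated, by
#' construction), truncal and subclonal mutation clusters with binomial read
#' counts at Poisson depths, heterozygous-SNP BAFs encoding parental
#' haplotypes, optional mirrored (MSAI) loss events, and optional exact scar
#' targets. With \code{noise = 0} all count/BAF sampling is replaced by
#' expectations, producing a fully deterministic, noise-free case.
#'
#' @param config A \linkS4class{SimConfig}.
#' @param tumourID Identifier for the simulated tumour.
#' @return List with elements \code{case} (a \linkS4class{TumourCase}) and
#'   \code{truth} (a list: \code{wgd}, per-mutation \code{mutations} table
#'   with clonality/timing/multiplicity, \code{msai} events with per-region
#'   haplotypes, \code{scar_targets}, \code{purity}, \code{histology}).
#' @examples
#' sim <- simulateCase(simConfig(wgdTruth = 1, seed = 42))
#' sim$truth$wgd
#' callWGD(regions(sim$case)[[1]])
#' @export
simulateCase <- function(config, tumourID = "T1") {
  stopifnot(methods::is(config, "SimConfig"))
  old <- .restorableSeed()
  on.exit(old())
  set.seed(config@seed)

  ann <- config@genome
  lens <- chromLengths(ann)
  chroms <- names(lens)
  nb <- as.integer(lens / 1e6)
  binChrom <- rep(chroms, nb)
  binIdx <- unlist(lapply(nb, seq_len))
  nBins <- length(binChrom)
  R <- config@nRegions
  regionIDs <- paste0("R", seq_len(R))
  rho <- round(runif(R, config@purityRange[1], config@purityRange[2]), 3)
  det <- config@noise == 0
  w <- config@wgdTruth

  if (config@msaiEvents > 0L && R < 2L)
    stop("invalid 'msaiEvents': mirrored events need at least 2 regions")

  targets <- config@scarTargets
  hasTargets <- length(targets) > 0 && any(unlist(targets) > 0)
  plan <- if (hasTargets) .planScarInjection(targets, ann)
          else list(plan = list(), chroms = character())
  freeChroms <- setdiff(chroms, plan$chroms)
  if (config@msaiEvents > 2L * length(freeChroms))
    stop("invalid 'msaiEvents': not enough free chromosomes to host them")

  cnA <- matrix(1L, nBins, R)
  cnB <- matrix(1L, nBins, R)
  clean <- rep(TRUE, nBins)

  ## reserve the MSAI slots up front so background SCNAs cannot split an
  ## injected mirrored event
  msaiSlots <- NULL
  reserved <- integer(0)
  if (config@msaiEvents > 0L) {
    msaiSlots <- expand.grid(slot = c("p", "q"), chrom = freeChroms,
                             stringsAsFactors = FALSE)
    msaiSlots <- msaiSlots[seq_len(config@msaiEvents), , drop = FALSE]
    ## the reservation includes a one-bin buffer: a background SCNA ending
    ## flush against a mirrored loss with the same major/minor state would
    ## merge with it and dilute the phasing majority vote
    reserved <- unlist(lapply(seq_len(nrow(msaiSlots)), function(e) {
      bins <- which(binChrom == msaiSlots$chrom[e])
      span <- if (msaiSlots$slot[e] == "p") 10:19 else 60:69
      bins[span[span >= 1 & span <= length(bins)]]
    }))
  }

  pickInterval <- function(pool, lenBins) {
    for (try in 1:50) {
      ch <- if (length(pool) == 1) pool else sample(pool, 1)
      i <- which(binChrom == ch)
      s <- sample.int(length(i) - lenBins + 1, 1)
      idx <- i[s:(s + lenBins - 1)]
      if (!any(idx %in% reserved)) return(idx)
    }
    idx[!idx %in% reserved]
  }

  ## clonal background SCNAs (identical in every region); suppressed when
  ## exact scar targets are requested so the targets stay exact
  if (!hasTargets && length(freeChroms)) {
    for (k in 1:2) {
      idx <- pickInterval(freeChroms, sample(10:25, 1))
      cnA[idx, ] <- cnA[idx, ] + 1L
      clean[idx] <- FALSE
    }
  }

  ## whole-genome doubling(s): exact duplication
  if (w > 0) {
    cnA <- cnA * 2L^w
    cnB <- cnB * 2L^w
  }

  ## post-WGD single-copy losses, taken from the smaller haplotype so the
  ## major allele (and hence the WGD footprint) is preserved
  if (!hasTargets && length(freeChroms)) {
    for (k in 1:2) {
      idx <- pickInterval(freeChroms, sample(8:15, 1))
      sub <- cnB[idx, , drop = FALSE] <= cnA[idx, , drop = FALSE]
      b <- cnB[idx, , drop = FALSE]; a <- cnA[idx, , drop = FALSE]
      b[sub] <- pmax(b[sub] - 1L, 0L)
      a[!sub] <- pmax(a[!sub] - 1L, 0L)
      cnB[idx, ] <- b; cnA[idx, ] <- a
      clean[idx] <- FALSE
    }
  }

  ## mirrored subclonal allelic imbalance: the same loss on opposite
  ## parental haplotypes in two disjoint region groups
  msaiTruth <- NULL
  if (config@msaiEvents > 0L) {
    g1 <- seq_len(ceiling(R / 2))
    g2 <- setdiff(seq_len(R), g1)
    rows <- vector("list", config@msaiEvents)
    for (e in seq_len(config@msaiEvents)) {
      ch <- msaiSlots$chrom[e]
      bins <- which(binChrom == ch)
      span <- if (msaiSlots$slot[e] == "p") 11:18 else 61:68
      idx <- bins[span]
      cnB[idx, g1] <- 0L
      cnA[idx, g2] <- 0L
      clean[idx] <- FALSE
      hap <- setNames(ifelse(seq_len(R) %in% g1, "H1", "H2"), regionIDs)
      rows[[e]] <- data.frame(chrom = ch, start = (span[1] - 1) * 1e6 + 1,
                              end = span[length(span)] * 1e6,
                              class = "loss/LOH",
                              haplotypes = paste(paste0(regionIDs, "=", hap),
                                                 collapse = ","),
                              stringsAsFactors = FALSE)
    }
    msaiTruth <- do.call(rbind, rows)
  }

  ## exact scar shapes on dedicated chromosomes (identical in every region)
  for (entry in plan$plan) {
    bins <- which(binChrom == entry$chrom)
    shape <- .scarShapeBins(entry$type, entry$count, 2L^w, 2L^w)
    for (i in seq_len(nrow(shape))) {
      idx <- bins[shape$startBin[i]:shape$endBin[i]]
      cnA[idx, ] <- shape$cnA[i]
      cnB[idx, ] <- shape$cnB[i]
      clean[idx] <- FALSE  # bins between shapes keep the baseline state
    }
  }

  ## region profiles: compress bins to segments (major/minor per haplotype)
  profiles <- lapply(seq_len(R), function(r) {
    M <- pmax(cnA[, r], cnB[, r])
    m <- pmin(cnA[, r], cnB[, r])
    id <- paste(binChrom, M, m, sep = "|")
    runs <- rle(id)
    endI <- cumsum(runs$lengths)
    startI <- c(1L, endI[-length(endI)] + 1L)
    RegionProfile(regionIDs[r],
      data.frame(chrom = binChrom[startI],
                 start = (binIdx[startI] - 1) * 1e6 + 1,
                 end = binIdx[endI] * 1e6,
                 cn_major = M[startI], cn_minor = m[startI]),
      rho[r])
  })

  ## heterozygous SNPs: the B allele sits on haplotype A or B; per-region
  ## BAF reflects haplotype-specific CN, purity and (optionally) jitter
  nSnp <- round(sum(nb) * config@snpsPerMb)
  snpBin <- sort(sample.int(nBins, nSnp, replace = TRUE))
  snpPos <- as.integer((binIdx[snpBin] - 1) * 1e6 +
    sample.int(1e6, nSnp, replace = TRUE))
  snpChrom <- binChrom[snpBin]
  ord <- order(match(snpChrom, chroms), snpPos)
  snpBin <- snpBin[ord]; snpPos <- snpPos[ord]; snpChrom <- snpChrom[ord]
  bOnA <- sample(c(TRUE, FALSE), nSnp, replace = TRUE)
  snps <- do.call(rbind, lapply(seq_len(R), function(r) {
    nBcopies <- ifelse(bOnA, cnA[snpBin, r], cnB[snpBin, r])
    tot <- cnA[snpBin, r] + cnB[snpBin, r]
    baf <- (rho[r] * nBcopies + (1 - rho[r])) /
      (rho[r] * tot + 2 * (1 - rho[r]))
    if (!det) baf <- pmin(pmax(baf + rnorm(nSnp, 0, config@noise), 0), 1)
    depth <- if (det) rep(config@meanDepth, nSnp) else rpois(nSnp, config@meanDepth)
    data.frame(chrom = snpChrom, pos = snpPos, region = regionIDs[r],
               baf = baf, depth = as.integer(depth), stringsAsFactors = FALSE)
  }))
  rownames(snps) <- NULL

  ## mutations: neutral draws from the toy gene set, placed in clean bins so
  ## multiplicity and local CN are unambiguous
  genes <- toyGeneSet()
  K <- config@nSubclonalClusters
  nSub <- K * config@mutationsPerCluster
  nMut <- config@nTruncal + nSub
  clusters <- data.frame(cluster = 0:K,
                         is_trunk = c(TRUE, rep(FALSE, K)))
  ccf <- matrix(0, nrow = K + 1, ncol = R,
                dimnames = list(0:K, regionIDs))
  ccf[1, ] <- 1
  if (K > 0) for (k in seq_len(K)) {
    sz <- if (R == 1) 1L else sample.int(R - 1L, 1)
    present <- sample.int(R, sz)
    ccf[k + 1, present] <- round(runif(length(present), 0.25, 0.6), 3)
  }

  mutTruth <- NULL
  mutations <- .emptyMutations()
  mutCounts <- .emptyMutCounts()
  if (nMut > 0) {
    siteTabs <- .cachedSiteTabs(genes)
    gene <- sample(names(genes), nMut, replace = TRUE)
    picked <- lapply(gene, function(g) {
      tab <- siteTabs[[g]]
      tab[sample.int(nrow(tab), 1, prob = tab$rate), ]
    })
    picked <- do.call(rbind, picked)
    cluster <- c(rep(0L, config@nTruncal),
                 if (nSub) rep(seq_len(K), each = config@mutationsPerCluster))
    nEarly <- if (w > 0) round(config@wgdTimingFractionEarly * config@nTruncal)
              else 0L
    mult <- ifelse(cluster == 0L & seq_len(nMut) <= nEarly, 2L^w, 1L)
    timing <- rep(NA_character_, nMut)
    if (w > 0)
      timing[cluster == 0L] <- ifelse(mult[cluster == 0L] >= 2, "early", "late")
    cleanBins <- which(clean)
    mbin <- sample(cleanBins, nMut, replace = TRUE)
    mutations <- data.frame(
      mut_id = sprintf("M%04d", seq_len(nMut)),
      chrom = binChrom[mbin],
      pos = as.integer((binIdx[mbin] - 1) * 1e6 +
        sample.int(1e6, nMut, replace = TRUE)),
      ref = picked$ref, alt = picked$alt, gene = gene,
      consequence = picked$consequence, context = picked$context,
      cluster = cluster, stringsAsFactors = FALSE)
    cnTotal <- 2L * 2L^w  # clean bins carry the baseline post-WGD state
    mutCounts <- do.call(rbind, lapply(seq_len(R), function(r) {
      vaf <- ccf[cluster + 1L, r] * mult * rho[r] /
        (rho[r] * cnTotal + 2 * (1 - rho[r]))
      depth <- if (det) rep(config@meanDepth, nMut)
               else rpois(nMut, config@meanDepth)
      alt <- if (det) round(depth * vaf) else rbinom(nMut, depth, vaf)
      data.frame(mut_id = mutations$mut_id, region = regionIDs[r],
                 ref_count = as.integer(depth - alt),
                 alt_count = as.integer(alt), stringsAsFactors = FALSE)
    }))
    rownames(mutCounts) <- NULL
    mutTruth <- data.frame(
      mut_id = mutations$mut_id, cluster = cluster,
      clonality = ifelse(cluster == 0L, "clonal", "subclonal"),
      timing = timing, multiplicity = mult, stringsAsFactors = FALSE)
  }

  histology <- sample(c("LUAD", "LUSC"), 1, prob = c(0.55, 0.45))
  case <- TumourCase(tumourID, profiles, mutations = mutations,
                     mutCounts = mutCounts, snps = snps,
                     clusters = clusters, genome = ann,
                     meta = list(histology = histology,
                                 seed = config@seed))
  truth <- list(wgd = w, purity = setNames(rho, regionIDs),
                mutations = mutTruth, msai = msaiTruth,
                scar_targets = if (hasTargets) targets else NULL,
                histology = histology)
  list(case = case, truth = truth)
}

#' Simulate a cohort of tumour cases
#'
#' Thin wrapper over \code{\link{simulateCase}}: per-tumour seeds are
#' derived from \code{seed}, WGD truth is drawn from \code{wgdProbs}
#' (defaults roughly echo the high WGD prevalence of non-small-cell lung
#' cancer cohorts), and remaining arguments override the
#' \code{\link{simConfig}} defaults.
#'
#' @param nTumours Number of tumours.
#' @param seed Cohort seed.
#' @param wgdProbs Probabilities of 0/1/2 WGD events per tumour.
#' @param ... Passed to \code{\link{simConfig}} (except \code{seed} and
#'   \code{wgdTruth}).
#' @return List of \code{list(case, truth)} as from
#'   \code{\link{simulateCase}}.
#' @export
simulateCohort <- function(nTumours = 20, seed = 1,
                           wgdProbs = c(0.25, 0.6, 0.15), ...) {
  old <- .restorableSeed()
  on.exit(old())
  set.seed(seed)
  wgd <- sample(0:2, nTumours, replace = TRUE, prob = wgdProbs)
  lapply(seq_len(nTumours), function(i) {
    cfg <- simConfig(..., wgdTruth = wgd[i], seed = seed * 1000L + i)
    simulateCase(cfg, tumourID = sprintf("T%03d", i))
  })
}
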