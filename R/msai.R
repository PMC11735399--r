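## Mirrored subclonal allelic imbalance: SNP phasing across regions,
## parallel-event detection, cytoband rates and permutation empirical P.

#' Phase heterozygous SNPs across regions from allelic imbalance
#'
#' Within one segment, the region with the strongest allelic imbalance
#' (largest mean |BAF - 0.5|) defines the reference haplotype H1 as its
#' per-SNP major alleles. Every other imbalanced region is labelled H1 when
#' the majority of its per-SNP major alleles agree with the reference, H2
#' otherwise; balanced regions stay unassigned. Majority voting (rather
#' than per-SNP assignment) tolerates genotyping noise.
#'
#' @param baf Numeric matrix of BAFs, SNPs x regions (column names are
#'   region IDs).
#' @param aiThreshold Minimum mean |BAF - 0.5| for a region to count as
#'   imbalanced (default 0.08).
#' @param minSnps Minimum number of SNPs required (default 5).
#' @return List: \code{haplotype} (named character, H1/H2/NA per region),
#'   \code{reference} (region defining H1), \code{meanDev} (named numeric),
#'   \code{nSnps}, \code{status} (\code{"ok"}, \code{"no_signal"} or
#'   \code{"insufficient_snps"}).
#' @examples
#' baf <- cbind(A = c(0.8, 0.2, 0.8), B = c(0.2, 0.8, 0.2))
#' phaseSNPs(baf, minSnps = 3)$haplotype  # A = "H1", B = "H2"
#' @export
phaseSNPs <- function(baf, aiThreshold = 0.08, minSnps = 5) {
  baf <- as.matrix(baf)
  regionsIDs <- colnames(baf)
  if (is.null(regionsIDs)) regionsIDs <- paste0("R", seq_len(ncol(baf)))
  hap <- setNames(rep(NA_character_, ncol(baf)), regionsIDs)
  meanDev <- setNames(colMeans(abs(baf - 0.5)), regionsIDs)
  if (nrow(baf) < minSnps)
    return(list(haplotype = hap, reference = NA_character_,
                meanDev = meanDev, nSnps = nrow(baf),
                status = "insufficient_snps"))
  imb <- meanDev >= aiThreshold
  if (!any(imb))
    return(list(haplotype = hap, reference = NA_character_,
                meanDev = meanDev, nSnps = nrow(baf), status = "no_signal"))
  ref <- regionsIDs[imb][which.max(meanDev[imb])]
  majorB <- baf > 0.5   # TRUE when the B allele is the major allele
  for (r in regionsIDs[imb]) {
    agree <- mean(majorB[, r] == majorB[, ref])
    hap[r] <- if (agree >= 0.5) "H1" else "H2"
  }
  list(haplotype = hap, reference = ref, meanDev = meanDev,
       nSnps = nrow(baf), status = "ok")
}

## per-region SCNA class of one segment relative to the region's rounded
## weighted ploidy: loss/LOH when total CN is below ploidy or the minor
## allele is lost; gain/amplification when above ploidy
.eventClass <- function(cnMajor, cnMinor, ploidy) {
  total <- cnMajor + cnMinor
  ifelse(total < ploidy | cnMinor == 0, "loss/LOH",
         ifelse(total > ploidy, "gain/amplification", "neutral"))
}

#' Detect mirrored subclonal allelic imbalance events
#'
#' Harmonizes the case's region segmentations, then emits an event for
#' every segment where at least two regions carry the same SCNA class
#' (relative to each region's rounded ploidy) but opposite phased
#' major-haplotype labels - the same event hitting distinct parental
#' alleles in different regions, i.e. parallel evolution. Adjacent
#' segments with identical event signatures are merged; events are
#' annotated with overlapping cytobands.
#'
#' @param case A \linkS4class{TumourCase} with SNP BAFs.
#' @param bands Cytoband table (\code{\link{toyCytobands}} format).
#' @param aiThreshold,minSnps Passed to \code{\link{phaseSNPs}}.
#' @return data.frame with one row per MSAI event: \code{chrom},
#'   \code{start}, \code{end}, \code{class}, \code{cytobands},
#'   \code{n_snps}, \code{regions} (comma-separated \code{region=H}
#'   labels of the regions showing the event), \code{mean_dev}.
#'   Zero rows when the case has no mirrored events.
#' @examples
#' sim <- simulateCase(simConfig(msaiEvents = 1, noise = 0, seed = 5))
#' detectMSAI(sim$case)[, c("chrom", "start", "end", "class")]
#' @export
detectMSAI <- function(case, bands = toyCytobands(case@genome),
                       aiThreshold = 0.08, minSnps = 5) {
  harm <- harmonizeSegmentation(case@regions)
  regionsIDs <- vapply(harm, regionID, character(1))
  ploidy <- vapply(harm, function(p) round(weightedPloidy(p)), numeric(1))
  tabs <- lapply(harm, .segTable)
  segs <- tabs[[1]][c("chrom", "start", "end")]
  snps <- case@snps
  events <- list()
  for (i in seq_len(nrow(segs))) {
    cls <- vapply(seq_along(harm), function(r)
      .eventClass(tabs[[r]]$cnMajor[i], tabs[[r]]$cnMinor[i], ploidy[r]),
      character(1))
    names(cls) <- regionsIDs
    if (!any(cls != "neutral")) next
    inSeg <- snps$chrom == segs$chrom[i] & snps$pos >= segs$start[i] &
      snps$pos <= segs$end[i]
    if (!any(inSeg)) next
    sub <- snps[inSeg, ]
    wide <- tapply(sub$baf, list(sub$pos, sub$region), mean)
    wide <- wide[, regionsIDs[regionsIDs %in% colnames(wide)], drop = FALSE]
    ph <- phaseSNPs(wide, aiThreshold, minSnps)
    if (ph$status != "ok") next
    for (klass in c("loss/LOH", "gain/amplification")) {
      rr <- regionsIDs[cls == klass & !is.na(ph$haplotype[regionsIDs])]
      if (length(rr) < 2) next
      labs <- ph$haplotype[rr]
      if (length(unique(labs)) < 2) next
      events[[length(events) + 1L]] <- data.frame(
        chrom = segs$chrom[i], start = segs$start[i], end = segs$end[i],
        class = klass,
        regions = paste(paste0(rr, "=", labs), collapse = ","),
        n_snps = ph$nSnps,
        mean_dev = mean(ph$meanDev[rr]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(events)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), class = character(),
                      regions = character(), n_snps = integer(),
                      mean_dev = numeric(), cytobands = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, events)
  ## merge adjacent segments carrying the same event signature
  out <- out[order(out$chrom, out$start), ]
  merged <- out[1, , drop = FALSE]
  if (nrow(out) > 1) for (i in 2:nrow(out)) {
    j <- nrow(merged)
    if (out$chrom[i] == merged$chrom[j] &&
        out$start[i] == merged$end[j] + 1 &&
        out$class[i] == merged$class[j] &&
        out$regions[i] == merged$regions[j]) {
      merged$end[j] <- out$end[i]
      merged$n_snps[j] <- merged$n_snps[j] + out$n_snps[i]
    } else merged <- rbind(merged, out[i, , drop = FALSE])
  }
  merged$cytobands <- .overlappingBands(merged, bands)
  rownames(merged) <- NULL
  merged
}

.overlappingBands <- function(events, bands) {
  if (!nrow(events)) return(character(0))
  ev <- GenomicRanges::GRanges(events$chrom,
                               IRanges::IRanges(events$start, events$end))
  bg <- .bandsToGRanges(bands)
  hits <- GenomicRanges::findOverlaps(ev, bg)
  vapply(seq_len(nrow(events)), function(i) {
    b <- GenomicRanges::mcols(bg)$band[subjectHits(hits)[queryHits(hits) == i]]
    paste(b, collapse = ",")
  }, character(1))
}

#' Proportion of tumours with an MSAI event per cytoband
#'
#' Each tumour counts at most once per band, however many of its events
#' overlap it.
#'
#' @param cohortEvents Named list (one entry per tumour) of
#'   \code{\link{detectMSAI}} results.
#' @param bands Cytoband table.
#' @return \code{bands} with added columns \code{n_tumours} and
#'   \code{proportion}.
#' @export
cytobandMSAIRate <- function(cohortEvents, bands) {
  if (!length(cohortEvents)) stop("empty cohort")
  bg <- .bandsToGRanges(bands)
  hitMat <- vapply(cohortEvents, function(ev) {
    if (is.null(ev) || !nrow(ev)) return(rep(FALSE, length(bg)))
    gr <- GenomicRanges::GRanges(ev$chrom,
                                 IRanges::IRanges(ev$start, ev$end))
    GenomicRanges::countOverlaps(bg, gr) > 0
  }, logical(length(bg)))
  out <- bands
  out$n_tumours <- rowSums(hitMat)
  out$proportion <- out$n_tumours / length(cohortEvents)
  out
}

#' Permutation empirical P value for MSAI enrichment at a cytoband
#'
#' The null keeps each tumour's event count and event lengths but relocates
#' every event to a uniformly random genome position (any chromosome long
#' enough, start uniform over the eligible positions), then recomputes the
#' per-band proportion of tumours with an event. The empirical P for a band
#' is \code{(1 + k) / (nPerm + 1)} where \code{k} permutations reach a
#' proportion at least as large as observed, so P is bounded below by
#' \code{1/(nPerm + 1)} and equals 1 when the observed proportion is 0.
#'
#' @param cohortEvents Named list of \code{\link{detectMSAI}} results.
#' @param bands Cytoband table.
#' @param band Band name(s) to report; \code{NULL} reports every band.
#' @param nPerm Number of permutations (default 999).
#' @param seed RNG seed.
#' @param genome A \linkS4class{GenomeAnnotation} defining where events may
#'   be relocated.
#' @return data.frame: \code{band}, \code{observed} proportion, \code{p},
#'   \code{p_bh} (Benjamini-Hochberg across the reported bands),
#'   \code{n_perm}.
#' @export
msaiEmpiricalP <- function(cohortEvents, bands, band = NULL, nPerm = 999,
                           seed = 1, genome = toyGenome()) {
  if (nPerm < 1) stop("'nPerm' must be >= 1")
  if (!is.null(band) && !all(band %in% bands$band))
    stop("unknown cytoband: ", paste(setdiff(band, bands$band), collapse = ", "))
  obs <- cytobandMSAIRate(cohortEvents, bands)
  lens <- chromLengths(genome)
  chroms <- names(lens)
  nT <- length(cohortEvents)
  widths <- lapply(cohortEvents, function(ev)
    if (is.null(ev) || !nrow(ev)) numeric(0) else ev$end - ev$start + 1)
  old <- .restorableSeed()
  on.exit(old())
  set.seed(seed)
  exceed <- rep(0L, nrow(bands))
  for (p in seq_len(nPerm)) {
    hit <- matrix(FALSE, nrow(bands), nT)
    for (t in seq_len(nT)) {
      wdt <- widths[[t]]
      if (!length(wdt)) next
      for (wd in wdt) {
        elig <- pmax(lens - wd + 1, 0)
        ch <- sample(chroms[elig > 0], 1, prob = elig[elig > 0])
        s <- sample.int(elig[[ch]], 1)
        e <- s + wd - 1
        hit[, t] <- hit[, t] |
          (bands$chrom == ch & bands$start <= e & bands$end >= s)
      }
    }
    prop <- rowSums(hit) / nT
    exceed <- exceed + as.integer(prop >= obs$proportion)
  }
  res <- data.frame(band = bands$band, observed = obs$proportion,
                    p = (1 + exceed) / (nPerm + 1), n_perm = nPerm,
                    stringsAsFactors = FALSE)
  res$p_bh <- p.adjust(res$p, method = "BH")
  if (!is.null(band)) res <- res[res$band %in% band, ]
  rownames(res) <- NULL
  res
}
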