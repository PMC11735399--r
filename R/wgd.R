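## Whole-genome doubling calls from allele-specific copy number.

.autosomalSegs <- function(profile, excludeSex = TRUE) {
  st <- .segTable(profile)
  if (excludeSex)
    st <- st[!st$chrom %in% c("chrX", "chrY", "X", "Y"), , drop = FALSE]
  if (!nrow(st)) stop("empty profile: no (autosomal) segments")
  st
}

#' Genome fraction with major-allele copy number at least k
#'
#' The genome-length-weighted fraction of a region's covered genome whose
#' major-allele copy number is >= \code{k}. This is the quantity the WGD
#' rule thresholds at 0.5.
#'
#' @param profile A \linkS4class{RegionProfile}.
#' @param k Copy-number threshold (>= 0).
#' @param excludeSex Drop chrX/chrY from numerator and denominator
#'   (default TRUE), avoiding haploid-X artefacts.
#' @return Fraction in [0, 1]; monotonically non-increasing in \code{k}.
#' @examples
#' seg <- data.frame(chrom = "chr1", start = c(1, 60e6 + 1),
#'                   end = c(60e6, 100e6), cn_major = c(2, 1),
#'                   cn_minor = c(1, 1))
#' genomeFractionMajorGe(RegionProfile("R1", seg), 2)  # 0.6
#' @export
genomeFractionMajorGe <- function(profile, k, excludeSex = TRUE) {
  if (k < 0) stop("'k' must be >= 0")
  st <- .autosomalSegs(profile, excludeSex)
  sum(st$width[st$cnMajor >= k]) / sum(st$width)
}

#' Call whole-genome doubling status
#'
#' A profile is called doubled when the major-allele copy number is >= 2
#' across at least 50\% of the genome (length-weighted); a major-allele copy
#' number >= 3 across at least 50\% reflects two WGD events. Both thresholds
#' are inclusive. Calls whose decisive fraction falls within
#' \code{borderlineMargin} of 0.5 are flagged as borderline.
#'
#' For a \linkS4class{TumourCase} the per-region calls are aggregated to a
#' tumour-level consensus (the modal \code{nWGD}; ties resolved upwards).
#'
#' @param x A \linkS4class{RegionProfile} or \linkS4class{TumourCase}.
#' @param threshold Genome fraction required (default 0.5, inclusive).
#' @param excludeSex Drop sex chromosomes from the fractions (default TRUE).
#' @param borderlineMargin Half-width of the borderline flag zone around the
#'   threshold (default 0.02).
#' @return For a profile, a \linkS4class{GDStatus}. For a case, a list with
#'   \code{perRegion} (list of GDStatus) and \code{consensus} (integer).
#' @examples
#' seg <- data.frame(chrom = "chr1", start = 1, end = 100e6,
#'                   cn_major = 2, cn_minor = 1)
#' callWGD(RegionProfile("R1", seg))  # one WGD event
#' @export
setGeneric("callWGD", function(x, threshold = 0.5, excludeSex = TRUE,
                               borderlineMargin = 0.02)
  standardGeneric("callWGD"))

#' @rdname callWGD
#' @export
setMethod("callWGD", "RegionProfile",
  function(x, threshold = 0.5, excludeSex = TRUE, borderlineMargin = 0.02) {
    f2 <- genomeFractionMajorGe(x, 2, excludeSex)
    f3 <- genomeFractionMajorGe(x, 3, excludeSex)
    n <- if (f3 >= threshold) 2L else if (f2 >= threshold) 1L else 0L
    decisive <- if (n == 2L) f3 else f2
    new("GDStatus", nWGD = n, fracMajorGe2 = f2, fracMajorGe3 = f3,
        borderline = abs(decisive - threshold) <= borderlineMargin)
  })

#' @rdname callWGD
#' @export
setMethod("callWGD", "TumourCase",
  function(x, threshold = 0.5, excludeSex = TRUE, borderlineMargin = 0.02) {
    per <- lapply(x@regions, callWGD, threshold = threshold,
                  excludeSex = excludeSex,
                  borderlineMargin = borderlineMargin)
    names(per) <- vapply(x@regions, regionID, character(1))
    n <- vapply(per, nWGD, integer(1))
    tab <- table(n)
    modal <- as.integer(names(tab)[tab == max(tab)])
    list(perRegion = per, consensus = max(modal))
  })

#' Harmonize segmentation across tumour regions
#'
#' Re-cuts every region's segments at the union of all regions' breakpoints
#' so that all regions share one minimal common segmentation. Copy-number
#' values are preserved on every sub-interval, so length-weighted summaries
#' (\code{\link{genomeFractionMajorGe}}, \code{\link{weightedPloidy}}) are
#' unchanged, and the operation is idempotent.
#'
#' @param profiles List of \linkS4class{RegionProfile} covering the same
#'   chromosome set.
#' @return List of \linkS4class{RegionProfile} sharing one breakpoint set.
#' @examples
#' a <- RegionProfile("A", data.frame(chrom = "chr1", start = 1, end = 100,
#'                                    cn_major = 1, cn_minor = 1))
#' b <- RegionProfile("B", data.frame(chrom = "chr1", start = c(1, 31),
#'                                    end = c(30, 100), cn_major = c(2, 1),
#'                                    cn_minor = c(0, 1)))
#' harmonizeSegmentation(list(a, b))
#' @export
harmonizeSegmentation <- function(profiles) {
  if (!length(profiles)) stop("need at least one region profile")
  chromSets <- lapply(profiles, function(p)
    sort(unique(as.character(GenomicRanges::seqnames(p@segments)))))
  if (length(unique(chromSets)) != 1L)
    stop("regions cover inconsistent chromosome sets")
  if (length(profiles) == 1L) return(profiles)
  tabs <- lapply(profiles, .segTable)
  cut <- do.call(rbind, lapply(tabs, function(t) t[c("chrom", "start", "end")]))
  ## union breakpoint set per chromosome
  bp <- lapply(split(cut, cut$chrom), function(d)
    sort(unique(c(d$start, d$end + 1L))))
  lapply(profiles, function(p) {
    st <- .segTable(p)
    pieces <- lapply(seq_len(nrow(st)), function(i) {
      cuts <- bp[[st$chrom[i]]]
      inner <- cuts[cuts > st$start[i] & cuts <= st$end[i]]
      starts <- c(st$start[i], inner)
      ends <- c(inner - 1L, st$end[i])
      data.frame(chrom = st$chrom[i], start = starts, end = ends,
                 cn_major = st$cnMajor[i], cn_minor = st$cnMinor[i],
                 stringsAsFactors = FALSE)
    })
    RegionProfile(p@regionID, do.call(rbind, pieces), p@purity)
  })
}
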