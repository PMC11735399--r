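## HRD genomic scar scores: LST, TAI, HRD-LOH, wGII, and permutation bands.

## merge neighbouring segments with identical allele-specific CN; all scores
## call this first so they are invariant to same-CN segment splitting
.mergeIdentical <- function(st) {
  if (nrow(st) < 2) return(st)
  st <- st[order(st$chrom, st$start), , drop = FALSE]
  keep <- logical(nrow(st))
  keep[1] <- TRUE
  for (i in 2:nrow(st)) {
    prev <- max(which(keep[1:(i - 1)]))
    joined <- st$chrom[i] == st$chrom[prev] &&
      st$start[i] == st$end[prev] + 1 &&
      st$cnMajor[i] == st$cnMajor[prev] && st$cnMinor[i] == st$cnMinor[prev]
    if (joined) {
      st$end[prev] <- st$end[i]
    } else keep[i] <- TRUE
  }
  st <- st[keep, , drop = FALSE]
  st$width <- st$end - st$start + 1
  rownames(st) <- NULL
  st
}

## iteratively absorb segments shorter than minLen into their larger
## neighbour (the neighbour keeps its CN); standard pre-step of the LST count
.smoothSegments <- function(st, minLen = 3e6) {
  out <- lapply(split(st, st$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    repeat {
      d <- .mergeIdentical(d)
      small <- which(d$width < minLen)
      if (!length(small) || nrow(d) == 1) break
      i <- small[which.min(d$width[small])]
      left <- if (i > 1) d$width[i - 1] else -Inf
      right <- if (i < nrow(d)) d$width[i + 1] else -Inf
      j <- if (left >= right) i - 1 else i + 1
      d$cnMajor[i] <- d$cnMajor[j]
      d$cnMinor[i] <- d$cnMinor[j]
    }
    d
  })
  st <- do.call(rbind, out)
  rownames(st) <- NULL
  st
}

#' Large-scale transition (LST) score
#'
#' After absorbing segments shorter than \code{smoothLen} into their larger
#' neighbour, counts chromosome-internal breakpoints whose two flanking
#' segments are both at least \code{minSeg} long and differ in
#' allele-specific copy number. Elevated LST counts are an HRD scar.
#'
#' @param profile A \linkS4class{RegionProfile}.
#' @param minSeg Minimum flanking-segment length (default 10 Mb).
#' @param smoothLen Segments shorter than this are smoothed away first
#'   (default 3 Mb).
#' @return Integer count.
#' @examples
#' seg <- data.frame(chrom = "chr1", start = c(1, 12e6 + 1, 27e6 + 1),
#'                   end = c(12e6, 27e6, 38e6), cn_major = c(1, 2, 1),
#'                   cn_minor = c(1, 1, 1))
#' lstScore(RegionProfile("R1", seg))  # 2
#' @export
lstScore <- function(profile, minSeg = 10e6, smoothLen = 3e6) {
  st <- .smoothSegments(.mergeIdentical(.segTable(profile)), smoothLen)
  total <- 0L
  for (d in split(st, st$chrom)) {
    if (nrow(d) < 2) next
    d <- d[order(d$start), , drop = FALSE]
    i <- seq_len(nrow(d) - 1)
    diffCN <- d$cnMajor[i] != d$cnMajor[i + 1] |
      d$cnMinor[i] != d$cnMinor[i + 1]
    total <- total + sum(d$width[i] >= minSeg & d$width[i + 1] >= minSeg &
                           diffCN)
  }
  as.integer(total)
}

#' Telomeric allelic imbalance (TAI) score
#'
#' Counts segments with allelic imbalance (\code{cnMajor != cnMinor}) that
#' reach a telomere (touch a chromosome end), do not cross the centromere
#' (do not span the full centromere interval into the other arm), and are
#' not whole-chromosome events (< \code{wholeChromFrac} of the annotated
#' length). No minimum segment size is imposed by default.
#'
#' @param profile A \linkS4class{RegionProfile}.
#' @param annotation A \linkS4class{GenomeAnnotation} covering the
#'   profile's chromosomes.
#' @param minLen Optional minimum segment length (default 0).
#' @param wholeChromFrac Fraction of chromosome length above which a
#'   segment counts as whole-chromosome and is excluded (default 0.95).
#' @return Integer count.
#' @examples
#' seg <- data.frame(chrom = "chr1", start = c(1, 30e6 + 1),
#'                   end = c(30e6, 100e6), cn_major = c(2, 1),
#'                   cn_minor = c(1, 1))
#' taiScore(RegionProfile("R1", seg), toyGenome())  # 1
#' @export
taiScore <- function(profile, annotation, minLen = 0, wholeChromFrac = 0.95) {
  st <- .mergeIdentical(.segTable(profile))
  lens <- chromLengths(annotation)
  if (!all(st$chrom %in% names(lens)))
    stop("annotation does not cover all chromosomes in the profile")
  if (any(st$end > lens[st$chrom]))
    stop("segment extends beyond annotated chromosome length")
  cen <- centromeres(annotation)
  cenStart <- setNames(cen$start, cen$chrom)
  cenEnd <- setNames(cen$end, cen$chrom)
  len <- lens[st$chrom]
  ai <- st$cnMajor != st$cnMinor
  telo <- st$start <= 1 | st$end >= len
  crossesCen <- st$start <= cenStart[st$chrom] & st$end >= cenEnd[st$chrom]
  whole <- st$width >= wholeChromFrac * len
  sum(ai & telo & !crossesCen & !whole & st$width >= minLen)
}

#' HRD-LOH score
#'
#' Counts loss-of-heterozygosity segments (\code{cnMinor == 0},
#' \code{cnMajor >= 1}) longer than \code{minLen} that do not span a whole
#' chromosome.
#'
#' @param profile A \linkS4class{RegionProfile}.
#' @param annotation A \linkS4class{GenomeAnnotation} (needed for the
#'   whole-chromosome exclusion).
#' @param minLen Minimum LOH segment length (default 15 Mb, exclusive).
#' @param wholeChromFrac As in \code{\link{taiScore}}.
#' @return Integer count.
#' @examples
#' seg <- data.frame(chrom = "chr1", start = c(1, 40e6 + 1, 60e6 + 1),
#'                   end = c(40e6, 60e6, 100e6), cn_major = c(1, 1, 1),
#'                   cn_minor = c(1, 0, 1))
#' hrdLOHScore(RegionProfile("R1", seg), toyGenome())  # 1
#' @export
hrdLOHScore <- function(profile, annotation, minLen = 15e6,
                        wholeChromFrac = 0.95) {
  st <- .mergeIdentical(.segTable(profile))
  lens <- chromLengths(annotation)
  len <- lens[st$chrom]
  loh <- st$cnMinor == 0 & st$cnMajor >= 1
  sum(loh & st$width > minLen & st$width < wholeChromFrac * len)
}

#' Weighted genome instability index (wGII)
#'
#' For each chromosome, the fraction of its covered length whose total copy
#' number differs from the sample's rounded weighted ploidy; wGII is the
#' unweighted mean of these per-chromosome fractions, so every chromosome
#' contributes equally regardless of size. Because deviation is measured
#' from sample ploidy (not from 2), a uniformly doubled genome has wGII 0.
#'
#' @param profile A \linkS4class{RegionProfile}.
#' @return Fraction in [0, 1].
#' @examples
#' seg <- data.frame(chrom = paste0("chr", 1:5),
#'                   start = 1, end = 100e6,
#'                   cn_major = c(3, 1, 1, 1, 1), cn_minor = 1)
#' wgii(RegionProfile("R1", seg))  # 0.2
#' @export
wgii <- function(profile) {
  st <- .segTable(profile)
  if (!nrow(st)) stop("empty profile")
  ploidy <- round(weightedPloidy(profile))
  fr <- vapply(split(st, st$chrom), function(d) {
    tot <- sum(d$width)
    if (tot == 0) {
      warning("chromosome with zero covered length skipped")
      return(NA_real_)
    }
    sum(d$width[d$cnMajor + d$cnMinor != ploidy]) / tot
  }, numeric(1))
  mean(fr, na.rm = TRUE)
}

#' All scar scores for one region
#'
#' @param profile A \linkS4class{RegionProfile}.
#' @param annotation A \linkS4class{GenomeAnnotation}.
#' @param ... Passed on to the individual scorers.
#' @return One-row data.frame: \code{region}, \code{lst}, \code{tai},
#'   \code{hrd_loh}, \code{wgii}.
#' @export
scarScores <- function(profile, annotation, ...) {
  data.frame(region = regionID(profile),
             lst = lstScore(profile, ...),
             tai = taiScore(profile, annotation, ...),
             hrd_loh = hrdLOHScore(profile, annotation, ...),
             wgii = wgii(profile),
             stringsAsFactors = FALSE)
}

#' Permutation test of a score difference between two groups
#'
#' Replicates the permutation confidence-band analysis used to relate scar
#' scores or wGII to a binary sample label: the observed statistic (group
#' mean difference, or Spearman correlation between score and label) is
#' compared against a null built by permuting the labels. The returned
#' 90th/95th null quantiles are the "confidence band" lines; the empirical
#' P uses the add-one estimator on the two-sided (absolute) statistic, so
#' it is bounded below by 1/(nPerm + 1).
#'
#' @param scores Numeric vector of per-sample scores.
#' @param group Binary per-sample labels (logical, or a two-level vector).
#' @param nPerm Number of label permutations (default 999).
#' @param seed RNG seed.
#' @param statistic \code{"meandiff"} (default) or \code{"spearman"}.
#' @return List with \code{observed}, \code{null_q90}, \code{null_q95},
#'   \code{p}, \code{nPerm}, \code{statistic}.
#' @examples
#' permutationCorrelation(c(1, 2, 3, 10, 11, 12),
#'                        c(0, 0, 0, 1, 1, 1), nPerm = 99)
#' @export
permutationCorrelation <- function(scores, group, nPerm = 999, seed = 1,
                                   statistic = c("meandiff", "spearman")) {
  statistic <- match.arg(statistic)
  g <- as.integer(factor(group)) - 1L
  if (length(unique(g)) != 2L || min(table(g)) < 2L)
    stop("need two groups with at least 2 samples each")
  if (length(scores) != length(g)) stop("scores and group lengths differ")
  stat <- switch(statistic,
    meandiff = function(x, g) mean(x[g == 1L]) - mean(x[g == 0L]),
    spearman = function(x, g) {
      if (stats::sd(x) == 0) 0 else stats::cor(x, g, method = "spearman")
    })
  obs <- stat(scores, g)
  old <- .restorableSeed()
  on.exit(old())
  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(i) stat(scores, sample(g)),
                 numeric(1))
  list(observed = obs,
       null_q90 = unname(quantile(null, 0.90, type = 7)),
       null_q95 = unname(quantile(null, 0.95, type = 7)),
       p = (1 + sum(abs(null) >= abs(obs))) / (nPerm + 1),
       nPerm = nPerm, statistic = statistic)
}

## save/restore the global RNG state so seeded helpers do not perturb
## the caller's stream
.restorableSeed <- function() {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  saved <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  function() {
    if (!is.null(saved)) assign(".Random.seed", saved, envir = globalenv())
  }
}
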