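## S4 classes for the central data objects. Segments are stored as GRanges
## (1-based, inclusive) with integer mcols cnMajor/cnMinor.

#' GenomeAnnotation: chromosome lengths, centromeres and telomeres
#'
#' Holds the reference skeleton needed by telomere/centromere-aware scores
#' (TAI) and by the simulator: per-chromosome length and centromere interval.
#' Telomeres are taken to be the chromosome ends.
#'
#' @slot lengths Named numeric vector of chromosome lengths in bp.
#' @slot centromeres data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (1-based inclusive centromere interval per chromosome).
#' @seealso \code{\link{toyGenome}}, \code{\link{taiScore}}
#' @export
setClass("GenomeAnnotation",
  slots = c(lengths = "numeric", centromeres = "data.frame"))

setValidity("GenomeAnnotation", function(object) {
  ln <- object@lengths
  cen <- object@centromeres
  if (is.null(names(ln)) || any(!nzchar(names(ln))))
    return("'lengths' must be a named vector of chromosome lengths")
  if (any(ln <= 0)) return("chromosome lengths must be > 0")
  if (!all(c("chrom", "start", "end") %in% names(cen)))
    return("'centromeres' needs columns chrom, start, end")
  if (!all(cen$chrom %in% names(ln)))
    return("centromere table refers to unknown chromosomes")
  bad <- cen$start < 1 | cen$end > ln[cen$chrom] | cen$start > cen$end
  if (any(bad)) return("centromere interval outside chromosome bounds")
  TRUE
})

#' Construct a GenomeAnnotation
#'
#' @param lengths Named numeric vector of chromosome lengths (bp).
#' @param centromeres data.frame with columns \code{chrom}, \code{start},
#'   \code{end}.
#' @return A \linkS4class{GenomeAnnotation} object.
#' @examples
#' genomeAnnotation(c(chr1 = 50e6),
#'                  data.frame(chrom = "chr1", start = 20e6, end = 25e6))
#' @export
genomeAnnotation <- function(lengths, centromeres) {
  new("GenomeAnnotation", lengths = lengths,
      centromeres = as.data.frame(centromeres))
}

#' RegionProfile: allele-specific copy number for one tumour region
#'
#' One sequenced region of a tumour: its ASCN segmentation (major/minor
#' allele copy number per segment) and sample purity. Segments must be
#' sorted and non-overlapping; coordinates are 1-based inclusive.
#'
#' @slot regionID Character scalar region identifier.
#' @slot segments GRanges with integer metadata columns \code{cnMajor} and
#'   \code{cnMinor} (\code{cnMajor >= cnMinor >= 0}).
#' @slot purity Tumour cell fraction of the sample, in (0, 1].
#' @seealso \code{\link{RegionProfile}}, \code{\link{callWGD}},
#'   \code{\link{scarScores}}
#' @export
setClass("RegionProfile",
  slots = c(regionID = "character", segments = "GRanges", purity = "numeric"))

setValidity("RegionProfile", function(object) {
  gr <- object@segments
  if (length(object@regionID) != 1L) return("'regionID' must be a scalar")
  p <- object@purity
  if (length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    return("'purity' must be a single value in (0, 1]")
  mc <- GenomicRanges::mcols(gr)
  if (!all(c("cnMajor", "cnMinor") %in% names(mc)))
    return("segments need metadata columns cnMajor and cnMinor")
  if (length(gr)) {
    if (any(mc$cnMinor < 0) || any(mc$cnMajor < mc$cnMinor))
      return("need cnMajor >= cnMinor >= 0 on every segment")
    if (S4Vectors::isSorted(gr) == FALSE)
      return("segments must be sorted")
    cov <- sum(GenomicRanges::width(GenomicRanges::reduce(gr)))
    if (cov != sum(GenomicRanges::width(gr)))
      return("segments must not overlap")
  }
  TRUE
})

#' Construct a RegionProfile
#'
#' @param regionID Region identifier.
#' @param segments Either a GRanges with mcols \code{cnMajor}/\code{cnMinor},
#'   or a data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{cn_major}, \code{cn_minor} (1-based inclusive).
#' @param purity Sample purity in (0, 1].
#' @return A \linkS4class{RegionProfile}.
#' @examples
#' seg <- data.frame(chrom = "chr1", start = 1, end = 10e6,
#'                   cn_major = 2, cn_minor = 1)
#' RegionProfile("R1", seg, purity = 0.6)
#' @export
RegionProfile <- function(regionID, segments, purity = 1) {
  if (is.data.frame(segments)) segments <- .segDfToGRanges(segments)
  segments <- BiocGenerics::sort(segments)
  new("RegionProfile", regionID = as.character(regionID),
      segments = segments, purity = as.numeric(purity))
}

.segDfToGRanges <- function(df) {
  need <- c("chrom", "start", "end", "cn_major", "cn_minor")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("segment table is missing column(s): ", paste(miss, collapse = ", "))
  gr <- GenomicRanges::GRanges(df$chrom,
          IRanges::IRanges(df$start, df$end))
  GenomicRanges::mcols(gr)$cnMajor <- as.integer(df$cn_major)
  GenomicRanges::mcols(gr)$cnMinor <- as.integer(df$cn_minor)
  gr
}

## plain data.frame view of a profile's segments, used by most computations
.segTable <- function(profile) {
  gr <- profile@segments
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
             width = BiocGenerics::width(gr),
             cnMajor = GenomicRanges::mcols(gr)$cnMajor,
             cnMinor = GenomicRanges::mcols(gr)$cnMinor,
             stringsAsFactors = FALSE)
}

#' GDStatus: whole-genome doubling call for a profile
#'
#' @slot nWGD Integer number of WGD events called (0, 1 or 2).
#' @slot fracMajorGe2 Genome-length-weighted fraction with major CN >= 2.
#' @slot fracMajorGe3 Genome-length-weighted fraction with major CN >= 3.
#' @slot borderline TRUE when the decisive fraction lies within 0.02 of the
#'   0.5 threshold; such calls deserve review against mutation copy numbers.
#' @seealso \code{\link{callWGD}}
#' @export
setClass("GDStatus",
  slots = c(nWGD = "integer", fracMajorGe2 = "numeric",
            fracMajorGe3 = "numeric", borderline = "logical"))

setValidity("GDStatus", function(object) {
  if (!object@nWGD %in% 0:2) return("nWGD must be 0, 1 or 2")
  f2 <- object@fracMajorGe2; f3 <- object@fracMajorGe3
  if (f2 < 0 || f2 > 1 || f3 < 0 || f3 > 1)
    return("genome fractions must lie in [0, 1]")
  if (object@nWGD >= 1L && f2 < 0.5) return("nWGD >= 1 requires fracMajorGe2 >= 0.5")
  if (object@nWGD == 2L && f3 < 0.5) return("nWGD == 2 requires fracMajorGe3 >= 0.5")
  TRUE
})

#' TumourCase: a multi-region tumour
#'
#' Container tying together everything known about one patient tumour:
#' per-region ASCN profiles, mutation observations with per-region read
#' counts, heterozygous-SNP BAFs, mutation cluster definitions with their
#' per-region phyloCCF summaries, and the genome annotation.
#'
#' @slot tumourID Character scalar.
#' @slot regions List of \linkS4class{RegionProfile}, one per region.
#' @slot mutations data.frame of per-mutation metadata: \code{mut_id},
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{gene},
#'   \code{consequence}, \code{context}, \code{cluster}.
#' @slot mutCounts Long data.frame of read counts: \code{mut_id},
#'   \code{region}, \code{ref_count}, \code{alt_count}.
#' @slot snps Long data.frame of heterozygous SNP BAFs: \code{chrom},
#'   \code{pos}, \code{region}, \code{baf}, \code{depth}.
#' @slot clusters data.frame: \code{cluster}, \code{is_trunk}.
#' @slot clusterCCF data.frame of per-cluster, per-region phyloCCF
#'   summaries: \code{cluster}, \code{region}, \code{mean}, \code{low},
#'   \code{high} (95\% CI). Filled by \code{\link{estimateClusterCCF}}.
#' @slot genome \linkS4class{GenomeAnnotation}.
#' @slot meta List of free-form labels (e.g. \code{histology}).
#' @export
setClass("TumourCase",
  slots = c(tumourID = "character", regions = "list",
            mutations = "data.frame", mutCounts = "data.frame",
            snps = "data.frame", clusters = "data.frame",
            clusterCCF = "data.frame", genome = "GenomeAnnotation",
            meta = "list"))

setValidity("TumourCase", function(object) {
  if (length(object@tumourID) != 1L) return("'tumourID' must be a scalar")
  if (!length(object@regions)) return("a TumourCase needs at least one region")
  ok <- vapply(object@regions, function(r) methods::is(r, "RegionProfile"),
               logical(1))
  if (!all(ok)) return("'regions' must be a list of RegionProfile objects")
  ids <- vapply(object@regions, function(r) r@regionID, character(1))
  if (anyDuplicated(ids)) return("duplicated region identifiers")
  TRUE
})

#' Construct a TumourCase
#'
#' @param tumourID Tumour identifier.
#' @param regions List of \linkS4class{RegionProfile}.
#' @param mutations,mutCounts,snps,clusters,clusterCCF See the class slots.
#' @param genome A \linkS4class{GenomeAnnotation}.
#' @param meta Optional list of labels (e.g. \code{histology}).
#' @return A \linkS4class{TumourCase}.
#' @export
TumourCase <- function(tumourID, regions,
                       mutations = .emptyMutations(),
                       mutCounts = .emptyMutCounts(),
                       snps = .emptySnps(),
                       clusters = data.frame(cluster = integer(),
                                             is_trunk = logical()),
                       clusterCCF = .emptyClusterCCF(),
                       genome = toyGenome(), meta = list()) {
  new("TumourCase", tumourID = as.character(tumourID), regions = regions,
      mutations = mutations, mutCounts = mutCounts, snps = snps,
      clusters = clusters, clusterCCF = clusterCCF, genome = genome,
      meta = meta)
}

.emptyMutations <- function() {
  data.frame(mut_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), gene = character(),
             consequence = character(), context = character(),
             cluster = integer(), stringsAsFactors = FALSE)
}
.emptyMutCounts <- function() {
  data.frame(mut_id = character(), region = character(),
             ref_count = integer(), alt_count = integer(),
             stringsAsFactors = FALSE)
}
.emptySnps <- function() {
  data.frame(chrom = character(), pos = integer(), region = character(),
             baf = numeric(), depth = integer(), stringsAsFactors = FALSE)
}
.emptyClusterCCF <- function() {
  data.frame(cluster = integer(), region = character(), mean = numeric(),
             low = numeric(), high = numeric(), stringsAsFactors = FALSE)
}

#' SimConfig: configuration for the multi-region tumour simulator
#'
#' @slot nRegions Number of tumour regions to simulate.
#' @slot genome \linkS4class{GenomeAnnotation}; chromosome lengths must be
#'   multiples of 1 Mb (the simulator's internal resolution).
#' @slot purityRange Length-2 numeric, purities drawn uniformly from it.
#' @slot meanDepth Mean sequencing depth (reads); per-site depths are
#'   Poisson around it unless \code{noise == 0}.
#' @slot nTruncal Number of truncal (clonal) mutations.
#' @slot nSubclonalClusters,mutationsPerCluster Subclonal structure.
#' @slot wgdTruth True number of WGD events (0, 1 or 2).
#' @slot wgdTimingFractionEarly Fraction of truncal mutations placed before
#'   the WGD event(s).
#' @slot msaiEvents Number of mirrored (MSAI) loss events to inject.
#' @slot scarTargets Optional named list with any of \code{lst}, \code{tai},
#'   \code{hrd_loh}: exact scar counts to engineer into every region.
#' @slot snpsPerMb Heterozygous SNP density used for phasing.
#' @slot noise BAF jitter standard deviation; 0 switches off *all*
#'   stochastic sampling of read counts, depths and BAFs, making the case
#'   fully deterministic apart from its seeded structure.
#' @slot seed Integer RNG seed.
#' @seealso \code{\link{simConfig}}, \code{\link{simulateCase}}
#' @export
setClass("SimConfig",
  slots = c(nRegions = "integer", genome = "GenomeAnnotation",
            purityRange = "numeric", meanDepth = "numeric",
            nTruncal = "integer", nSubclonalClusters = "integer",
            mutationsPerCluster = "integer", wgdTruth = "integer",
            wgdTimingFractionEarly = "numeric", msaiEvents = "integer",
            scarTargets = "list", snpsPerMb = "numeric", noise = "numeric",
            seed = "integer"))

setValidity("SimConfig", function(object) {
  chk <- function(cond, field, what)
    if (!cond) sprintf("invalid '%s': %s", field, what) else NULL
  msgs <- c(
    chk(object@nRegions >= 1L, "nRegions", "need at least one region"),
    chk(length(object@purityRange) == 2L &&
        all(object@purityRange > 0 & object@purityRange <= 1) &&
        object@purityRange[1] <= object@purityRange[2],
        "purityRange", "must be an increasing pair within (0, 1]"),
    chk(object@meanDepth >= 1, "meanDepth", "depth must be >= 1"),
    chk(object@nTruncal >= 0L, "nTruncal", "counts must be >= 0"),
    chk(object@nSubclonalClusters >= 0L, "nSubclonalClusters",
        "counts must be >= 0"),
    chk(object@mutationsPerCluster >= 0L, "mutationsPerCluster",
        "counts must be >= 0"),
    chk(object@wgdTruth %in% 0:2, "wgdTruth", "must be 0, 1 or 2"),
    chk(object@wgdTimingFractionEarly >= 0 &&
        object@wgdTimingFractionEarly <= 1,
        "wgdTimingFractionEarly", "must be a fraction in [0, 1]"),
    chk(object@msaiEvents >= 0L, "msaiEvents", "counts must be >= 0"),
    chk(all(unlist(object@scarTargets) >= 0), "scarTargets",
        "target counts must be >= 0"),
    chk(all(names(object@scarTargets) %in% c("lst", "tai", "hrd_loh")),
        "scarTargets", "names must be among lst, tai, hrd_loh"),
    chk(object@snpsPerMb > 0, "snpsPerMb", "must be > 0"),
    chk(object@noise >= 0, "noise", "must be >= 0"),
    chk(all(object@genome@lengths %% 1e6 == 0), "genome",
        "chromosome lengths must be multiples of 1 Mb"))
  if (length(msgs)) msgs[[1]] else TRUE
})

#' Construct a simulator configuration
#'
#' Defaults describe a small but realistic multi-region WES experiment on
#' the bundled five-chromosome toy genome: three regions at 100x mean
#' depth, purities between 0.4 and 0.9, 40 truncal mutations plus two
#' subclonal clusters of 15, and a BAF jitter of 0.02.
#'
#' @param nRegions,genome,purityRange,meanDepth,nTruncal See
#'   \linkS4class{SimConfig}.
#' @param nSubclonalClusters,mutationsPerCluster,wgdTruth See
#'   \linkS4class{SimConfig}.
#' @param wgdTimingFractionEarly,msaiEvents,scarTargets,snpsPerMb See
#'   \linkS4class{SimConfig}.
#' @param noise,seed See \linkS4class{SimConfig}.
#' @return A validated \linkS4class{SimConfig}; invalid values raise an
#'   error naming the offending field.
#' @examples
#' simConfig(wgdTruth = 1, seed = 7)
#' @export
simConfig <- function(nRegions = 3, genome = toyGenome(),
                      purityRange = c(0.4, 0.9), meanDepth = 100,
                      nTruncal = 40, nSubclonalClusters = 2,
                      mutationsPerCluster = 15, wgdTruth = 0,
                      wgdTimingFractionEarly = 0.5, msaiEvents = 0,
                      scarTargets = list(), snpsPerMb = 2, noise = 0.02,
                      seed = 1) {
  new("SimConfig", nRegions = as.integer(nRegions), genome = genome,
      purityRange = as.numeric(purityRange), meanDepth = as.numeric(meanDepth),
      nTruncal = as.integer(nTruncal),
      nSubclonalClusters = as.integer(nSubclonalClusters),
      mutationsPerCluster = as.integer(mutationsPerCluster),
      wgdTruth = as.integer(wgdTruth),
      wgdTimingFractionEarly = as.numeric(wgdTimingFractionEarly),
      msaiEvents = as.integer(msaiEvents), scarTargets = scarTargets,
      snpsPerMb = as.numeric(snpsPerMb), noise = as.numeric(noise),
      seed = as.integer(seed))
}

#' SpectrumModel: trinucleotide substitution spectrum
#'
#' Relative rates over the 96 canonical trinucleotide substitution classes
#' (pyrimidine-centred, e.g. \code{"A[C>T]G"}); rates are normalized to sum
#' to one.
#'
#' @slot rates Named numeric vector of length 96 summing to 1.
#' @seealso \code{\link{spectrumModel}}, \code{\link{uniformSpectrum}},
#'   \code{\link{expectedNSCounts}}
#' @export
setClass("SpectrumModel", slots = c(rates = "numeric"))

setValidity("SpectrumModel", function(object) {
  r <- object@rates
  if (length(r) != 96L || !identical(sort(names(r)), sort(trinucClasses())))
    return("rates must be named by the 96 canonical trinucleotide classes")
  if (any(r < 0)) return("rates must be >= 0")
  if (abs(sum(r) - 1) > 1e-9) return("rates must sum to 1")
  TRUE
})
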