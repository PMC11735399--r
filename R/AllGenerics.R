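## Generics, accessors and show methods.

#' @rdname RegionProfile-class
#' @param x,object A \linkS4class{RegionProfile}.
#' @export
setGeneric("regionID", function(x) standardGeneric("regionID"))

#' @rdname RegionProfile-class
#' @export
setMethod("regionID", "RegionProfile", function(x) x@regionID)

#' @rdname RegionProfile-class
#' @export
setGeneric("purity", function(x) standardGeneric("purity"))

#' @rdname RegionProfile-class
#' @export
setMethod("purity", "RegionProfile", function(x) x@purity)

#' @rdname RegionProfile-class
#' @export
setGeneric("cnSegments", function(x) standardGeneric("cnSegments"))

#' @rdname RegionProfile-class
#' @export
setMethod("cnSegments", "RegionProfile", function(x) x@segments)

#' Length-weighted mean total copy number (sample ploidy)
#'
#' @param x A \linkS4class{RegionProfile}.
#' @return Numeric scalar: the length-weighted mean of
#'   \code{cnMajor + cnMinor} over all segments.
#' @examples
#' seg <- data.frame(chrom = c("chr1", "chr1"), start = c(1, 50e6 + 1),
#'                   end = c(50e6, 100e6), cn_major = c(2, 1),
#'                   cn_minor = c(2, 1))
#' weightedPloidy(RegionProfile("R1", seg))  # 3
#' @export
setGeneric("weightedPloidy", function(x) standardGeneric("weightedPloidy"))

#' @rdname weightedPloidy
#' @export
setMethod("weightedPloidy", "RegionProfile", function(x) {
  st <- .segTable(x)
  if (!nrow(st)) stop("empty profile: no segments to average over")
  sum((st$cnMajor + st$cnMinor) * st$width) / sum(st$width)
})

#' @rdname TumourCase-class
#' @param x,object A \linkS4class{TumourCase}.
#' @export
setGeneric("tumourID", function(x) standardGeneric("tumourID"))

#' @rdname TumourCase-class
#' @export
setMethod("tumourID", "TumourCase", function(x) x@tumourID)

#' @rdname TumourCase-class
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname TumourCase-class
#' @export
setMethod("regions", "TumourCase", function(x) x@regions)

#' @rdname TumourCase-class
#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))

#' @rdname TumourCase-class
#' @export
setMethod("mutations", "TumourCase", function(x) x@mutations)

#' @rdname GDStatus-class
#' @param x,object A \linkS4class{GDStatus}.
#' @export
setGeneric("nWGD", function(x) standardGeneric("nWGD"))

#' @rdname GDStatus-class
#' @export
setMethod("nWGD", "GDStatus", function(x) x@nWGD)

#' @rdname GenomeAnnotation-class
#' @param x,object A \linkS4class{GenomeAnnotation}.
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GenomeAnnotation-class
#' @export
setMethod("chromLengths", "GenomeAnnotation", function(x) x@lengths)

#' @rdname GenomeAnnotation-class
#' @export
setGeneric("centromeres", function(x) standardGeneric("centromeres"))

#' @rdname GenomeAnnotation-class
#' @export
setMethod("centromeres", "GenomeAnnotation", function(x) x@centromeres)

#' @rdname SpectrumModel-class
#' @param x,object A \linkS4class{SpectrumModel}.
#' @export
setGeneric("spectrumRates", function(x) standardGeneric("spectrumRates"))

#' @rdname SpectrumModel-class
#' @export
setMethod("spectrumRates", "SpectrumModel", function(x) x@rates)

setMethod("show", "RegionProfile", function(object) {
  st <- .segTable(object)
  cat(sprintf("RegionProfile '%s': %d segments on %d chromosome(s), %.1f Mb\n",
              object@regionID, nrow(st), length(unique(st$chrom)),
              sum(st$width) / 1e6))
  cat(sprintf("  purity %.2f, weighted ploidy %.2f\n", object@purity,
              weightedPloidy(object)))
})

setMethod("show", "TumourCase", function(object) {
  cat(sprintf("TumourCase '%s': %d regions, %d mutations, %d SNPs, %d clusters\n",
              object@tumourID, length(object@regions),
              nrow(object@mutations),
              length(unique(object@snps$pos)), nrow(object@clusters)))
  if (!is.null(object@meta$histology))
    cat("  histology:", object@meta$histology, "\n")
})

setMethod("show", "GDStatus", function(object) {
  cat(sprintf("GDStatus: %d WGD event(s) [frac(major>=2) = %.3f, frac(major>=3) = %.3f]%s\n",
              object@nWGD, object@fracMajorGe2, object@fracMajorGe3,
              if (object@borderline) " (borderline)" else ""))
})

setMethod("show", "GenomeAnnotation", function(object) {
  cat(sprintf("GenomeAnnotation: %d chromosomes, %.0f Mb total\n",
              length(object@lengths), sum(object@lengths) / 1e6))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d regions, depth %.0fx, purity [%.2f, %.2f], WGD truth %d, seed %d\n",
    object@nRegions, object@meanDepth, object@purityRange[1],
    object@purityRange[2], object@wgdTruth, object@seed))
})

setMethod("show", "SpectrumModel", function(object) {
  cat(sprintf("SpectrumModel: 96 trinucleotide classes, max rate %.4f (%s)\n",
              max(object@rates), names(which.max(object@rates))))
})
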