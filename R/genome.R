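#' Bundled toy genome: five 100-Mb chromosomes
#'
#' A compact reference skeleton used by the simulator and the examples:
#' chromosomes \code{chr1}..\code{chr5}, each 100 Mb with a centromere at
#' 45-55 Mb and telomeres at the chromosome ends. Real genome builds can be
#' supplied instead via \code{\link{genomeAnnotation}} or
#' \code{\link{readGenomeAnnotation}}.
#'
#' @param nChrom Number of chromosomes (default 5).
#' @param chromLength Length of each chromosome in bp (default 100 Mb).
#' @return A \linkS4class{GenomeAnnotation}.
#' @examples
#' toyGenome()
#' @export
toyGenome <- function(nChrom = 5, chromLength = 100e6) {
  chroms <- paste0("chr", seq_len(nChrom))
  lens <- setNames(rep(chromLength, nChrom), chroms)
  cen <- data.frame(chrom = chroms,
                    start = round(0.45 * chromLength) + 1,
                    end = round(0.55 * chromLength),
                    stringsAsFactors = FALSE)
  genomeAnnotation(lens, cen)
}

#' Toy cytoband table for the bundled genome
#'
#' Ten 10-Mb bands per chromosome, named \code{<n>p5..<n>p1} (telomere to
#' centromere on the p arm) then \code{<n>q1..<n>q5}. These play the role a
#' real cytoband file (e.g. locating 4q35.2) plays for a genome build.
#'
#' @param genome A \linkS4class{GenomeAnnotation} whose chromosome lengths
#'   are multiples of 10 Mb.
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{band} (1-based inclusive; non-overlapping, sorted).
#' @examples
#' head(toyCytobands())
#' @export
toyCytobands <- function(genome = toyGenome()) {
  lens <- chromLengths(genome)
  out <- lapply(names(lens), function(ch) {
    n <- lens[[ch]] / 10e6
    if (n %% 2 != 0) stop("toyCytobands needs an even number of 10 Mb bands")
    half <- n / 2
    starts <- seq(1, lens[[ch]], by = 10e6)
    num <- sub("^chr", "", ch)
    nm <- c(paste0(num, "p", half:1), paste0(num, "q", 1:half))
    data.frame(chrom = ch, start = starts, end = starts + 10e6 - 1,
               band = nm, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.bandsToGRanges <- function(bands) {
  gr <- GenomicRanges::GRanges(bands$chrom,
                               IRanges::IRanges(bands$start, bands$end))
  GenomicRanges::mcols(gr)$band <- bands$band
  gr
}
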