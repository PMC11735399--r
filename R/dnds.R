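## Simplified context-aware dN/dS estimation: site enumeration over a coding
## sequence weighted by a 96-class trinucleotide spectrum, observed/expected
## ratio, and exact Poisson (Garwood) confidence intervals combined on the
## log-ratio scale.

.BASES <- c("A", "C", "G", "T")

## memoised uniform-spectrum site tables (the simulator re-enumerates the
## same toy gene set for every case otherwise)
.siteCache <- new.env(parent = emptyenv())

.cachedSiteTabs <- function(genes) {
  key <- paste(names(genes), vapply(genes, nchar, integer(1)),
               substr(genes, 1, 24), collapse = ";")
  if (!is.null(.siteCache[[key]])) return(.siteCache[[key]])
  tabs <- lapply(genes, enumerateSites, spectrum = uniformSpectrum())
  .siteCache[[key]] <- tabs
  tabs
}

## vectorized reverse complement for trinucleotide strings
.revcomp3 <- function(x) {
  y <- chartr("ACGT", "TGCA", x)
  paste0(substr(y, 3, 3), substr(y, 2, 2), substr(y, 1, 1))
}

#' The 96 canonical trinucleotide substitution classes
#'
#' Pyrimidine-centred class labels of the form \code{"A[C>T]G"}: 6
#' substitution types (C>A, C>G, C>T, T>A, T>C, T>G) times 16 flanking-base
#' combinations.
#'
#' @return Character vector of length 96.
#' @export
trinucClasses <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) for (up in .BASES) for (dn in .BASES)
    out <- c(out, paste0(up, "[", s, "]", dn))
  out
}

## map (trinucleotide context, alt base) to its canonical pyrimidine class
.contextClass <- function(context, alt) {
  ref <- substr(context, 2, 2)
  flip <- ref %in% c("A", "G")
  context[flip] <- .revcomp3(context[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  paste0(substr(context, 1, 1), "[", substr(context, 2, 2), ">", alt, "]",
         substr(context, 3, 3))
}

#' Construct a trinucleotide spectrum model
#'
#' @param rates Named non-negative numeric vector over the 96 classes of
#'   \code{\link{trinucClasses}}; normalized internally to sum to 1 (so
#'   expected-count ratios are invariant to rescaling).
#' @return A \linkS4class{SpectrumModel}.
#' @export
spectrumModel <- function(rates) {
  if (sum(rates) <= 0) stop("spectrum rates must not all be zero")
  new("SpectrumModel", rates = rates[trinucClasses()] / sum(rates))
}

#' @rdname spectrumModel
#' @export
uniformSpectrum <- function() {
  spectrumModel(setNames(rep(1, 96), trinucClasses()))
}

#' Enumerate all single-nucleotide changes of a coding sequence
#'
#' Lists every possible substitution at every position of \code{cds} (3L
#' changes for a sequence of length L), classifies each as synonymous or
#' non-synonymous by codon translation (standard genetic code), and attaches
#' its trinucleotide-class spectrum rate. The flanking context of the first
#' and last base wraps around the sequence ends.
#'
#' @param cds Coding sequence (character scalar, A/C/G/T, length a multiple
#'   of 3, no premature stop codon).
#' @param spectrum A \linkS4class{SpectrumModel}.
#' @return data.frame with columns \code{pos}, \code{ref}, \code{alt},
#'   \code{context}, \code{class}, \code{aa_ref}, \code{aa_alt},
#'   \code{synonymous}, \code{consequence}, \code{rate}.
#' @export
enumerateSites <- function(cds, spectrum = uniformSpectrum()) {
  bases <- strsplit(toupper(cds), "")[[1]]
  L <- length(bases)
  if (L %% 3 != 0) stop("coding sequence length must be a multiple of 3")
  if (!all(bases %in% .BASES))
    stop("invalid codon alphabet: coding sequence must be A/C/G/T only")
  codons <- paste0(bases[seq(1, L, 3)], bases[seq(2, L, 3)], bases[seq(3, L, 3)])
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  if (any(aa[-length(aa)] == "*"))
    stop("coding sequence contains a premature stop codon")
  pos <- rep(seq_len(L), each = 3)
  ref <- bases[pos]
  alt <- unlist(lapply(bases, function(b) .BASES[.BASES != b]),
                use.names = FALSE)
  up <- bases[ifelse(pos == 1L, L, pos - 1L)]
  dn <- bases[ifelse(pos == L, 1L, pos + 1L)]
  context <- paste0(up, ref, dn)
  ci <- (pos - 1L) %/% 3L + 1L
  off <- (pos - 1L) %% 3L + 1L
  mutCodon <- codons[ci]
  substr(mutCodon, off, off) <- alt
  aaAlt <- unname(Biostrings::GENETIC_CODE[mutCodon])
  syn <- aaAlt == aa[ci]
  cls <- .contextClass(context, alt)
  data.frame(pos = pos, ref = ref, alt = alt, context = context,
             class = cls, aa_ref = aa[ci], aa_alt = aaAlt, synonymous = syn,
             consequence = ifelse(syn, "synonymous",
                                  ifelse(aaAlt == "*", "nonsense", "missense")),
             rate = unname(spectrumRates(spectrum)[cls]),
             stringsAsFactors = FALSE)
}

#' Expected non-synonymous and synonymous mutation rates of a CDS
#'
#' Sums the spectrum rates of all possible non-synonymous and synonymous
#' single-nucleotide changes of the coding sequence. The ratio
#' \code{n_exp / s_exp} is the neutral expectation used to normalize
#' observed counts in \code{\link{dndsEstimate}}; it is invariant to
#' rescaling of the spectrum.
#'
#' @inheritParams enumerateSites
#' @return Named numeric vector \code{c(n_exp, s_exp)}.
#' @examples
#' expectedNSCounts("ATGGCTGCT", uniformSpectrum())
#' @export
expectedNSCounts <- function(cds, spectrum = uniformSpectrum()) {
  sites <- enumerateSites(cds, spectrum)
  c(n_exp = sum(sites$rate[!sites$synonymous]),
    s_exp = sum(sites$rate[sites$synonymous]))
}

#' Bundled toy gene set
#'
#' A fixed set of short coding sequences (no stop codons) generated once
#' from an internal seed, shared between the simulator (which draws neutral
#' mutations from them) and the dN/dS expectation so that simulated cohorts
#' are exactly neutral by construction.
#'
#' @param nGenes Number of genes.
#' @param nCodons Codons per gene.
#' @param seed Internal seed; fixed default so the set is stable.
#' @return Named character vector of coding sequences.
#' @export
toyGeneSet <- function(nGenes = 4, nCodons = 400, seed = 99L) {
  old <- .restorableSeed()
  on.exit(old())
  set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  codons <- setdiff(apply(expand.grid(.BASES, .BASES, .BASES), 1, paste,
                          collapse = ""), stops)
  out <- vapply(seq_len(nGenes), function(i)
    paste(sample(codons, nCodons, replace = TRUE), collapse = ""),
    character(1))
  setNames(out, paste0("gene", seq_len(nGenes)))
}

#' Draw neutral mutations from a spectrum over a gene set
#'
#' Samples single-nucleotide changes with probability proportional to their
#' spectrum rate, i.e. with no selection on consequence; the resulting
#' mutation table has expected dN/dS of 1.
#'
#' @param genes Named character vector of coding sequences
#'   (\code{\link{toyGeneSet}}).
#' @param spectrum A \linkS4class{SpectrumModel}.
#' @param nMut Number of mutations to draw.
#' @param seed RNG seed.
#' @return data.frame with columns \code{gene}, \code{ref}, \code{alt},
#'   \code{context}, \code{consequence}.
#' @export
simulateNeutralMutations <- function(genes, spectrum = uniformSpectrum(),
                                     nMut = 100, seed = 1) {
  old <- .restorableSeed()
  on.exit(old())
  set.seed(seed)
  tabs <- lapply(genes, enumerateSites, spectrum = spectrum)
  all <- do.call(rbind, Map(function(g, t) cbind(gene = g, t),
                            names(tabs), tabs))
  rows <- sample.int(nrow(all), nMut, replace = TRUE, prob = all$rate)
  out <- all[rows, c("gene", "ref", "alt", "context", "consequence")]
  rownames(out) <- NULL
  out
}

## exact Poisson (Garwood) interval for a count
.garwood <- function(k, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (k == 0) 0 else qchisq(a, 2 * k) / 2
  hi <- qchisq(1 - a, 2 * (k + 1)) / 2
  c(lo, hi)
}

#' Timing-stratified dN/dS estimate with confidence intervals
#'
#' Computes, per stratum, the ratio of observed to expected non-synonymous
#' mutations over the ratio of observed to expected synonymous mutations:
#' \deqn{dN/dS = (n_{obs}/n_{exp}) / (s_{obs}/s_{exp})}
#' with the expectations from \code{\link{expectedNSCounts}} summed over the
#' gene set. Values above (below) 1 indicate positive (negative) selection.
#' The 95\% CI treats the observed counts as independent Poisson draws:
#' exact Garwood intervals on each count are combined on the log-ratio
#' scale, a deliberately simple, conservative stand-in for regression-based
#' intervals. Nonsense and splice mutations count as non-synonymous; set
#' \code{truncatingSeparately = TRUE} to also report a truncating-only
#' stratum (nonsense + splice against the nonsense-site expectation).
#'
#' @param mutations data.frame with at least a \code{consequence} column
#'   (values among synonymous/missense/nonsense/splice/other).
#' @param strata Optional vector of per-mutation stratum labels (e.g.
#'   \code{clonal_early}/\code{clonal_late}); \code{NULL} gives a single
#'   \code{"all"} stratum.
#' @param genes Named character vector of coding sequences defining the
#'   site expectation.
#' @param spectrum A \linkS4class{SpectrumModel}.
#' @param truncatingSeparately Also report truncating-only rows per stratum.
#' @return data.frame with one row per stratum: \code{stratum},
#'   \code{n_obs}, \code{s_obs}, \code{n_exp}, \code{s_exp}, \code{dnds},
#'   \code{ci_low}, \code{ci_high}, \code{flag} (\code{"s_obs=0"} when the
#'   upper bound is infinite).
#' @examples
#' muts <- simulateNeutralMutations(toyGeneSet(), nMut = 200, seed = 3)
#' dndsEstimate(muts, genes = toyGeneSet())
#' @export
dndsEstimate <- function(mutations, strata = NULL, genes = toyGeneSet(),
                         spectrum = uniformSpectrum(),
                         truncatingSeparately = FALSE) {
  if (!nrow(mutations))
    stop("no mutations supplied: dN/dS is undefined on an empty set")
  if (is.null(strata)) strata <- rep("all", nrow(mutations))
  if (length(strata) != nrow(mutations))
    stop("'strata' must have one label per mutation")
  exp2 <- Reduce(`+`, lapply(genes, expectedNSCounts, spectrum = spectrum))
  nExp <- exp2[["n_exp"]]; sExp <- exp2[["s_exp"]]
  if (sExp == 0) stop("undefined ratio: zero expected synonymous rate")
  nonsyn <- c("missense", "nonsense", "splice", "other")
  oneRow <- function(label, keep) {
    cons <- mutations$consequence[keep]
    nObs <- sum(cons %in% nonsyn)
    sObs <- sum(cons == "synonymous")
    nCI <- .garwood(nObs); sCI <- .garwood(sObs)
    point <- if (sObs > 0) (nObs / nExp) / (sObs / sExp) else Inf
    low <- if (sCI[2] > 0) (nCI[1] / nExp) / (sCI[2] / sExp) else 0
    high <- if (sCI[1] > 0) (nCI[2] / nExp) / (sCI[1] / sExp) else Inf
    data.frame(stratum = label, n_obs = nObs, s_obs = sObs,
               n_exp = nExp, s_exp = sExp, dnds = point, ci_low = low,
               ci_high = high,
               flag = if (sObs == 0) "s_obs=0" else "",
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(unique(strata), function(s)
    oneRow(s, strata == s)))
  if (truncatingSeparately) {
    sites <- do.call(rbind, lapply(genes, enumerateSites, spectrum = spectrum))
    truncExp <- sum(sites$rate[sites$aa_alt == "*" & !sites$synonymous])
    truncRows <- do.call(rbind, lapply(unique(strata), function(s) {
      keep <- strata == s
      cons <- mutations$consequence[keep]
      tObs <- sum(cons %in% c("nonsense", "splice"))
      sObs <- sum(cons == "synonymous")
      tCI <- .garwood(tObs); sCI <- .garwood(sObs)
      point <- if (sObs > 0) (tObs / truncExp) / (sObs / sExp) else Inf
      data.frame(stratum = paste0(s, "_truncating"), n_obs = tObs,
                 s_obs = sObs, n_exp = truncExp, s_exp = sExp, dnds = point,
                 ci_low = if (sCI[2] > 0) (tCI[1] / truncExp) / (sCI[2] / sExp) else 0,
                 ci_high = if (sCI[1] > 0) (tCI[2] / truncExp) / (sCI[1] / sExp) else Inf,
                 flag = if (sObs == 0) "s_obs=0" else "",
                 stringsAsFactors = FALSE)
    }))
    out <- rbind(out, truncRows)
  }
  rownames(out) <- NULL
  out
}

#' Chi-squared enrichment test on a 2x2 contingency table
#'
#' Pearson chi-squared without continuity correction (1 df), as used for
#' cohort category enrichment (e.g. WGD versus histology); Fisher's exact
#' test is available as an alternative.
#'
#' @param table 2x2 matrix of non-negative integer counts with all margins
#'   positive.
#' @param method \code{"chisq"} (default) or \code{"fisher"}.
#' @return List with \code{statistic} (NA for Fisher), \code{p.value} and
#'   \code{method}.
#' @examples
#' enrichmentTest(matrix(c(20, 5, 8, 17), 2))
#' @export
enrichmentTest <- function(table, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin: every row and column must have a positive total")
  if (method == "chisq") {
    ht <- suppressWarnings(chisq.test(table, correct = FALSE))
    list(statistic = unname(ht$statistic), p.value = ht$p.value,
         method = "chisq")
  } else {
    ht <- fisher.test(table)
    list(statistic = NA_real_, p.value = ht$p.value, method = "fisher")
  }
}
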