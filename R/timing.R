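## Mutation clonality via phyloCCF CI overlap and timing relative to WGD.

#' Mutation copy number from VAF
#'
#' Inverts the multiplicity/VAF relation of \code{\link{expectedVAF}}:
#' \code{mutCN = vaf * (purity * T + 2 * (1 - purity)) / purity}. Rounding
#' to an integer multiplicity is kept separate
#' (\code{\link{roundMultiplicity}}) so the raw value remains available for
#' CCF estimation.
#'
#' @param vaf Variant allele fraction in [0, 1].
#' @param purity Sample purity in (0, 1].
#' @param cnTotalTumour Total tumour copy number at the locus (>= 1).
#' @return Real-valued mutation copy number.
#' @examples
#' mutationCopyNumber(0.5, 1, 2)      # 1
#' mutationCopyNumber(1 / 3, 0.5, 4)  # 2
#' @export
mutationCopyNumber <- function(vaf, purity, cnTotalTumour) {
  if (any(purity <= 0 | purity > 1)) stop("'purity' must be in (0, 1]")
  if (any(vaf < 0 | vaf > 1)) stop("'vaf' must be in [0, 1]")
  if (any(cnTotalTumour < 1)) stop("'cnTotalTumour' must be >= 1")
  vaf * (purity * cnTotalTumour + 2 * (1 - purity)) / purity
}

#' Round a mutation copy number to an integer multiplicity
#'
#' Nearest integer with ties-to-even, clamped to [1, cnTotal]; intended for
#' mutations already established as present (clonal), hence the lower clamp
#' at one mutant copy.
#'
#' @param mutCN Real-valued mutation copy number.
#' @param cnTotal Total copy number at the locus (upper clamp).
#' @return Integer multiplicity.
#' @export
roundMultiplicity <- function(mutCN, cnTotal) {
  as.integer(pmin(pmax(round(mutCN), 1), cnTotal))
}

#' Classify a mutation cluster's clonality in one region
#'
#' A cluster is clonal in a region when its 95\% phyloCCF confidence
#' interval overlaps the trunk cluster's 95\% CI, where the trunk CI's left
#' bound is raised to at least 0.9; subclonal when its mean phyloCCF is
#' greater than 0 but the overlap test fails; absent otherwise.
#'
#' @param cluster List or one-row data.frame with \code{mean}, \code{low},
#'   \code{high} for the cluster in this region.
#' @param trunk Same for the trunk cluster in this region.
#' @param trunkFloor Minimum left bound imposed on the trunk CI
#'   (default 0.9).
#' @return \code{"clonal"}, \code{"subclonal"} or \code{"absent"}.
#' @examples
#' classifyClonality(list(mean = 0.95, low = 0.85, high = 1.0),
#'                   list(mean = 0.98, low = 0.92, high = 1.0))  # clonal
#' classifyClonality(list(mean = 0.30, low = 0.20, high = 0.40),
#'                   list(mean = 0.98, low = 0.92, high = 1.0))  # subclonal
#' @export
classifyClonality <- function(cluster, trunk, trunkFloor = 0.9) {
  need <- c("mean", "low", "high")
  if (!all(need %in% names(cluster)) || !all(need %in% names(trunk)))
    stop("cluster and trunk need 'mean', 'low' and 'high' entries")
  tLow <- max(trunk$low, trunkFloor)
  tHigh <- trunk$high
  if (cluster$high >= tLow && cluster$low <= tHigh) return("clonal")
  if (cluster$mean > 0) return("subclonal")
  "absent"
}

#' Time a clonal mutation relative to whole-genome doubling
#'
#' In a WGD tumour, a clonal mutation whose copy number is consistent with
#' the doubled ploidy (multiplicity >= 2 at a locus with major CN >= 2) was
#' present before the doubling and is called early; multiplicity 1 is
#' called late. Loci that lost copies down to major CN < 2 are
#' uninformative (\code{"not_applicable"}), as is everything in tumours
#' without WGD.
#'
#' @param multiplicity Rounded integer multiplicity of the mutation.
#' @param cnMajor Major-allele copy number at the locus.
#' @param gd A \linkS4class{GDStatus} (or integer number of WGD events).
#' @param cnTotal Optional total copy number at the locus; when supplied, a
#'   multiplicity above it raises an error.
#' @return \code{"early"}, \code{"late"} or \code{"not_applicable"}.
#' @examples
#' timeMutationVsWGD(2, 2, 1L)  # early
#' timeMutationVsWGD(1, 2, 1L)  # late
#' @export
timeMutationVsWGD <- function(multiplicity, cnMajor, gd, cnTotal = NULL) {
  n <- if (methods::is(gd, "GDStatus")) nWGD(gd) else as.integer(gd)
  if (!is.null(cnTotal) && multiplicity > cnTotal)
    stop("multiplicity exceeds the total copy number at the locus")
  if (n == 0L) return("not_applicable")
  if (cnMajor < 2) return("not_applicable")
  if (multiplicity >= 2) return("early")
  "late"
}

#' Estimate per-cluster, per-region phyloCCF with bootstrap CIs
#'
#' A deliberately simple phyloCCF construction from read counts: each
#' mutation's CCF in a region is its mutation copy number divided by its
#' rounded multiplicity; cluster-level means get 95\% percentile bootstrap
#' intervals over the cluster's mutations (degenerate intervals for
#' single-mutation clusters). CCFs are capped at 1.2 to absorb noise.
#'
#' @param case A \linkS4class{TumourCase} with mutations and read counts.
#' @param nBoot Bootstrap replicates (default 200).
#' @param seed RNG seed for the bootstrap.
#' @return The case with its \code{clusterCCF} slot filled: columns
#'   \code{cluster}, \code{region}, \code{mean}, \code{low}, \code{high}.
#' @export
estimateClusterCCF <- function(case, nBoot = 200, seed = 1) {
  old <- .restorableSeed()
  on.exit(old())
  set.seed(seed)
  muts <- case@mutations
  if (!nrow(muts)) {
    case@clusterCCF <- .emptyClusterCCF()
    return(case)
  }
  counts <- case@mutCounts
  rows <- list()
  for (prof in case@regions) {
    rid <- regionID(prof)
    cc <- counts[counts$region == rid, ]
    cc <- cc[match(muts$mut_id, cc$mut_id), ]
    depth <- cc$ref_count + cc$alt_count
    vaf <- ifelse(depth > 0, cc$alt_count / depth, 0)
    cnT <- .localTotalCN(prof, muts$chrom, muts$pos)
    mutCN <- mutationCopyNumber(pmin(vaf, 1), purity(prof), pmax(cnT, 1))
    ccf <- pmin(mutCN / pmax(1, round(mutCN)), 1.2)
    for (cl in sort(unique(muts$cluster))) {
      x <- ccf[muts$cluster == cl]
      if (length(x) == 1L) {
        ci <- c(x, x)
      } else {
        bm <- vapply(seq_len(nBoot), function(b)
          mean(sample(x, replace = TRUE)), numeric(1))
        ci <- unname(quantile(bm, c(0.025, 0.975)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, region = rid, mean = mean(x),
        low = min(ci[1], mean(x)), high = max(ci[2], mean(x)),
        stringsAsFactors = FALSE)
    }
  }
  case@clusterCCF <- do.call(rbind, rows)
  case
}

## total CN of the segment containing each (chrom, pos); NA when uncovered
.localTotalCN <- function(profile, chrom, pos) {
  st <- .segTable(profile)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(st$chrom, IRanges::IRanges(st$start, st$end))
  hit <- GenomicRanges::findOverlaps(q, s, select = "first")
  out <- rep(NA_real_, length(chrom))
  ok <- !is.na(hit)
  out[ok] <- st$cnMajor[hit[ok]] + st$cnMinor[hit[ok]]
  out
}

.localMajorCN <- function(profile, chrom, pos) {
  st <- .segTable(profile)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  s <- GenomicRanges::GRanges(st$chrom, IRanges::IRanges(st$start, st$end))
  hit <- GenomicRanges::findOverlaps(q, s, select = "first")
  out <- rep(NA_real_, length(chrom))
  ok <- !is.na(hit)
  out[ok] <- st$cnMajor[hit[ok]]
  out
}

#' Cluster- and mutation-level clonality for a whole case
#'
#' Applies \code{\link{classifyClonality}} to every cluster in every
#' region. A mutation is clonal at tumour level when its cluster is clonal
#' in every region, subclonal when its cluster has positive CCF somewhere
#' without being clonal everywhere, and absent otherwise. The resulting
#' partition is exhaustive and exclusive, and independent of region order.
#'
#' @param case A \linkS4class{TumourCase} whose \code{clusterCCF} slot is
#'   filled (see \code{\link{estimateClusterCCF}}).
#' @param trunkFloor Passed to \code{\link{classifyClonality}}.
#' @return List with \code{perRegion} (data.frame cluster x region x label)
#'   and \code{byCluster} (named vector of tumour-level labels).
#' @export
caseClonality <- function(case, trunkFloor = 0.9) {
  ccf <- case@clusterCCF
  if (!nrow(ccf)) stop("clusterCCF is empty; run estimateClusterCCF() first")
  trunkId <- case@clusters$cluster[case@clusters$is_trunk][1]
  regionsIDs <- vapply(case@regions, regionID, character(1))
  per <- do.call(rbind, lapply(sort(unique(ccf$cluster)), function(cl) {
    do.call(rbind, lapply(regionsIDs, function(rid) {
      cRow <- ccf[ccf$cluster == cl & ccf$region == rid, ]
      tRow <- ccf[ccf$cluster == trunkId & ccf$region == rid, ]
      if (!nrow(cRow) || !nrow(tRow))
        stop("missing clusterCCF entry for cluster ", cl, " in region ", rid)
      data.frame(cluster = cl, region = rid,
                 label = classifyClonality(cRow, tRow, trunkFloor),
                 stringsAsFactors = FALSE)
    }))
  }))
  byCluster <- vapply(sort(unique(per$cluster)), function(cl) {
    lab <- per$label[per$cluster == cl]
    mn <- ccf$mean[ccf$cluster == cl]
    if (all(lab == "clonal")) "clonal"
    else if (any(mn > 0)) "subclonal"
    else "absent"
  }, character(1))
  names(byCluster) <- sort(unique(per$cluster))
  list(perRegion = per, byCluster = byCluster)
}

#' Time all clonal mutations of a case relative to WGD
#'
#' For each tumour-level clonal mutation, estimates its multiplicity by a
#' depth-weighted average of per-region mutation copy numbers (rounded
#' ties-to-even, clamped to the local total CN), then applies the
#' early/late rule per region and takes the majority label over informative
#' regions (ties resolve to late, the conservative call).
#'
#' @param case A \linkS4class{TumourCase}.
#' @param gd Tumour-level number of WGD events (integer or
#'   \linkS4class{GDStatus}).
#' @param clonality Output of \code{\link{caseClonality}}; computed from
#'   the case when \code{NULL}.
#' @param seed Seed for the CCF bootstrap when clonality must be computed.
#' @return data.frame: \code{mut_id}, \code{cluster}, \code{clonality},
#'   \code{multiplicity}, \code{timing}.
#' @export
timeMutations <- function(case, gd, clonality = NULL, seed = 1) {
  nGD <- if (methods::is(gd, "GDStatus")) nWGD(gd) else as.integer(gd)
  if (is.null(clonality)) {
    if (!nrow(case@clusterCCF)) case <- estimateClusterCCF(case, seed = seed)
    clonality <- caseClonality(case)
  }
  muts <- case@mutations
  if (!nrow(muts))
    return(data.frame(mut_id = character(), cluster = integer(),
                      clonality = character(), multiplicity = integer(),
                      timing = character(), stringsAsFactors = FALSE))
  counts <- case@mutCounts
  R <- length(case@regions)
  mutCN <- matrix(NA_real_, nrow(muts), R)
  wts <- matrix(0, nrow(muts), R)
  cnMaj <- matrix(NA_real_, nrow(muts), R)
  cnTot <- matrix(NA_real_, nrow(muts), R)
  for (r in seq_len(R)) {
    prof <- case@regions[[r]]
    cc <- counts[counts$region == regionID(prof), ]
    cc <- cc[match(muts$mut_id, cc$mut_id), ]
    depth <- cc$ref_count + cc$alt_count
    vaf <- ifelse(depth > 0, cc$alt_count / depth, 0)
    cnTot[, r] <- .localTotalCN(prof, muts$chrom, muts$pos)
    cnMaj[, r] <- .localMajorCN(prof, muts$chrom, muts$pos)
    mutCN[, r] <- mutationCopyNumber(pmin(vaf, 1), purity(prof),
                                     pmax(cnTot[, r], 1))
    wts[, r] <- ifelse(is.na(depth), 0, depth)
  }
  wsum <- rowSums(wts)
  est <- rowSums(mutCN * wts, na.rm = TRUE) / ifelse(wsum > 0, wsum, 1)
  clusterLabel <- clonality$byCluster[as.character(muts$cluster)]
  mult <- roundMultiplicity(est, apply(cnTot, 1, max, na.rm = TRUE))
  timing <- vapply(seq_len(nrow(muts)), function(i) {
    if (clusterLabel[i] != "clonal") return("not_applicable")
    if (nGD == 0L) return("not_applicable")
    labs <- vapply(seq_len(R), function(r) {
      if (is.na(cnMaj[i, r])) return("not_applicable")
      timeMutationVsWGD(min(mult[i], cnTot[i, r]), cnMaj[i, r], nGD)
    }, character(1))
    labs <- labs[labs != "not_applicable"]
    if (!length(labs)) return("not_applicable")
    if (sum(labs == "early") > length(labs) / 2) "early" else "late"
  }, character(1))
  data.frame(mut_id = muts$mut_id, cluster = muts$cluster,
             clonality = unname(clusterLabel), multiplicity = mult,
             timing = timing, stringsAsFactors = FALSE)
}
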