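## Independent brute-force oracles and fixture builders used across the
## suite. These deliberately re-derive every rule from its plain-language
## statement with naive scans, sharing no code with the package internals.

## ---- profile fixtures ---------------------------------------------------

flatProfile <- function(cnMajor = 1, cnMinor = 1, genome = toyGenome(),
                        purity = 1, id = "R1") {
  lens <- chromLengths(genome)
  RegionProfile(id, data.frame(chrom = names(lens), start = 1, end = lens,
                               cn_major = cnMajor, cn_minor = cnMinor),
                purity)
}

## one-chromosome profile from widths (Mb) and CN pairs
chromProfile <- function(widthsMb, major, minor, chrom = "chr1", id = "R1") {
  ends <- cumsum(widthsMb) * 1e6
  starts <- c(1, head(ends, -1) + 1)
  RegionProfile(id, data.frame(chrom = chrom, start = starts, end = ends,
                               cn_major = major, cn_minor = minor))
}

## random profile over a random subset of the toy genome; segments cover
## each chromosome fully
randomProfile <- function(seed, maxBreaks = 5, genome = toyGenome()) {
  set.seed(seed)
  lens <- chromLengths(genome)
  chroms <- sample(names(lens), sample(2:length(lens), 1))
  segs <- do.call(rbind, lapply(sort(chroms), function(ch) {
    nb <- sample(0:maxBreaks, 1)
    cuts <- sort(sample(seq(2e6, lens[[ch]] - 2e6, by = 1e6), nb))
    starts <- c(1, cuts + 1)
    ends <- c(cuts, lens[[ch]])
    minor <- sample(0:3, length(starts), replace = TRUE)
    major <- minor + sample(0:3, length(starts), replace = TRUE)
    major <- pmax(major, 1)
    data.frame(chrom = ch, start = starts, end = ends, cn_major = major,
               cn_minor = minor)
  }))
  RegionProfile(paste0("S", seed), segs)
}

segFrame <- function(profile) {
  gr <- cnSegments(profile)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
             M = GenomicRanges::mcols(gr)$cnMajor,
             m = GenomicRanges::mcols(gr)$cnMinor,
             stringsAsFactors = FALSE)
}

## ---- scar-score oracles -------------------------------------------------

## join touching runs of equal (M, m)
oracleJoin <- function(d) {
  d <- d[order(d$start), , drop = FALSE]
  out <- d[1, , drop = FALSE]
  for (i in seq_len(nrow(d))[-1]) {
    k <- nrow(out)
    if (d$start[i] == out$end[k] + 1 && d$M[i] == out$M[k] &&
        d$m[i] == out$m[k]) {
      out$end[k] <- d$end[i]
    } else out <- rbind(out, d[i, , drop = FALSE])
  }
  out
}

oracleSmooth <- function(d, minLen = 3e6) {
  repeat {
    d <- oracleJoin(d)
    w <- d$end - d$start + 1
    if (all(w >= minLen) || nrow(d) == 1) return(d)
    i <- which.min(ifelse(w < minLen, w, Inf))
    wl <- if (i > 1) w[i - 1] else -1
    wr <- if (i < nrow(d)) w[i + 1] else -1
    j <- if (wl >= wr) i - 1 else i + 1
    d$M[i] <- d$M[j]; d$m[i] <- d$m[j]
  }
}

oracleLST <- function(profile, minSeg = 10e6, smoothLen = 3e6) {
  d <- segFrame(profile)
  n <- 0L
  for (ch in unique(d$chrom)) {
    s <- oracleSmooth(d[d$chrom == ch, , drop = FALSE], smoothLen)
    if (nrow(s) < 2) next
    for (i in seq_len(nrow(s) - 1)) {
      wl <- s$end[i] - s$start[i] + 1
      wr <- s$end[i + 1] - s$start[i + 1] + 1
      if (wl >= minSeg && wr >= minSeg &&
          (s$M[i] != s$M[i + 1] || s$m[i] != s$m[i + 1])) n <- n + 1L
    }
  }
  n
}

oracleTAI <- function(profile, genome = toyGenome(), wholeFrac = 0.95) {
  d <- segFrame(profile)
  lens <- chromLengths(genome)
  cen <- centromeres(genome)
  n <- 0L
  for (ch in unique(d$chrom)) {
    s <- oracleJoin(d[d$chrom == ch, , drop = FALSE])
    L <- lens[[ch]]
    cs <- cen$start[cen$chrom == ch]; ce <- cen$end[cen$chrom == ch]
    for (i in seq_len(nrow(s))) {
      if (s$M[i] == s$m[i]) next
      reachesTelomere <- s$start[i] == 1 || s$end[i] == L
      spansCentromere <- s$start[i] <= cs && s$end[i] >= ce
      whole <- (s$end[i] - s$start[i] + 1) >= wholeFrac * L
      if (reachesTelomere && !spansCentromere && !whole) n <- n + 1L
    }
  }
  n
}

oracleHRDLOH <- function(profile, genome = toyGenome(), minLen = 15e6,
                         wholeFrac = 0.95) {
  d <- segFrame(profile)
  lens <- chromLengths(genome)
  n <- 0L
  for (ch in unique(d$chrom)) {
    s <- oracleJoin(d[d$chrom == ch, , drop = FALSE])
    for (i in seq_len(nrow(s))) {
      w <- s$end[i] - s$start[i] + 1
      if (s$m[i] == 0 && s$M[i] >= 1 && w > minLen &&
          w < wholeFrac * lens[[ch]]) n <- n + 1L
    }
  }
  n
}

oracleWGII <- function(profile) {
  d <- segFrame(profile)
  w <- d$end - d$start + 1
  ploidy <- round(sum((d$M + d$m) * w) / sum(w))
  mean(vapply(unique(d$chrom), function(ch) {
    s <- d[d$chrom == ch, ]
    sw <- s$end - s$start + 1
    sum(sw[s$M + s$m != ploidy]) / sum(sw)
  }, numeric(1)))
}

## ---- dN/dS site-enumeration oracle --------------------------------------

## naive per-site loop using its own codon table; context wraps around the
## sequence ends like the package convention
oracleCodonTable <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    b <- c("T", "C", "A", "G")
    aas <- strsplit(paste0(
      "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
      "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
    nm <- character(64)
    k <- 0
    for (b1 in b) for (b2 in b) for (b3 in b) {
      k <- k + 1
      nm[k] <- paste0(b1, b2, b3)
    }
    tab <<- setNames(aas, nm)
    tab
  }
})

oracleClassName <- function(context, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- substr(context, 2, 2)
  if (ref %in% c("A", "G")) {
    sp <- rev(strsplit(context, "")[[1]])
    context <- paste(comp[sp], collapse = "")
    alt <- comp[[alt]]
  }
  paste0(substr(context, 1, 1), "[", substr(context, 2, 2), ">", alt, "]",
         substr(context, 3, 3))
}

oracleNSCounts <- function(cds, rates) {
  ct <- oracleCodonTable()
  bases <- strsplit(cds, "")[[1]]
  L <- length(bases)
  nExp <- 0; sExp <- 0
  for (p in seq_len(L)) {
    codonStart <- 3 * ((p - 1) %/% 3) + 1
    codon <- paste(bases[codonStart:(codonStart + 2)], collapse = "")
    for (alt in setdiff(c("A", "C", "G", "T"), bases[p])) {
      mut <- bases
      mut[p] <- alt
      mutCodon <- paste(mut[codonStart:(codonStart + 2)], collapse = "")
      up <- bases[if (p == 1) L else p - 1]
      dn <- bases[if (p == L) 1 else p + 1]
      cls <- oracleClassName(paste0(up, bases[p], dn), alt)
      r <- rates[[cls]]
      if (ct[[codon]] == ct[[mutCodon]]) sExp <- sExp + r
      else nExp <- nExp + r
    }
  }
  c(n_exp = nExp, s_exp = sExp)
}

randomCDS <- function(nCodons, seed) {
  set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  codons <- setdiff(codons, stops)
  paste(sample(codons, nCodons, replace = TRUE), collapse = "")
}

randomSpectrum <- function(seed) {
  set.seed(seed)
  spectrumModel(setNames(stats::rgamma(96, 1), trinucClasses()))
}

## ---- chi-squared by hand -------------------------------------------------

oracleChi2 <- function(t) {
  N <- sum(t)
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}
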