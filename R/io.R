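## Tab-delimited I/O. All on-disk coordinates are 1-based inclusive; files
## are UTF-8 TSV with a header line and '#' comments allowed.

.readTsv <- function(path, required, label) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("schema error in %s (%s): missing required column(s) %s",
                 label, path, paste(miss, collapse = ", ")))
  extra <- setdiff(names(df), required)
  if (length(extra))
    warning(sprintf("%s: ignoring unknown column(s) %s", label,
                    paste(extra, collapse = ", ")))
  df
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write allele-specific copy-number segments (SEG-like TSV)
#'
#' Columns: \code{sample}, \code{chrom}, \code{start}, \code{end},
#' \code{cn_major}, \code{cn_minor}; coordinates 1-based inclusive. Rows
#' with \code{start >= end} raise a schema error naming the row.
#'
#' @param path TSV file path.
#' @param purity Optional named vector of per-sample purities (default 1).
#' @return \code{readSegments}: named list of \linkS4class{RegionProfile}.
#' @export
readSegments <- function(path, purity = NULL) {
  df <- .readTsv(path, c("sample", "chrom", "start", "end", "cn_major",
                         "cn_minor"), "segment table")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(sprintf("schema error in %s: start >= end at row %d", path, bad[1]))
  out <- lapply(split(df, df$sample), function(d) {
    p <- if (!is.null(purity) && d$sample[1] %in% names(purity))
      purity[[d$sample[1]]] else 1
    RegionProfile(d$sample[1], d[c("chrom", "start", "end", "cn_major",
                                   "cn_minor")], p)
  })
  out[unique(df$sample)]
}

#' @rdname readSegments
#' @param profiles List of \linkS4class{RegionProfile} to write.
#' @export
writeSegments <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    st <- .segTable(p)
    data.frame(sample = regionID(p), chrom = st$chrom, start = st$start,
               end = st$end, cn_major = st$cnMajor, cn_minor = st$cnMinor,
               stringsAsFactors = FALSE)
  }))
  .writeTsv(rows, path)
}

#' Read/write mutation tables
#'
#' Long TSV with per-mutation metadata repeated per region: \code{mut_id},
#' \code{chrom}, \code{pos}, \code{ref}, \code{alt}, \code{gene},
#' \code{consequence}, \code{context}, \code{cluster}, \code{region},
#' \code{ref_count}, \code{alt_count}.
#'
#' @param path TSV file path.
#' @return \code{readMutations}: list with \code{mutations} (per-mutation
#'   metadata) and \code{counts} (per-region read counts).
#' @export
readMutations <- function(path) {
  cols <- c("mut_id", "chrom", "pos", "ref", "alt", "gene", "consequence",
            "context", "cluster", "region", "ref_count", "alt_count")
  df <- .readTsv(path, cols, "mutation table")
  meta <- unique(df[c("mut_id", "chrom", "pos", "ref", "alt", "gene",
                      "consequence", "context", "cluster")])
  rownames(meta) <- NULL
  list(mutations = meta,
       counts = df[c("mut_id", "region", "ref_count", "alt_count")])
}

#' @rdname readMutations
#' @param mutations,counts As produced by \code{\link{readMutations}} or
#'   stored in a \linkS4class{TumourCase}.
#' @export
writeMutations <- function(mutations, counts, path) {
  df <- merge(counts, mutations, by = "mut_id", sort = FALSE)
  df <- df[order(df$mut_id, df$region),
           c("mut_id", "chrom", "pos", "ref", "alt", "gene", "consequence",
             "context", "cluster", "region", "ref_count", "alt_count")]
  .writeTsv(df, path)
}

#' Read mutations from a minimal multi-sample VCF
#'
#' Accepts a VCF whose samples are tumour regions with an \code{AD}
#' FORMAT field (\code{ref,alt} depths) and optional INFO keys \code{GENE},
#' \code{CSQ} (consequence), \code{CTX} (trinucleotide context) and
#' \code{CLU} (cluster). Produces the same structure as
#' \code{\link{readMutations}} on equivalent data.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return List with \code{mutations} and \code{counts} data.frames.
#' @export
readMutationsVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (is.null(x)) rep(NA_character_, nrow(fix)) else x
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad)) stop("schema error: VCF has no AD FORMAT field")
  ids <- fix$ID
  if (is.null(ids) || all(is.na(ids)))
    ids <- sprintf("M%04d", seq_len(nrow(fix)))
  meta <- data.frame(
    mut_id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, gene = info("GENE"),
    consequence = info("CSQ"), context = info("CTX"),
    cluster = as.integer(info("CLU")), stringsAsFactors = FALSE)
  counts <- do.call(rbind, lapply(colnames(ad), function(rg) {
    parts <- strsplit(ad[, rg], ",", fixed = TRUE)
    data.frame(mut_id = ids, region = rg,
               ref_count = as.integer(vapply(parts, `[`, character(1), 1)),
               alt_count = as.integer(vapply(parts, `[`, character(1), 2)),
               stringsAsFactors = FALSE)
  }))
  rownames(counts) <- NULL
  list(mutations = meta, counts = counts)
}

#' Read/write heterozygous-SNP BAF tables
#'
#' Long TSV: \code{chrom}, \code{pos}, \code{region}, \code{baf},
#' \code{depth}.
#'
#' @param path TSV file path.
#' @return \code{readBAFs}: the data.frame.
#' @export
readBAFs <- function(path) {
  .readTsv(path, c("chrom", "pos", "region", "baf", "depth"), "BAF table")
}

#' @rdname readBAFs
#' @param snps data.frame in the same layout.
#' @export
writeBAFs <- function(snps, path) .writeTsv(snps, path)

#' Read a cytoband table (BED-like TSV)
#'
#' Columns \code{chrom}, \code{start}, \code{end}, \code{band}; 1-based
#' inclusive like every other table in the package.
#'
#' @param path TSV file path.
#' @return data.frame of bands.
#' @export
readCytobands <- function(path) {
  .readTsv(path, c("chrom", "start", "end", "band"), "cytoband table")
}

#' Read a genome annotation table
#'
#' Columns \code{chrom}, \code{length}, \code{cen_start}, \code{cen_end}.
#'
#' @param path TSV file path.
#' @return A \linkS4class{GenomeAnnotation}.
#' @export
readGenomeAnnotation <- function(path) {
  df <- .readTsv(path, c("chrom", "length", "cen_start", "cen_end"),
                 "genome annotation")
  genomeAnnotation(setNames(df$length, df$chrom),
                   data.frame(chrom = df$chrom, start = df$cen_start,
                              end = df$cen_end, stringsAsFactors = FALSE))
}

#' Write / read a complete simulated case directory
#'
#' \code{writeCase} serializes a case (and optionally its truth record) as
#' \code{segments.seg.tsv}, \code{mutations.tsv}, \code{snps_baf.tsv},
#' \code{samples.tsv} (region purities and histology) and
#' \code{truth.json}. \code{readCase} reads the directory back, applying
#' the purity floor: regions with purity below \code{minPurity} are
#' excluded and reported.
#'
#' @param case A \linkS4class{TumourCase}.
#' @param dir Directory to write into (created if needed).
#' @param truth Optional truth record from \code{\link{simulateCase}}.
#' @return \code{writeCase}: the directory, invisibly. \code{readCase}: a
#'   list with \code{case}, \code{truth} (NULL if absent) and
#'   \code{excluded} (character vector of dropped regions).
#' @export
writeCase <- function(case, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSegments(case@regions, file.path(dir, "segments.seg.tsv"))
  writeMutations(case@mutations, case@mutCounts,
                 file.path(dir, "mutations.tsv"))
  writeBAFs(case@snps, file.path(dir, "snps_baf.tsv"))
  samples <- data.frame(
    region = vapply(case@regions, regionID, character(1)),
    purity = vapply(case@regions, purity, numeric(1)),
    stringsAsFactors = FALSE)
  samples$tumour <- tumourID(case)
  samples$histology <- if (is.null(case@meta$histology)) NA_character_
                       else case@meta$histology
  .writeTsv(samples, file.path(dir, "samples.tsv"))
  .writeTsv(case@clusters, file.path(dir, "clusters.tsv"))
  if (!is.null(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
  invisible(dir)
}

#' @rdname writeCase
#' @param minPurity Purity floor; regions below it are excluded at load
#'   (default 0.10).
#' @param genome Annotation to attach to the case.
#' @export
readCase <- function(dir, minPurity = 0.10, genome = toyGenome()) {
  samples <- .readTsv(file.path(dir, "samples.tsv"),
                      c("region", "purity", "tumour", "histology"),
                      "sample table")
  pur <- setNames(samples$purity, samples$region)
  profiles <- readSegments(file.path(dir, "segments.seg.tsv"), purity = pur)
  excluded <- names(profiles)[vapply(profiles, purity, numeric(1)) < minPurity]
  profiles <- profiles[setdiff(names(profiles), excluded)]
  if (!length(profiles))
    stop("all regions excluded by the purity floor in ", dir)
  m <- readMutations(file.path(dir, "mutations.tsv"))
  m$counts <- m$counts[!m$counts$region %in% excluded, ]
  snps <- readBAFs(file.path(dir, "snps_baf.tsv"))
  snps <- snps[!snps$region %in% excluded, ]
  clusters <- .readTsv(file.path(dir, "clusters.tsv"),
                       c("cluster", "is_trunk"), "cluster table")
  truthPath <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthPath))
    jsonlite::read_json(truthPath, simplifyVector = TRUE) else NULL
  case <- TumourCase(samples$tumour[1], unname(profiles), mutations = m$mutations,
                     mutCounts = m$counts, snps = snps, clusters = clusters,
                     genome = genome,
                     meta = list(histology = samples$histology[1]))
  list(case = case, truth = truth, excluded = excluded)
}
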