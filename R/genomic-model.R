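## Methylation BED serialization and CpG strand merging.
##
## The methylation BED is 5 tab-separated columns with 0-based half-open
## coordinates: chrom, start, end, beta, coverage. Beta is written with 4
## decimal places; counts are reconstructed by rounding beta x coverage,
## which is lossy beyond coverage 10,000.

#' Read a methylation BED file
#'
#' @param path Path to a 5-column tab-separated file (chrom, start, end,
#'   beta, coverage), optionally gzip-compressed.
#' @return A [MethylSiteSet-class] of CpG records (strand `*`). Counts are
#'   reconstructed as `M = round(beta * coverage)`, `U = coverage - M`.
#' @export
readMethylationBed <- function(path) {
  dt <- if (endsWith(path, ".gz")) {
    as.data.table(utils::read.table(gzfile(path), sep = "\t",
                                    colClasses = c("character", "integer",
                                                   "integer", "numeric",
                                                   "integer")))
  } else {
    fread(path, header = FALSE, sep = "\t")
  }
  if (ncol(dt) != 5L)
    stop("malformed methylation BED: expected 5 columns, got ", ncol(dt),
         call. = FALSE)
  setnames(dt, c("chrom", "start", "end", "beta", "coverage"))
  bad <- which(!is.character(dt$chrom) | is.na(dt$chrom) |
               is.na(dt$start) | is.na(dt$end) | is.na(dt$beta) |
               is.na(dt$coverage) | dt$start < 0 | dt$end <= dt$start |
               dt$coverage <= 0)
  if (length(bad))
    stop("malformed methylation BED line ", bad[1L], call. = FALSE)
  if (any(dt$beta < 0 | dt$beta > 1))
    stop("beta outside [0, 1] at line ",
         which(dt$beta < 0 | dt$beta > 1)[1L], call. = FALSE)
  M <- as.integer(round(dt$beta * dt$coverage))
  gr <- GRanges(dt$chrom, IRanges(dt$start + 1L, dt$end),
                context = "CpG", M = M,
                U = as.integer(dt$coverage) - M)
  MethylSiteSet(gr)
}

#' Write a methylation BED file
#'
#' @param msset A [MethylSiteSet-class] (typically merged CpG records).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param digits Decimal places for beta (default 4).
#' @return `path`, invisibly.
#' @export
writeMethylationBed <- function(msset, path, digits = 4L) {
  gr <- siteRecords(msset)
  mc <- mcols(gr)
  covv <- mc$M + mc$U
  dt <- data.table(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr),
                   beta = formatC(mc$M / covv, digits = digits,
                                  format = "f"),
                   coverage = covv)
  fwrite(dt, path, sep = "\t", col.names = FALSE,
         compress = if (endsWith(path, ".gz")) "gzip" else "none")
  invisible(path)
}

#' Merge CpG records across strands
#'
#' The two cytosines of a palindromic CpG sit at adjacent positions on
#' opposite strands; their M and U counts are summed into one record
#' anchored at the top-strand C (a width-2 range, strand `*`). CpGs
#' observed on only one strand pass through unchanged (minus-only records
#' are re-anchored at the top-strand position). Non-CpG contexts are not
#' merged and are dropped from the output.
#'
#' @param msset A [MethylSiteSet-class] of strand-resolved records, sorted
#'   by position (as produced by [extractMethylation()]).
#' @return A [MethylSiteSet-class] of merged CpG records, sorted; total M
#'   and U are conserved.
#' @export
mergeCpGStrands <- function(msset) {
  gr <- siteRecords(msset)
  gr <- gr[mcols(gr)$context == "CpG"]
  if (!identical(order(as.integer(seqnames(gr)), start(gr)),
                 seq_along(gr)))
    stop("input records must be sorted by (chrom, start)", call. = FALSE)
  dt <- data.table(chrom = as.character(seqnames(gr)),
                   pos = start(gr),
                   minus = as.character(strand(gr)) == "-",
                   M = mcols(gr)$M, U = mcols(gr)$U)
  ## anchor: top-strand C position of the palindrome
  dt[, anchor := fifelse(minus, pos - 1L, pos)]
  agg <- dt[, .(M = sum(M), U = sum(U)), by = .(chrom, anchor)]
  agg[, chrom_i := as.integer(factor(chrom, levels = seqlevels(gr)))]
  setorder(agg, chrom_i, anchor)
  out <- GRanges(factor(agg$chrom, levels = seqlevels(gr)),
                 IRanges(agg$anchor, width = 2L),
                 context = "CpG", M = agg$M, U = agg$U,
                 seqinfo = seqinfo(gr))
  MethylSiteSet(out)
}

#' Read region annotations from a BED file
#'
#' BED3+label (label in the fourth/name column, BED 0-based half-open);
#' one [RegionSet-class] label per distinct value.
#'
#' @param path Path to the BED file.
#' @return A [RegionSet-class].
#' @export
readRegionsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(mcols(gr)$name))
    stop("regions BED needs a label in column 4", call. = FALSE)
  labs <- unique(mcols(gr)$name)
  args <- lapply(labs, function(lb) granges(gr[mcols(gr)$name == lb]))
  names(args) <- labs
  do.call(RegionSet, args)
}

#' Read a mappability track from a bedGraph file
#'
#' @param path Path to a bedGraph file (chrom, start, end, score in
#'   \[0, 1\]).
#' @return A [MappabilityTrack-class].
#' @export
readMappabilityBedGraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  MappabilityTrack(gr)
}
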