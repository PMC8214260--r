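## Per-site methylation extraction, context-stratified retention, M-bias,
## and conversion-control assessment.

## strand whose cytosines a read reports, by bisulfite strand
.parent_strand <- c(OT = "+", CTOT = "+", OB = "-", CTOB = "-")

## Cytosine observations of qualifying reads against the reference census.
## Returns a data.table with one row per (read, cytosine) observation:
## site index into `sites`, read number, read position, and observed state
## ("M" retained, "U" converted, "O" other).
.cytosineObservations <- function(rd, sites) {
  if (!nrow(rd))
    return(data.table(site = integer(0), read = integer(0),
                      read_pos = integer(0), state = character(0),
                      width = integer(0)))
  reads_gr <- GRanges(rd$chrom, IRanges(rd$pos + 1L, width = rd$width))
  hits <- findOverlaps(reads_gr, sites, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  keep <- as.character(strand(sites))[sh] == .parent_strand[rd$bs_strand[qh]]
  qh <- qh[keep]; sh <- sh[keep]
  off <- start(sites)[sh] - (rd$pos[qh] + 1L)
  read_pos <- ifelse(rd$reverse[qh], rd$width[qh] - off, off + 1L)
  ## observed base at the site, from the concatenated read sequences
  offsets <- c(0L, cumsum(rd$width))
  bytes <- seqBytes(rd$seq)
  obs <- bytes[offsets[qh] + off + 1L]
  bs <- rd$bs_strand[qh]
  ret <- as.integer(charToRaw(paste(.retained_letter[bs], collapse = "")))
  con <- as.integer(charToRaw(paste(.converted_letter[bs], collapse = "")))
  state <- rep("O", length(obs))
  state[obs == ret] <- "M"
  state[obs == con] <- "U"
  data.table(site = sh, read = rd$read[qh], read_pos = read_pos,
             state = state, width = rd$width[qh])
}

.qualifyReads <- function(frags, genome, mapq_min, exclude_duplicates) {
  rd <- fragmentReads(frags)
  rd <- rd[mapped == TRUE & mapq >= mapq_min]
  if (exclude_duplicates) rd <- rd[dup == FALSE]
  bad <- setdiff(unique(rd$chrom), names(genomeSequences(genome)))
  if (length(bad))
    stop("fragments reference contigs absent from the reference: ",
         paste(bad, collapse = ", "), call. = FALSE)
  rd
}

#' Extract per-site methylation from aligned fragments
#'
#' Re-infers the conversion state of every cytosine observation by comparing
#' the aligned read bases to the reference: for OT/CTOB-strand reads the
#' cytosines are the reference top-strand Cs, for OB/CTOT reads the
#' bottom-strand Cs (reference Gs); the retained/converted letters follow
#' the bisulfite strand, so PBAT (CTOT/CTOB) fragments are strand-flipped
#' in silico before context assignment. Observations within `end_clip`
#' bases of either read end are excluded (aligner-style end trimming), as
#' are the first `r2_clip` positions of read 2 (Adaptase tail). Only mapped,
#' non-duplicate reads with MAPQ >= `mapq_min` contribute. Context is the
#' reference dinucleotide 3' of the cytosine on its own strand; cytosines
#' with an ambiguous neighbour are excluded.
#'
#' @param frags A [FragmentSet-class].
#' @param genome A [SyntheticGenome-class] (or any object with the same
#'   accessors) providing the reference sequences.
#' @param end_clip Bases excluded at both read ends (default 3).
#' @param r2_clip Additional bases excluded at the start of read 2
#'   (default 0; set to the protocol's `r2_tail_clip` for Swift-like data).
#' @param mapq_min MAPQ threshold (default 40).
#' @param exclude_duplicates Drop duplicate-flagged reads (default TRUE).
#' @return A [MethylSiteSet-class] of strand-resolved site records over all
#'   dinucleotide contexts; observations in state "other" (sequencing error)
#'   count toward neither M nor U.
#' @export
extractMethylation <- function(frags, genome, end_clip = 3L, r2_clip = 0L,
                               mapq_min = 40L, exclude_duplicates = TRUE) {
  rd <- .qualifyReads(frags, genome, mapq_min, exclude_duplicates)
  sites <- cytosineSites(genomeSequences(genome))
  ob <- .cytosineObservations(rd, sites)
  if (end_clip > 0L)
    ob <- ob[read_pos > end_clip & read_pos <= width - end_clip]
  if (r2_clip > 0L)
    ob <- ob[!(read == 2L & read_pos <= r2_clip)]
  ob <- ob[state != "O"]
  agg <- ob[, .(M = sum(state == "M"), U = sum(state == "U")), by = site]
  gr <- sites[agg$site]
  mcols(gr)$M <- agg$M
  mcols(gr)$U <- agg$U
  mcols(gr) <- mcols(gr)[, c("context", "M", "U")]
  MethylSiteSet(GenomicRanges::sort(gr, ignore.strand = TRUE))
}

#' Context-stratified cytosine retention
#'
#' Read-averaged retention is total M over total (M+U) pooled across all
#' observations; base-averaged retention is the unweighted mean of per-site
#' betas. Both in percent. The two differ whenever coverage and beta are
#' correlated; read-averaged retention is identically the coverage-weighted
#' mean of site betas.
#'
#' @param msset A [MethylSiteSet-class] (any mix of contexts).
#' @param contexts Contexts to report (default all present).
#' @return data.frame with `context`, `read_averaged`, `base_averaged`
#'   (percent), `n_observations`, `n_sites`.
#' @export
retentionSummary <- function(msset,
                             contexts = c("CpG", "CpA", "CpC", "CpT")) {
  gr <- siteRecords(msset)
  mc <- mcols(gr)
  contexts <- intersect(contexts, unique(mc$context))
  if (!length(contexts)) stop("no observations in requested contexts",
                              call. = FALSE)
  res <- lapply(contexts, function(cx) {
    i <- mc$context == cx
    M <- as.numeric(mc$M[i]); U <- as.numeric(mc$U[i])
    data.frame(context = cx,
               read_averaged = 100 * sum(M) / sum(M + U),
               base_averaged = 100 * mean(M / (M + U)),
               n_observations = sum(M + U),
               n_sites = sum(i))
  })
  do.call(rbind, res)
}

#' M-bias profile
#'
#' Retention per read position, separately per read in pair and per
#' dinucleotide context, with no end exclusion (M-bias is the diagnostic
#' used to choose end clipping, so clipping is not applied here).
#'
#' @inheritParams extractMethylation
#' @return data.frame with `read`, `context`, `position`, `retention`
#'   (percent) and `n` observations; positions with no observation are
#'   absent (undefined).
#' @export
mbiasProfile <- function(frags, genome, mapq_min = 40L,
                         exclude_duplicates = TRUE) {
  rd <- .qualifyReads(frags, genome, mapq_min, exclude_duplicates)
  sites <- cytosineSites(genomeSequences(genome))
  ob <- .cytosineObservations(rd, sites)
  ob <- ob[state != "O"]
  ob[, context := mcols(sites)$context[site]]
  agg <- ob[, .(retention = 100 * sum(state == "M") / .N, n = .N),
            by = .(read, context, read_pos)]
  setorder(agg, read, context, read_pos)
  setnames(agg, "read_pos", "position")
  as.data.frame(agg)
}

#' Conversion-control report
#'
#' Beta-distribution summaries on the conversion-control regions: the
#' unmethylated lambda-like spike-in, the methylated pUC19-like spike-in and
#' the unmethylated mitochondria-like contig. Control CpGs must reach the
#' control's minimum coverage: 3 reads for the mitochondrial contig, 1 for
#' the trace-level spike-ins. The mean beta of an unmethylated control
#' estimates incomplete conversion; one minus the mean beta of the
#' methylated control estimates over-conversion. A control with no
#' qualifying site is flagged empty, never an error.
#'
#' @param msset A [MethylSiteSet-class] of merged CpG records (see
#'   [mergeCpGStrands()]).
#' @param regionset A [RegionSet-class] carrying the control labels
#'   `spikein_unmethylated`, `spikein_methylated`, `mitochondrial`.
#' @param min_cov_mito Minimum coverage on the mitochondrial control
#'   (default 3).
#' @param min_cov_spikein Minimum coverage on the spike-ins (default 1).
#' @return data.frame with one row per control: `control`, `n_sites`,
#'   `mean_beta`, `median_beta`, `q25`, `q75`, `min_cov`, `empty`, and the
#'   derived `conversion_estimate` (incomplete conversion for unmethylated
#'   controls, over-conversion for the methylated control).
#' @export
controlReport <- function(msset, regionset, min_cov_mito = 3L,
                          min_cov_spikein = 1L) {
  specs <- data.frame(
    control = c("lambda_like", "puc19_like", "mito_like"),
    label = c("spikein_unmethylated", "spikein_methylated", "mitochondrial"),
    min_cov = c(min_cov_spikein, min_cov_spikein, min_cov_mito),
    methylated = c(FALSE, TRUE, FALSE))
  gr <- siteRecords(msset)
  res <- lapply(seq_len(nrow(specs)), function(i) {
    reg <- regions(regionset, specs$label[i])
    sub <- subsetByOverlaps(gr, reg, ignore.strand = TRUE)
    covv <- mcols(sub)$M + mcols(sub)$U
    sub <- sub[covv >= specs$min_cov[i]]
    b <- mcols(sub)$M / (mcols(sub)$M + mcols(sub)$U)
    empty <- length(b) == 0L
    mb <- if (empty) NA_real_ else mean(b)
    data.frame(control = specs$control[i], n_sites = length(b),
               mean_beta = mb,
               median_beta = if (empty) NA_real_ else median(b),
               q25 = if (empty) NA_real_ else unname(quantile(b, 0.25)),
               q75 = if (empty) NA_real_ else unname(quantile(b, 0.75)),
               min_cov = specs$min_cov[i], empty = empty,
               conversion_estimate = if (specs$methylated[i]) 1 - mb else mb)
  })
  do.call(rbind, res)
}
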