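## Depth-based metrics: fixed-depth subsampling, CpG coverage per region,
## mappability-weighted observed/expected coverage uniformity.

#' Subsampling fraction for fixed-depth comparison
#'
#' The fraction of well-mapped fragments to keep so every library is
#' compared at the same depth: `target / n_mapped_q40`, capped at 1 (a
#' library smaller than the target cannot be upsampled).
#'
#' @param n_mapped_q40 Number of mapped read fragments with MAPQ >= 40.
#' @param target Target fragment count (default 150e6, the depth equivalent
#'   to roughly 4.8X mean coverage of the human genome at 100 bp reads).
#' @return The sampling fraction in (0, 1].
#' @export
subsampleFraction <- function(n_mapped_q40, target = 150e6) {
  if (length(n_mapped_q40) != 1L || is.na(n_mapped_q40) || n_mapped_q40 <= 0)
    stop("n_mapped_q40 must be a positive count", call. = FALSE)
  frac <- target / n_mapped_q40
  if (frac > 1) {
    warning("library smaller than target; fraction capped at 1")
    frac <- 1
  }
  frac
}

#' Mean genome coverage at a fixed fragment count
#'
#' Closed-form mean depth `n_fragments * read_len / genome_length`, the
#' arithmetic behind expressing a fragment-count target as an X-fold
#' coverage (150 million 100-bp fragments over the ~3.1 Gbp human primary
#' assembly is about 4.8X).
#'
#' @param n_fragments Number of read fragments.
#' @param read_len Read length in bp.
#' @param genome_length Genome length in bp.
#' @return Mean coverage (numeric).
#' @export
approxGenomeCoverage <- function(n_fragments, read_len = 100,
                                 genome_length = 3.1e9) {
  n_fragments * read_len / genome_length
}

#' Subsample a FragmentSet to a fixed depth
#'
#' Filters to mapped reads with MAPQ >= `mapq_min`, then keeps each read
#' pair independently with probability `frac` (both mates share fate).
#' When `frac` is `NULL` it is computed from `target` via
#' [subsampleFraction()] on the qualifying read-fragment count.
#'
#' @param frags A [FragmentSet-class].
#' @param frac Sampling fraction; `NULL` to derive from `target`.
#' @param target Target read-fragment count (used when `frac` is `NULL`).
#' @param mapq_min MAPQ threshold (default 40).
#' @param seed Mandatory RNG seed.
#' @return The subsampled [FragmentSet-class] (unmapped and low-MAPQ reads
#'   are never retained).
#' @export
subsampleFragments <- function(frags, frac = NULL, target = 150e6,
                               mapq_min = 40L, seed) {
  seed <- .check_seed(seed)
  rd <- fragmentReads(frags)
  rd <- rd[mapped == TRUE & mapq >= mapq_min]
  if (is.null(frac)) frac <- subsampleFraction(nrow(rd), target)
  if (frac <= 0 || frac > 1) stop("frac must be in (0, 1]", call. = FALSE)
  set.seed(seed)
  ids <- unique(rd$pair_id)
  keep_ids <- ids[runif(length(ids)) < frac]
  FragmentSet(rd[pair_id %in% keep_ids], seqinfo(frags), runManifest(frags))
}

#' Percent of reference CpGs covered in a region
#'
#' Fraction of the reference CpG census falling in `region` that is covered
#' by at least `min_cov` site observations. The denominator is the census
#' (all reference CpGs in the region), not only observed sites.
#'
#' @param msset A [MethylSiteSet-class] of merged CpG records.
#' @param region `GRanges` of the region.
#' @param census `GRanges` of all reference CpG dinucleotides (e.g. the
#'   `cpg_sites` label of a [RegionSet-class]).
#' @param min_cov Minimum coverage to call a CpG covered (default 1).
#' @return Fraction in \[0, 1\]; `NA` with a warning when the region
#'   contains no census CpG.
#' @export
percentCpGsCovered <- function(msset, region, census, min_cov = 1L) {
  in_region <- subsetByOverlaps(census, region, ignore.strand = TRUE)
  if (!length(in_region)) {
    warning("region contains no reference CpGs; fraction undefined")
    return(NA_real_)
  }
  gr <- siteRecords(msset)
  gr <- gr[mcols(gr)$M + mcols(gr)$U >= min_cov]
  covered <- unique(S4Vectors::queryHits(
    findOverlaps(in_region, gr, ignore.strand = TRUE)))
  length(covered) / length(in_region)
}

## RleList of per-base read-fragment depth over the full genome
.fragCoverage <- function(rd, si) {
  gr <- GRanges(rd$chrom, IRanges(rd$pos + 1L, width = rd$width),
                seqinfo = si)
  coverage(gr)
}

## RleList indicator of intervals over the full genome
.maskRle <- function(gr, si) {
  coverage(GRanges(seqnames(gr), IRanges(start(gr), end(gr)), seqinfo = si)) > 0
}

#' Observed/expected coverage ratio of a region
#'
#' Coverage uniformity under non-uniform accessibility: `Obs` is the share
#' of mapped read bases falling in the region, `Exp` the region's share of
#' the genome-wide mappability mass (sum of score x width), both restricted
#' to bases carrying a mappability score. Only mapped reads with
#' MAPQ >= `mapq_min` contribute; duplicate-flagged reads are excluded by
#' default (coverage by unique reads). Aligned read bases are counted
#' individually, so overlapping mates double-count.
#'
#' @param frags A [FragmentSet-class].
#' @param region `GRanges` of the region.
#' @param maptrack A [MappabilityTrack-class].
#' @param mapq_min MAPQ threshold (default 40).
#' @param include_duplicates Count duplicate-flagged reads (default FALSE).
#' @return data.frame with `obs`, `exp`, `ratio` (all `NA` with a warning
#'   when the region has no mappability mass).
#' @export
observedExpectedRatio <- function(frags, region, maptrack, mapq_min = 40L,
                                  include_duplicates = FALSE) {
  rd <- fragmentReads(frags)
  rd <- rd[mapped == TRUE & mapq >= mapq_min]
  if (!include_duplicates) rd <- rd[dup == FALSE]
  si <- seqinfo(frags)
  exp_den <- .mapMass(maptrack)
  exp_num <- .mapMass(maptrack, region)
  if (exp_num <= 0) {
    warning("region has no mappability mass; ratio undefined")
    return(data.frame(obs = NA_real_, exp = NA_real_, ratio = NA_real_))
  }
  cov <- .fragCoverage(rd, si)
  scored <- .maskRle(mappability(maptrack), si)
  in_region <- .maskRle(region, si)
  obs_den <- sum(as.numeric(sum(cov * scored)))
  obs_num <- sum(as.numeric(sum(cov * scored * in_region)))
  if (obs_den == 0) {
    warning("no mapped bases on scored positions; ratio undefined")
    return(data.frame(obs = NA_real_, exp = NA_real_, ratio = NA_real_))
  }
  obs <- obs_num / obs_den
  expv <- exp_num / exp_den
  data.frame(obs = obs, exp = expv, ratio = obs / expv)
}

#' Observed/expected ratios for every label of a RegionSet
#'
#' @param frags A [FragmentSet-class].
#' @param regionset A [RegionSet-class].
#' @param maptrack A [MappabilityTrack-class].
#' @param labels Labels to evaluate (default all).
#' @param ... Passed to [observedExpectedRatio()].
#' @return data.frame with one row per label.
#' @export
coverageUniformity <- function(frags, regionset, maptrack,
                               labels = regionLabels(regionset), ...) {
  res <- lapply(labels, function(lb) {
    out <- observedExpectedRatio(frags, regions(regionset, lb), maptrack, ...)
    cbind(data.frame(region_label = lb), out)
  })
  do.call(rbind, res)
}

#' Weighted average CpG coverage in a region
#'
#' Mean of per-CpG coverage over all reference CpGs in the region; census
#' CpGs without an observation count as coverage 0.
#'
#' @inheritParams percentCpGsCovered
#' @return Mean coverage; `NA` with a warning when the region has no CpG.
#' @export
weightedAverageCoverage <- function(msset, region, census) {
  in_region <- subsetByOverlaps(census, region, ignore.strand = TRUE)
  if (!length(in_region)) {
    warning("region contains no reference CpGs; mean coverage undefined")
    return(NA_real_)
  }
  gr <- siteRecords(msset)
  covv <- numeric(length(in_region))
  hits <- findOverlaps(in_region, gr, ignore.strand = TRUE)
  if (length(hits)) {
    dt <- data.table(q = S4Vectors::queryHits(hits),
                     v = (mcols(gr)$M + mcols(gr)$U)[S4Vectors::subjectHits(hits)])
    agg <- dt[, .(v = sum(v)), by = q]
    covv[agg$q] <- agg$v
  }
  mean(covv)
}
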