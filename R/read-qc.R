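## Raw-read and alignment-level quality metrics.

## pair-level view of mapped reads: one row per pair with the duplicate
## identity key (chrom, leftmost pos, parent strand, insert size)
.pairTable <- function(rd) {
  mp <- rd[mapped == TRUE]
  if (!nrow(mp))
    return(data.table(pair_id = integer(0), key_ = character(0),
                      dup = logical(0), minmapq = integer(0)))
  mp[, .(key_ = paste(chrom[1L], min(pos),
                      fifelse(bs_strand[1L] %in% c("OT", "CTOT"), "+", "-"),
                      isize[1L], sep = ":"),
         dup = dup[1L], minmapq = min(mapq)),
     by = pair_id]
}

#' Base-quality fractions per read in pair
#'
#' Fractions of sequenced bases in three Phred bins, computed separately for
#' reads 1 and 2 over all read fragments (raw-read metric; no mapping or
#' duplicate filter): low is q < 20, medium is 20 <= q <= 30, high is q > 30.
#'
#' @param frags A [FragmentSet-class].
#' @return data.frame with columns `read`, `frac_low`, `frac_mid`,
#'   `frac_high`, `n_bases`; fractions sum to 1 per read.
#' @export
baseQualityFractions <- function(frags) {
  rd <- fragmentReads(frags)
  if (!nrow(rd)) stop("no read fragments", call. = FALSE)
  res <- lapply(sort(unique(rd$read)), function(r) {
    q <- phredToInt(rd$qual[rd$read == r])
    n <- length(q)
    data.frame(read = r,
               frac_low = sum(q < 20L) / n,
               frac_mid = sum(q >= 20L & q <= 30L) / n,
               frac_high = sum(q > 30L) / n,
               n_bases = n)
  })
  do.call(rbind, res)
}

#' Alignment-quality fractions
#'
#' Fractions of read fragments (reads 1 and 2 counted separately) that are
#' optimally aligned (MAPQ >= 40), sub-optimally aligned (mapped, MAPQ < 40)
#' and not aligned.
#'
#' @param frags A [FragmentSet-class].
#' @param mapq_min Optimal/sub-optimal MAPQ boundary (default 40).
#' @return data.frame with `frac_optimal`, `frac_suboptimal`,
#'   `frac_unaligned`, `n_fragments`.
#' @export
alignmentFractions <- function(frags, mapq_min = 40L) {
  rd <- fragmentReads(frags)
  n <- nrow(rd)
  if (!n) stop("no read fragments", call. = FALSE)
  opt <- sum(rd$mapped & rd$mapq >= mapq_min, na.rm = TRUE)
  sub <- sum(rd$mapped & rd$mapq < mapq_min, na.rm = TRUE)
  data.frame(frac_optimal = opt / n, frac_suboptimal = sub / n,
             frac_unaligned = sum(!rd$mapped) / n, n_fragments = n)
}

#' Duplicate rate among well-mapped pairs
#'
#' Fraction of read pairs flagged as duplicates among mapped pairs whose
#' mates all have MAPQ >= `mapq_min`.
#'
#' @param frags A [FragmentSet-class] with duplicate flags set (by the
#'   simulator or by [markDuplicates()]).
#' @param mapq_min MAPQ threshold (default 40).
#' @return The duplicate rate in \[0, 1\], or `NA` with a warning when no
#'   pair qualifies.
#' @export
duplicateRate <- function(frags, mapq_min = 40L) {
  pt <- .pairTable(fragmentReads(frags))
  pt <- pt[minmapq >= mapq_min]
  if (!nrow(pt)) {
    warning("no mapped pairs with MAPQ >= ", mapq_min,
            "; duplicate rate undefined")
    return(NA_real_)
  }
  mean(pt$dup)
}

#' Mark duplicate read pairs
#'
#' Re-derives duplicate flags from the fragment identity key
#' (chrom, leftmost position, parent strand, insert size): the first
#' occurrence of each key is kept unflagged, later occurrences are flagged
#' on both mates. Pairs with no mapped read are never flagged.
#'
#' @param frags A [FragmentSet-class].
#' @return A [FragmentSet-class] with `dup` recomputed.
#' @export
markDuplicates <- function(frags) {
  rd <- fragmentReads(frags)
  pt <- .pairTable(rd)
  if (nrow(pt)) {
    pt[, dupnew := duplicated(key_)]
    rd[pt, dup := i.dupnew, on = "pair_id"]
    rd[!pair_id %in% pt$pair_id, dup := FALSE]
  } else rd[, dup := FALSE]
  FragmentSet(rd, seqinfo(frags), runManifest(frags))
}

#' Library complexity curve
#'
#' Distinct fragment count as a function of sequencing depth: mapped read
#' pairs are permuted once, and at each of `n_points` subsample sizes the
#' number of distinct fragment identity keys within the prefix of that size
#' is counted (a draw without replacement at every size, monotone by
#' construction). The final point uses all mapped pairs.
#'
#' @param frags A [FragmentSet-class].
#' @param n_points Number of curve points (>= 2).
#' @param seed RNG seed for the permutation.
#' @return data.frame with non-decreasing columns `total_fragments`,
#'   `distinct_fragments`.
#' @export
complexityCurve <- function(frags, n_points = 10L, seed) {
  seed <- .check_seed(seed)
  if (n_points < 2L) stop("n_points must be >= 2", call. = FALSE)
  pt <- .pairTable(fragmentReads(frags))
  n <- nrow(pt)
  set.seed(seed)
  perm <- sample.int(n)
  totals <- unique(pmax(1L, round(seq_len(n_points) / n_points * n)))
  firsts <- cumsum(!duplicated(pt$key_[perm]))
  data.frame(total_fragments = totals, distinct_fragments = firsts[totals])
}

#' Insert-size summary
#'
#' Mean, median and histogram of template lengths, counted once per pair
#' (mapped pairs only).
#'
#' @param frags A [FragmentSet-class].
#' @param bin_width Histogram bin width in bp (default 5).
#' @return list with `mean`, `median`, `n_pairs` and a `histogram`
#'   data.frame (`bin_start`, `count`).
#' @export
insertSizeSummary <- function(frags, bin_width = 5L) {
  rd <- fragmentReads(frags)
  iz <- rd[mapped == TRUE, isize[1L], by = pair_id]$V1
  if (!length(iz)) stop("no mapped pairs", call. = FALSE)
  bins <- floor(iz / bin_width) * bin_width
  tab <- as.data.frame(table(bins), stringsAsFactors = FALSE)
  list(mean = mean(iz), median = median(iz), n_pairs = length(iz),
       histogram = data.frame(bin_start = as.integer(tab$bins),
                              count = tab$Freq))
}
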