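## Cross-sample statistics: 100-kb binned betas, Spearman concordance,
## smoothed-M-value PCA, and the two-replicate cross-protocol bias test.

#' Bin CpG betas into fixed-width windows
#'
#' Tiles each contig into windows of `width` bp (the last bin per contig may
#' be shorter) and computes the unweighted mean of the site betas in each
#' bin, together with the CpG count and the per-bin M and U totals (the
#' totals feed the smoothed M-value transform for PCA).
#'
#' @param msset A [MethylSiteSet-class] of merged CpG records.
#' @param si A `Seqinfo` (or named vector of contig lengths) defining the
#'   tiling.
#' @param width Bin width in bp (default 100000).
#' @return A `GRanges` of bins with metadata `n_cpgs`, `mean_beta` (`NA`
#'   where no covered CpG), `M`, `U`.
#' @export
binBetas <- function(msset, si, width = 100000L) {
  if (width <= 0) stop("width must be positive", call. = FALSE)
  if (!is(si, "Seqinfo")) si <- Seqinfo(names(si), unname(si))
  bins <- tileGenome(si, tilewidth = width, cut.last.tile.in.chrom = TRUE)
  gr <- siteRecords(msset)
  hits <- findOverlaps(GRanges(seqnames(gr), IRanges(start(gr), width = 1L)),
                       bins, ignore.strand = TRUE)
  b <- mcols(gr)$M / (mcols(gr)$M + mcols(gr)$U)
  dt <- data.table(bin = S4Vectors::subjectHits(hits),
                   beta = b[S4Vectors::queryHits(hits)],
                   M = mcols(gr)$M[S4Vectors::queryHits(hits)],
                   U = mcols(gr)$U[S4Vectors::queryHits(hits)])
  agg <- dt[, .(n_cpgs = .N, mean_beta = mean(beta), M = sum(M), U = sum(U)),
            by = bin]
  mcols(bins)$n_cpgs <- 0L
  mcols(bins)$mean_beta <- NA_real_
  mcols(bins)$M <- 0L
  mcols(bins)$U <- 0L
  mcols(bins)$n_cpgs[agg$bin] <- agg$n_cpgs
  mcols(bins)$mean_beta[agg$bin] <- agg$mean_beta
  mcols(bins)$M[agg$bin] <- agg$M
  mcols(bins)$U[agg$bin] <- agg$U
  bins
}

#' Spearman concordance of binned betas
#'
#' Rank correlation (average ranks on ties) between the per-bin mean betas
#' of two samples, over the bins where both are defined; the common-bin
#' count is reported alongside, as correlations are depth-dependent.
#'
#' @param bins_a,bins_b Binned `GRanges` from [binBetas()] over the same
#'   tiling.
#' @return list with `r_s` and `n_bins`; `r_s` is `NA` with a warning when
#'   fewer than 3 common bins exist.
#' @export
spearmanConcordance <- function(bins_a, bins_b) {
  stopifnot(length(bins_a) == length(bins_b))
  a <- mcols(bins_a)$mean_beta
  b <- mcols(bins_b)$mean_beta
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 3L) {
    warning("fewer than 3 common bins; correlation undefined")
    return(list(r_s = NA_real_, n_bins = sum(ok)))
  }
  list(r_s = cor(a[ok], b[ok], method = "spearman"), n_bins = sum(ok))
}

#' Smoothed M-value transform
#'
#' `logit((M + k) / ((M + k) + (U + k)))`: the smoothing factor `k`
#' eliminates the infinities of the logit at beta 0 and 1, so the value is
#' finite for all non-negative counts, including M = U = 0 (which maps
#' to 0).
#'
#' @param M,U Non-negative methylated / unmethylated counts (vectorized).
#' @param k Smoothing factor, > 0 (default 0.5, half-count smoothing).
#' @return M-values (numeric).
#' @examples
#' mTransform(3, 1, k = 1) # logit(4/6) = log(2)
#' @export
mTransform <- function(M, U, k = 0.5) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (any(M < 0) || any(U < 0)) stop("counts must be non-negative",
                                     call. = FALSE)
  qlogis((M + k) / ((M + k) + (U + k)))
}

#' PCA of binned methylation across samples
#'
#' Per-bin M and U totals are transformed to smoothed M-values
#' ([mTransform()]), bins undefined in any sample are dropped listwise,
#' each retained bin is standardized to zero mean and unit variance across
#' samples, and the first two principal components are returned with their
#' explained-variance fractions.
#'
#' @param bin_list Named list (>= 3 samples) of binned `GRanges` from
#'   [binBetas()] over one common tiling.
#' @param k Smoothing factor for [mTransform()].
#' @return list with `coordinates` (samples x 2 matrix, columns PC1/PC2),
#'   `explained_variance` (length-2 fractions of total variance,
#'   non-increasing) and `n_bins` used.
#' @export
pcaProtocols <- function(bin_list, k = 0.5) {
  if (length(bin_list) < 3L)
    stop("PCA needs at least 3 samples", call. = FALSE)
  if (is.null(names(bin_list)))
    names(bin_list) <- paste0("sample", seq_along(bin_list))
  nb <- vapply(bin_list, length, integer(1))
  if (length(unique(nb)) != 1L)
    stop("all samples must share one bin tiling", call. = FALSE)
  defined <- Reduce(`&`, lapply(bin_list, function(x) mcols(x)$n_cpgs > 0L))
  if (sum(defined) < 2L)
    stop("fewer than 2 bins defined in every sample", call. = FALSE)
  mv <- vapply(bin_list, function(x)
    mTransform(mcols(x)$M[defined], mcols(x)$U[defined], k),
    numeric(sum(defined)))
  mat <- t(mv)                               # samples x bins
  sds <- apply(mat, 2L, sd)
  keep <- sds > 0
  mat <- scale(mat[, keep, drop = FALSE])
  pc <- prcomp(mat, center = FALSE, scale. = FALSE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- min(2L, ncol(pc$x))
  list(coordinates = pc$x[, seq_len(ncomp), drop = FALSE],
       explained_variance = var_frac[seq_len(ncomp)],
       n_bins = sum(defined))
}

#' Cross-protocol methylation bias test
#'
#' Flags CpGs whose beta values differ by more than `threshold` between two
#' protocols in replicate pair 1 AND in replicate pair 2, restricted to
#' CpGs with more than `min_cov` reads in all four inputs (strict
#' inequalities on both criteria).
#'
#' @param protoX_rep1,protoX_rep2 Merged CpG [MethylSiteSet-class]s for
#'   protocol X, technical replicates 1 and 2.
#' @param protoY_rep1,protoY_rep2 Same for protocol Y.
#' @param min_cov Reads required (exclusive bound, default 20: "> 20").
#' @param threshold Absolute beta difference bound (exclusive, default 0.5).
#' @return A `GRanges` of flagged CpGs with the four beta values; empty when
#'   no site satisfies both replicate criteria.
#' @export
biasCpGs <- function(protoX_rep1, protoX_rep2, protoY_rep1, protoY_rep2,
                     min_cov = 20L, threshold = 0.5) {
  tab <- function(ms) {
    gr <- siteRecords(ms)
    data.table(chrom = as.character(seqnames(gr)), pos = start(gr),
               cov = mcols(gr)$M + mcols(gr)$U,
               beta = mcols(gr)$M / (mcols(gr)$M + mcols(gr)$U))
  }
  x1 <- tab(protoX_rep1); x2 <- tab(protoX_rep2)
  y1 <- tab(protoY_rep1); y2 <- tab(protoY_rep2)
  setnames(x1, c("cov", "beta"), c("cov_x1", "beta_x1"))
  setnames(x2, c("cov", "beta"), c("cov_x2", "beta_x2"))
  setnames(y1, c("cov", "beta"), c("cov_y1", "beta_y1"))
  setnames(y2, c("cov", "beta"), c("cov_y2", "beta_y2"))
  m <- Reduce(function(a, b) merge(a, b, by = c("chrom", "pos")),
              list(x1, x2, y1, y2))
  m <- m[cov_x1 > min_cov & cov_x2 > min_cov &
         cov_y1 > min_cov & cov_y2 > min_cov &
         abs(beta_x1 - beta_y1) > threshold &
         abs(beta_x2 - beta_y2) > threshold]
  GRanges(m$chrom, IRanges(m$pos, width = 2L),
          beta_x1 = m$beta_x1, beta_x2 = m$beta_x2,
          beta_y1 = m$beta_y1, beta_y2 = m$beta_y2)
}
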