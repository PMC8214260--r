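test_that("bin means equal a base-R group-by oracle", {
  bins <- binBetas(fix_merged, seqinfo(fix_genome), width = 20000)
  want <- oracleBinMeans(fix_merged, 20000)
  got_key <- paste(seqnames(bins), (start(bins) - 1) %/% 20000)
  m <- match(want$bin, got_key)
  expect_false(anyNA(m))
  expect_equal(mcols(bins)$mean_beta[m], want$mean_beta)
  expect_equal(mcols(bins)$n_cpgs[m], want$n_cpgs)
  ## empty bins are undefined; CpG counts are conserved over the tiling
  expect_true(all(is.na(mcols(bins)$mean_beta[mcols(bins)$n_cpgs == 0])))
  expect_equal(sum(mcols(bins)$n_cpgs), length(fix_merged))
  ## bins tile each contig without gaps or overlaps
  expect_true(all(width(bins) <= 20000))
  expect_equal(sum(width(bins)),
               sum(GenomeInfoDb::seqlengths(seqinfo(fix_genome))))
  expect_error(binBetas(fix_merged, seqinfo(fix_genome), width = 0),
               "positive")
})

test_that("Spearman concordance hits the rank-correlation edge cases", {
  bins <- binBetas(fix_merged, seqinfo(fix_genome), width = 20000)
  expect_equal(spearmanConcordance(bins, bins)$r_s, 1.0)
  rev_bins <- bins
  ok <- !is.na(mcols(bins)$mean_beta)
  mcols(rev_bins)$mean_beta[ok] <-
    1 - rank(mcols(bins)$mean_beta[ok]) / (sum(ok) + 1)
  expect_equal(spearmanConcordance(bins, rev_bins)$r_s, -1.0)
  ## invariant under strictly monotone transforms
  tx <- bins
  mcols(tx)$mean_beta <- qlogis(pmin(pmax(mcols(tx)$mean_beta, 1e-6),
                                     1 - 1e-6))
  b2 <- binBetas(fix_merged, seqinfo(fix_genome), width = 20000)
  mcols(b2)$mean_beta <- mcols(b2)$mean_beta + runif(length(b2))
  expect_equal(spearmanConcordance(bins, b2)$r_s,
               spearmanConcordance(tx, b2)$r_s)
  ## too few common bins is undefined
  empty <- bins; mcols(empty)$mean_beta <- NA_real_
  expect_warning(out <- spearmanConcordance(bins, empty), "fewer than 3")
  expect_true(is.na(out$r_s))
})

test_that("replicate concordance rises with sequencing depth", {
  g <- generateGenome(contig_length = 5e5, n_islands = 8, seed = 151)
  tr <- assignTruth(g, seed = 152)
  p <- protocolProfile(duplication_rate = 0)
  rs_at <- function(n, s1, s2) {
    b <- lapply(c(s1, s2), function(s) {
      fr <- simulateFragments(g, tr, p, n_pairs = n, seed = s)
      binBetas(mergeCpGStrands(extractMethylation(fr, g)), seqinfo(g),
               width = 50000)
    })
    spearmanConcordance(b[[1]], b[[2]])$r_s
  }
  rs <- vapply(c(2000, 8000, 32000), function(n)
    rs_at(n, 160 + n %% 97, 260 + n %% 89), numeric(1))
  expect_true(all(diff(rs) > 0))
})

test_that("the smoothed M-value transform matches hand computations", {
  expect_equal(mTransform(3, 1, k = 1), log(2))
  expect_equal(mTransform(5, 5, k = 0.5), 0)
  expect_equal(mTransform(0, 0, k = 0.5), 0)      # (k)/(2k) = 0.5
  expect_true(is.finite(mTransform(100, 0)))
  expect_true(is.finite(mTransform(0, 100)))
  ## strictly increasing in M, antisymmetric in (M, U)
  ms <- mTransform(0:20, 5)
  expect_true(all(diff(ms) > 0))
  expect_equal(mTransform(7, 2), -mTransform(2, 7))
  expect_error(mTransform(1, 1, k = 0), "positive")
  expect_error(mTransform(-1, 1), "non-negative")
})

test_that("PCA standardizes bins and reproduces duplicated samples", {
  g <- generateGenome(contig_length = 3e5, n_islands = 5, seed = 171)
  tr <- assignTruth(g, seed = 172)
  p <- protocolProfile(duplication_rate = 0)
  mk <- function(s) {
    fr <- simulateFragments(g, tr, p, n_pairs = 5000, seed = s)
    binBetas(mergeCpGStrands(extractMethylation(fr, g)), seqinfo(g),
             width = 50000)
  }
  b <- list(a = mk(181), b = mk(182), c = mk(183))
  b$dup_a <- b$a
  res <- pcaProtocols(b)
  expect_equal(res$coordinates["a", ], res$coordinates["dup_a", ])
  expect_true(all(diff(res$explained_variance) <= 0))
  expect_lte(sum(res$explained_variance), 1 + 1e-12)
  expect_error(pcaProtocols(b[1:2]), "at least 3")
})

test_that("the bias test requires both replicate pairs to exceed threshold", {
  mk <- function(betas, covs = rep(30L, length(betas))) {
    M <- as.integer(round(betas * covs))
    MethylSiteSet(GRanges("chr1",
                          IRanges(seq(10, by = 100,
                                      length.out = length(betas)), width = 2),
                          context = "CpG", M = M, U = as.integer(covs) - M))
  }
  ## site 1: concordant; site 2: |d| > 0.5 in rep1 only; site 3: both reps
  x1 <- mk(c(0.5, 0.9, 1.0)); x2 <- mk(c(0.5, 0.5, 1.0))
  y1 <- mk(c(0.5, 0.2, 0.1)); y2 <- mk(c(0.5, 0.4, 0.2))
  out <- biasCpGs(x1, x2, y1, y2)
  expect_length(out, 1L)
  expect_equal(start(out), 210L)
  ## identical betas everywhere: empty
  expect_length(biasCpGs(x1, x1, x1, x1), 0L)
  ## coverage gate: a low-coverage site never flags
  x1b <- mk(c(0.5, 0.9, 1.0), covs = c(30L, 30L, 20L))   # 20 is not > 20
  expect_length(biasCpGs(x1b, x2, y1, y2), 0L)
  ## monotone non-increasing in threshold and min_cov
  n_lo <- length(biasCpGs(x1, x2, y1, y2, threshold = 0.3))
  n_hi <- length(biasCpGs(x1, x2, y1, y2, threshold = 0.7))
  expect_gte(n_lo, n_hi)
  n_cov <- length(biasCpGs(x1, x2, y1, y2, min_cov = 40))
  expect_lte(n_cov, length(out))
})

test_that("same-truth protocols flag nothing; planted discordance recovers", {
  g <- generateGenome(contig_length = 2e5, n_islands = 4, seed = 191)
  tr <- assignTruth(g, seed = 192)
  p <- protocolProfile(duplication_rate = 0)
  sim <- function(truth, s) {
    fr <- simulateFragments(g, truth, p, n_pairs = 45000, seed = s)
    mergeCpGStrands(extractMethylation(fr, g))
  }
  x1 <- sim(tr, 201); x2 <- sim(tr, 202)
  y1 <- sim(tr, 203); y2 <- sim(tr, 204)
  expect_lte(length(biasCpGs(x1, x2, y1, y2)), 2L)
  ## plant 10 discordant CpGs: truth 1 in protocol X, 0 in protocol Y
  st <- truthSites(tr)
  cpg_plus <- which(as.character(seqnames(st)) == "chr1" &
                    mcols(st)$context == "CpG" &
                    as.character(strand(st)) == "+")
  set.seed(9)
  chosen <- sort(sample(cpg_plus, 10))
  pair_pos <- start(st)[chosen] + 1L   # the matching minus-strand C
  idx <- c(chosen, which(as.character(seqnames(st)) == "chr1" &
                         start(st) %in% pair_pos &
                         as.character(strand(st)) == "-" &
                         mcols(st)$context == "CpG"))
  trX <- tr; mcols(trX@sites)$level[idx] <- 1
  trY <- tr; mcols(trY@sites)$level[idx] <- 0
  fx1 <- sim(trX, 205); fx2 <- sim(trX, 206)
  fy1 <- sim(trY, 207); fy2 <- sim(trY, 208)
  flagged <- biasCpGs(fx1, fx2, fy1, fy2)
  planted <- GRanges("chr1", IRanges(start(st)[chosen], width = 2))
  hit <- countOverlaps(planted, flagged) > 0
  expect_gte(sum(hit), 9)
})
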