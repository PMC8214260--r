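test_that("subsampling fraction follows the fixed-depth arithmetic", {
  expect_equal(subsampleFraction(300e6, 150e6), 0.5)
  expect_equal(subsampleFraction(150e6, 150e6), 1.0)
  expect_warning(fr <- subsampleFraction(120e6, 150e6), "capped")
  expect_equal(fr, 1.0)
  expect_error(subsampleFraction(0), "positive")
  expect_error(subsampleFraction(-5), "positive")
})

test_that("pair subsampling keeps mates together and filters first", {
  sub <- subsampleFragments(fix_frags, frac = 0.5, seed = 3)
  rd <- fragmentReads(sub)
  expect_true(all(rd$mapped))
  expect_true(all(rd$mapq >= 40))
  ## binomial bound on retained pairs
  rd0 <- fragmentReads(fix_frags)
  rd0 <- rd0[rd0$mapped & rd0$mapq >= 40, ]
  n_elig <- length(unique(rd0$pair_id))
  n_kept <- length(unique(rd$pair_id))
  expect_lt(abs(n_kept - 0.5 * n_elig), 3.29 * sqrt(0.25 * n_elig))
  ## FRAC 1 is the identity on the qualifying set
  sub1 <- subsampleFragments(fix_frags, frac = 1, seed = 3)
  expect_equal(nrow(fragmentReads(sub1)), nrow(rd0))
  ## unmapped reads are never retained
  expect_equal(sum(!fragmentReads(sub)$mapped), 0L)
})

test_that("fixed-count coverage arithmetic matches the closed form", {
  expect_equal(approxGenomeCoverage(150e6, 100, 3.1e9), 150e6 * 100 / 3.1e9)
  expect_equal(round(approxGenomeCoverage(150e6, 100, 3.1e9), 1), 4.8)
})

test_that("percent CpGs covered counts census CpGs, not observed sites", {
  ## constructed: 10 census CpGs, 8 covered
  census <- GRanges("chr1", IRanges(seq(10, 100, by = 10), width = 2))
  covered <- GRanges("chr1", IRanges(seq(10, 80, by = 10), width = 2),
                     context = "CpG", M = 1L, U = 0L)
  ms <- MethylSiteSet(covered)
  region <- GRanges("chr1", IRanges(1, 200))
  expect_equal(percentCpGsCovered(ms, region, census), 0.8)
  ## min_cov raises the bar
  mcols(covered)$U <- c(rep(0L, 4), rep(3L, 4))
  ms2 <- MethylSiteSet(covered)
  expect_equal(percentCpGsCovered(ms2, region, census, min_cov = 2), 0.4)
  ## empty region is undefined, signalled
  empty <- GRanges("chr1", IRanges(5000, 5001))
  expect_warning(v <- percentCpGsCovered(ms, empty, census), "no reference")
  expect_true(is.na(v))
})

test_that("percent covered and weighted coverage match brute-force counting", {
  isl <- regions(genomeRegions(fix_genome), "cpg_islands")
  for (region in list(fix_main, isl)) {
    expect_equal(percentCpGsCovered(fix_merged, region, fix_census),
                 oraclePctCovered(fix_merged, region, fix_census))
  }
  ## monotone non-increasing in min_cov
  v <- vapply(1:5, function(mc)
    percentCpGsCovered(fix_merged, fix_main, fix_census, min_cov = mc),
    numeric(1))
  expect_true(all(diff(v) <= 0))
  ## weighted average coverage equals the direct tally (uncovered count 0)
  st <- as.data.frame(siteRecords(fix_merged))
  cen <- as.data.frame(fix_census)
  cen <- cen[cen$seqnames == "chr1", ]
  covv <- integer(nrow(cen))
  m <- match(paste(st$seqnames, st$start), paste(cen$seqnames, cen$start))
  covv[m[!is.na(m)]] <- (st$M + st$U)[!is.na(m)]
  expect_equal(weightedAverageCoverage(fix_merged, fix_main, fix_census),
               mean(covv))
})

test_that("observed/expected ratio matches a per-base brute-force counter", {
  isl <- regions(genomeRegions(fix_genome), "cpg_islands")
  mt <- genomeMappability(fix_genome)
  got <- observedExpectedRatio(fix_frags, isl, mt)
  want <- oracleObsExp(fix_frags, isl, mt)
  expect_equal(got$obs, unname(want["obs"]))
  expect_equal(got$exp, unname(want["exp"]))
  expect_equal(got$ratio, unname(want["ratio"]))
  ## a region with no reads has ratio 0
  rd <- fragmentReads(fix_frags)
  ms <- makeFrags(pair_id = 1:3, pos = c(0L, 100L, 200L), width = 50L,
                  seqlen = 150000L)
  far <- GRanges("chr1", IRanges(100000, 110000))
  mt1 <- MappabilityTrack({
    g <- GRanges("chr1", IRanges(1, 150000)); mcols(g)$score <- 1; g
  })
  expect_equal(observedExpectedRatio(ms, far, mt1)$ratio, 0)
})

test_that("obs and exp each sum to one over a genome partition", {
  ## partition chr1 + control contigs into disjoint blocks
  si <- seqinfo(fix_genome)
  blocks <- tileGenome(si, tilewidth = 37000, cut.last.tile.in.chrom = TRUE)
  mt <- genomeMappability(fix_genome)
  res <- do.call(rbind, lapply(seq_along(blocks), function(i)
    suppressWarnings(observedExpectedRatio(fix_frags, blocks[i], mt))))
  res <- res[!is.na(res$obs), ]
  expect_equal(sum(res$obs), 1, tolerance = 1e-9)
  expect_equal(sum(res$exp), 1, tolerance = 1e-9)
  ## hence the Exp-weighted mean ratio is 1
  expect_equal(sum(res$exp * res$ratio), 1, tolerance = 1e-9)
})

test_that("with uniform mappability Exp reduces to the length share", {
  mt <- genomeMappability(fix_genome)   # score 1 everywhere by default
  reg <- GRanges("chr1", IRanges(1, 30000))
  got <- observedExpectedRatio(fix_frags, reg, mt)
  glen <- sum(GenomeInfoDb::seqlengths(seqinfo(fix_genome)))
  expect_equal(got$exp, 30000 / glen, tolerance = 1e-12)
})

test_that("island sampling bias moves the observed/expected ratio", {
  g <- generateGenome(contig_length = 4e5, n_islands = 10, seed = 81)
  tr <- assignTruth(g, seed = 82)
  isl <- regions(genomeRegions(g), "cpg_islands")
  mt <- genomeMappability(g)
  ## unbiased: island ratio within 5% of 1
  f1 <- simulateFragments(g, tr, protocolProfile(cgi_bias = 1),
                          n_pairs = 30000, seed = 83)
  r1 <- observedExpectedRatio(f1, isl, mt)$ratio
  expect_lt(abs(r1 - 1), 0.05)
  ## PBAT-like over-coverage: ratio clearly above 1.3
  f2 <- simulateFragments(g, tr, protocolProfile(cgi_bias = 2),
                          n_pairs = 30000, seed = 84)
  r2 <- observedExpectedRatio(f2, isl, mt)$ratio
  expect_gt(r2, 1.3)
  ## and the non-island remainder is under-covered
  rest <- GenomicRanges::setdiff(GRanges("chr1", IRanges(1, 4e5)), isl)
  expect_lt(observedExpectedRatio(f2, rest, mt)$ratio, 1)
})
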