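test_that("retention summaries separate read- and base-averaged views", {
  gr <- GRanges("chr1", IRanges(c(10, 50), width = 1), strand = "+",
                context = "CpG", M = c(3L, 1L), U = c(1L, 3L))
  rs <- retentionSummary(MethylSiteSet(gr))
  expect_equal(rs$read_averaged, 50)
  expect_equal(rs$base_averaged, 50)
  ## coverage-beta correlation splits the two
  mcols(gr)$M <- c(9L, 0L); mcols(gr)$U <- c(1L, 90L)
  rs2 <- retentionSummary(MethylSiteSet(gr))
  expect_equal(rs2$read_averaged, 9)
  expect_equal(rs2$base_averaged, 45)
  expect_error(retentionSummary(MethylSiteSet(gr), contexts = "CpC"),
               "no observations")
})

test_that("read-averaged retention is the coverage-weighted mean of betas", {
  rs <- retentionSummary(fix_sites)
  gr <- siteRecords(fix_sites)
  for (cx in rs$context) {
    sub <- gr[mcols(gr)$context == cx]
    covv <- mcols(sub)$M + mcols(sub)$U
    b <- mcols(sub)$M / covv
    expect_equal(rs$read_averaged[rs$context == cx],
                 100 * weighted.mean(b, covv))
  }
})

test_that("extraction conserves observations against a brute-force tally", {
  ## with no clipping, every qualifying on-strand cytosine observation that
  ## reads C or T lands in exactly one site record
  fr <- simulateFragments(fix_genome, fix_truth,
                          protocolProfile(error_rate = 0),
                          n_pairs = 1500, seed = 91)
  ms <- extractMethylation(fr, fix_genome, end_clip = 0)
  total <- sum(mcols(siteRecords(ms))$M + mcols(siteRecords(ms))$U)
  ## brute force: walk each read and count reference C/G on the parent strand
  rd <- as.data.frame(fragmentReads(fr))
  rd <- rd[rd$mapped & rd$mapq >= 40 & !rd$dup, ]
  seqs <- lapply(as.character(genomeSequences(fix_genome)),
                 function(s) strsplit(s, "")[[1]])
  names(seqs) <- names(genomeSequences(fix_genome))
  cnt <- 0L
  for (i in seq_len(nrow(rd))) {
    refc <- seqs[[rd$chrom[i]]][(rd$pos[i] + 1):(rd$pos[i] + rd$width[i])]
    want <- if (rd$bs_strand[i] %in% c("OT", "CTOT")) "C" else "G"
    hits <- which(refc == want)
    ## census excludes cytosines with off-contig or ambiguous neighbours
    abs_pos <- rd$pos[i] + hits
    L <- length(seqs[[rd$chrom[i]]])
    if (want == "C") hits <- hits[abs_pos < L] else hits <- hits[abs_pos > 1]
    cnt <- cnt + length(hits)
  }
  expect_equal(total, cnt)
})

test_that("end clipping removes read-end observations only", {
  fr <- simulateFragments(fix_genome, fix_truth, fix_profile,
                          n_pairs = 1500, seed = 92)
  ms0 <- extractMethylation(fr, fix_genome, end_clip = 0)
  ms3 <- extractMethylation(fr, fix_genome, end_clip = 3)
  n0 <- sum(mcols(siteRecords(ms0))$M + mcols(siteRecords(ms0))$U)
  n3 <- sum(mcols(siteRecords(ms3))$M + mcols(siteRecords(ms3))$U)
  expect_lt(n3, n0)
  ## clipped totals match the M-bias profile restricted to interior positions
  mb <- mbiasProfile(fr, fix_genome)
  rd <- fragmentReads(fr)
  interior <- mb[mb$position > 3 & mb$position <= max(rd$width) - 3, ]
  expect_equal(n3, sum(interior$n))
  ## with no clipping the M-bias aggregate equals the extraction totals
  expect_equal(n0, sum(mb$n))
})

test_that("M-bias is flat without a planted artifact and detects one", {
  g <- generateGenome(contig_length = 3e5, n_islands = 5, seed = 101)
  tr <- assignTruth(g, cpa_level = 0, seed = 102)
  p_flat <- protocolProfile(conversion_failure = 0.02, error_rate = 0)
  fr <- simulateFragments(g, tr, p_flat, n_pairs = 20000, seed = 103)
  mb <- mbiasProfile(fr, g)
  cph <- mb[mb$context == "CpT" & mb$read == 1, ]
  ## chi-square across positions, null: constant retention
  m_i <- round(cph$retention * cph$n / 100)
  tab <- rbind(m_i, cph$n - m_i)
  pval <- suppressWarnings(chisq.test(t(tab))$p.value)
  expect_gt(pval, 0.01)
  ## plant a 5x conversion-failure inflation in the first 5 bp
  p_bias <- protocolProfile(conversion_failure = 0.02, error_rate = 0,
                            mbias_curve = c(rep(5, 5), rep(1, 95)))
  fr2 <- simulateFragments(g, tr, p_bias, n_pairs = 20000, seed = 104)
  mb2 <- mbiasProfile(fr2, g)
  cph2 <- mb2[mb2$context %in% c("CpC", "CpT") & mb2$read == 1, ]
  head_ret <- weighted.mean(cph2$retention[cph2$position <= 5],
                            cph2$n[cph2$position <= 5])
  tail_ret <- weighted.mean(cph2$retention[cph2$position > 5],
                            cph2$n[cph2$position > 5])
  expect_gt(head_ret, 3 * tail_ret)
})

test_that("higher conversion failure raises CpH retention monotonically", {
  g <- generateGenome(contig_length = 2e5, n_islands = 4, seed = 111)
  tr <- assignTruth(g, seed = 112)
  ret <- vapply(c(0.002, 0.01, 0.03), function(cf) {
    fr <- simulateFragments(g, tr, protocolProfile(conversion_failure = cf),
                            n_pairs = 8000, seed = round(1000 * cf) + 7)
    rs <- retentionSummary(extractMethylation(fr, g))
    mean(rs$read_averaged[rs$context %in% c("CpC", "CpT")])
  }, numeric(1))
  expect_true(all(diff(ret) > 0))
})

test_that("biological CpA methylation adds to the conversion artifact", {
  g <- generateGenome(contig_length = 3e5, n_islands = 5, seed = 121)
  tr <- assignTruth(g, cpa_level = 0.02, seed = 122)
  fr <- simulateFragments(g, tr, protocolProfile(conversion_failure = 0.005),
                          n_pairs = 20000, seed = 123)
  rs <- retentionSummary(extractMethylation(fr, g))
  cpa <- rs$read_averaged[rs$context == "CpA"]
  n <- rs$n_observations[rs$context == "CpA"]
  expected <- 100 * (0.02 + (1 - 0.02) * 0.005)
  expect_lt(abs(cpa - expected), 100 * 2.576 * sqrt(0.025 * 0.975 / n) + 0.1)
  ## CpC/CpT stay at the artifact level
  expect_lt(max(rs$read_averaged[rs$context %in% c("CpC", "CpT")]), 1)
})

test_that("control report applies per-control coverage rules", {
  g <- generateGenome(contig_length = 2e5, n_islands = 4, seed = 131)
  tr <- assignTruth(g, seed = 132)
  fr <- simulateFragments(g, tr,
                          protocolProfile(conversion_failure = 0.01,
                                          overconversion = 0.02,
                                          duplication_rate = 0),
                          n_pairs = 30000, seed = 133,
                          spikein_unmeth_rate = 0.01,
                          spikein_meth_rate = 0.005)
  mg <- mergeCpGStrands(extractMethylation(fr, g))
  cr <- controlReport(mg, genomeRegions(g))
  expect_equal(cr$min_cov, c(1L, 1L, 3L))
  lam <- cr[cr$control == "lambda_like", ]
  n_obs <- sum({
    s <- siteRecords(mg)
    sel <- as.character(seqnames(s)) == "lambda_like"
    (mcols(s)$M + mcols(s)$U)[sel]
  })
  expect_lt(abs(lam$conversion_estimate - 0.01),
            2.576 * sqrt(0.01 * 0.99 / n_obs) + 0.005)
  puc <- cr[cr$control == "puc19_like", ]
  expect_false(puc$empty)
  expect_gt(puc$mean_beta, 0.9)
  mito <- cr[cr$control == "mito_like", ]
  expect_lt(mito$mean_beta, 0.05)
  ## empty control is flagged, not an error
  few <- simulateFragments(g, tr, protocolProfile(duplication_rate = 0),
                           n_pairs = 50, seed = 134,
                           spikein_unmeth_rate = 0, spikein_meth_rate = 0)
  mg2 <- mergeCpGStrands(extractMethylation(few, g))
  cr2 <- controlReport(mg2, genomeRegions(g))
  expect_true(cr2$empty[cr2$control == "puc19_like"])
  expect_true(is.na(cr2$mean_beta[cr2$control == "puc19_like"]))
})

test_that("the Adaptase tail is excluded by the read-2 clip", {
  g <- generateGenome(contig_length = 2e5, n_islands = 4, seed = 141)
  tr <- assignTruth(g, seed = 142)
  fr <- simulateFragments(g, tr, protocolPreset("swift"), n_pairs = 10000,
                          seed = 143)
  ## unclipped: the random tail garbles read-2 leading positions (CpH
  ## retention jumps there because random bases hit the retained letter)
  mb <- mbiasProfile(fr, g)
  cph <- mb[mb$context == "CpT" & mb$read == 2, ]
  head_ret <- weighted.mean(cph$retention[cph$position <= 14],
                            cph$n[cph$position <= 14])
  tail_ret <- weighted.mean(cph$retention[cph$position > 14],
                            cph$n[cph$position > 14])
  expect_gt(head_ret, 5 * tail_ret)
  ## clipping restores clean retention
  ms_clip <- extractMethylation(fr, g, r2_clip = 14)
  rs <- retentionSummary(ms_clip)
  expect_lt(max(rs$read_averaged[rs$context %in% c("CpC", "CpT")]), 1.5)
})
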