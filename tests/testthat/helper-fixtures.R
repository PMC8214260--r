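## Shared fixtures (built once per test run) and independent brute-force
## oracles used by the oracle-equivalence tests.

suppressMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

## -- small shared simulation -------------------------------------------------

fix_genome <- generateGenome(contig_length = 1.5e5, n_islands = 4, seed = 11)
fix_truth <- assignTruth(fix_genome, seed = 12)
fix_profile <- protocolPreset("neb")
fix_frags <- simulateFragments(fix_genome, fix_truth, fix_profile,
                               n_pairs = 4000, seed = 13)
fix_sites <- extractMethylation(fix_frags, fix_genome)
fix_merged <- mergeCpGStrands(fix_sites)
fix_census <- regions(genomeRegions(fix_genome), "cpg_sites")
fix_main <- GRanges("chr1", IRanges(1, 1.5e5))

## -- constructed FragmentSet for arithmetic cases ----------------------------

## build a minimal FragmentSet from parallel vectors; one row per read
makeFrags <- function(pair_id, read = rep(1L, length(pair_id)),
                      chrom = rep("chr1", length(pair_id)),
                      pos = rep(0L, length(pair_id)),
                      width = rep(10L, length(pair_id)),
                      reverse = rep(FALSE, length(pair_id)),
                      mapq = rep(60L, length(pair_id)),
                      mapped = rep(TRUE, length(pair_id)),
                      dup = rep(FALSE, length(pair_id)),
                      isize = rep(100L, length(pair_id)),
                      bs_strand = rep("OT", length(pair_id)),
                      seq = strrep("A", width),
                      qual = strrep("I", width),
                      seqlen = 100000L) {
  FragmentSet(data.frame(pair_id = as.integer(pair_id),
                         read = as.integer(read), chrom = chrom,
                         pos = as.integer(pos), width = as.integer(width),
                         reverse = reverse, mapq = as.integer(mapq),
                         mapped = mapped, dup = dup,
                         isize = as.integer(isize), bs_strand = bs_strand,
                         seq = seq, qual = qual),
              GenomeInfoDb::Seqinfo("chr1", seqlen))
}

## phred string from integer qualities
phredStr <- function(q) rawToChar(as.raw(q + 33L))

## -- independent brute-force oracles -----------------------------------------

## per-base observed/expected ratio by explicit base counting
oracleObsExp <- function(frags, region, maptrack, mapq_min = 40) {
  rd <- as.data.frame(fragmentReads(frags))
  rd <- rd[rd$mapped & rd$mapq >= mapq_min & !rd$dup, ]
  si <- seqinfo(frags)
  depth <- lapply(GenomeInfoDb::seqlengths(si), function(L) integer(L))
  for (i in seq_len(nrow(rd))) {
    idx <- (rd$pos[i] + 1):(rd$pos[i] + rd$width[i])
    depth[[rd$chrom[i]]][idx] <- depth[[rd$chrom[i]]][idx] + 1L
  }
  score <- lapply(GenomeInfoDb::seqlengths(si), function(L) rep(NA_real_, L))
  mp <- as.data.frame(mappability(maptrack))
  for (i in seq_len(nrow(mp)))
    score[[as.character(mp$seqnames[i])]][mp$start[i]:mp$end[i]] <- mp$score[i]
  inreg <- lapply(GenomeInfoDb::seqlengths(si), function(L) logical(L))
  rg <- as.data.frame(region)
  for (i in seq_len(nrow(rg)))
    inreg[[as.character(rg$seqnames[i])]][rg$start[i]:rg$end[i]] <- TRUE
  obs_num <- obs_den <- exp_num <- exp_den <- 0
  for (cn in names(depth)) {
    scored <- !is.na(score[[cn]])
    obs_den <- obs_den + sum(depth[[cn]][scored])
    obs_num <- obs_num + sum(depth[[cn]][scored & inreg[[cn]]])
    exp_den <- exp_den + sum(score[[cn]][scored])
    exp_num <- exp_num + sum(score[[cn]][scored & inreg[[cn]]])
  }
  obs <- obs_num / obs_den
  ex <- exp_num / exp_den
  c(obs = obs, exp = ex, ratio = obs / ex)
}

## percent of census CpGs in region covered >= min_cov, by explicit
## interval containment
oraclePctCovered <- function(msset, region, census, min_cov = 1) {
  cen <- as.data.frame(census); cen$seqnames <- as.character(cen$seqnames)
  rg <- as.data.frame(region); rg$seqnames <- as.character(rg$seqnames)
  inreg <- rep(FALSE, nrow(cen))
  for (i in seq_len(nrow(rg)))
    inreg <- inreg | (cen$seqnames == rg$seqnames[i] &
                      cen$end >= rg$start[i] & cen$start <= rg$end[i])
  cen <- cen[inreg, ]
  st <- as.data.frame(siteRecords(msset))
  st$seqnames <- as.character(st$seqnames)
  st$cov <- st$M + st$U
  covered <- vapply(seq_len(nrow(cen)), function(i) {
    any(st$seqnames == cen$seqnames[i] & st$cov >= min_cov &
        st$end >= cen$start[i] & st$start <= cen$end[i])
  }, logical(1))
  sum(covered) / nrow(cen)
}

## group-by bin means with base R
oracleBinMeans <- function(msset, width) {
  st <- as.data.frame(siteRecords(msset))
  st$beta <- st$M / (st$M + st$U)
  st$bin <- paste(st$seqnames, (st$start - 1) %/% width)
  means <- tapply(st$beta, st$bin, mean)
  counts <- tapply(st$beta, st$bin, length)
  data.frame(bin = names(means), mean_beta = as.numeric(means),
             n_cpgs = as.integer(counts))
}

## pair-level duplicate identity keys, built independently
oracleKeys <- function(frags) {
  rd <- as.data.frame(fragmentReads(frags))
  rd <- rd[rd$mapped, ]
  sp <- split(rd, rd$pair_id)
  vapply(sp, function(p) {
    paste(p$chrom[1], min(p$pos),
          if (p$bs_strand[1] %in% c("OT", "CTOT")) "+" else "-",
          p$isize[1], sep = ":")
  }, character(1))
}
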