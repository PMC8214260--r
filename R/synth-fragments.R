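## Bisulfite/enzymatic WGMS read-pair simulator.
##
## Works at the byte level throughout: reference substrings are gathered into
## one long raw vector, conversion/error/tail edits are applied as vectorized
## raw-vector assignments, and per-read strings are recovered with substring().

.retained_letter <- c(OT = "C", OB = "G", CTOT = "G", CTOB = "C")
.converted_letter <- c(OT = "T", OB = "A", CTOT = "A", CTOB = "T")

## extend an M-bias multiplier curve to read_len positions (last value held)
.mbias_vec <- function(curve, read_len) {
  curve[pmin(seq_len(read_len), length(curve))]
}

#' Simulate aligned WGMS read pairs
#'
#' Draws `n_pairs` paired-end fragments from a [SyntheticGenome-class] under a
#' [ProtocolProfile-class]: spike-in fragments at the configured rates
#' (defaults 0.01% unmethylated lambda-like, 0.0005% methylated pUC19-like,
#' the trace fractions at which the controls are added to genomic DNA),
#' remaining fragments over main + mito contigs in proportion to length, with
#' fragment starts re-weighted by `cgi_bias` inside CpG islands. Insert sizes
#' follow a log-normal law truncated to \[35, 1000\] bp and to at least half
#' the read length. Each fragment takes one parent strand; directional
#' libraries report it as OT/OB, PBAT as CTOT/CTOB. Per-cytosine observed
#' states are drawn from the truth level, `conversion_failure` (modulated
#' along the read by `mbias_curve`) and `overconversion`. PCR duplicates are
#' re-emissions of an earlier molecule (identical coordinates and conversion
#' states, fresh qualities) and are flagged on emission. A configurable
#' fraction of reads is emitted unmapped (chrom/pos absent) or with
#' MAPQ < 40.
#'
#' @param genome A [SyntheticGenome-class].
#' @param truth A [MethylationTruth-class] over the same genome.
#' @param profile A [ProtocolProfile-class].
#' @param n_pairs Number of read pairs to emit (>= 1).
#' @param read_len Read length in bp.
#' @param seed Mandatory RNG seed; the fragment stream is identical for a
#'   fixed seed.
#' @param spikein_unmeth_rate,spikein_meth_rate Fraction of fragments drawn
#'   from the unmethylated / methylated spike-in contigs.
#' @return A [FragmentSet-class]; its run manifest (see [runManifest()])
#'   records all parameters and the seed.
#' @examples
#' g <- generateGenome(contig_length = 1e5, n_islands = 3, seed = 1)
#' tr <- assignTruth(g, seed = 2)
#' fr <- simulateFragments(g, tr, protocolProfile(), n_pairs = 500, seed = 3)
#' fr
#' @export
simulateFragments <- function(genome, truth, profile, n_pairs,
                              read_len = 100L, seed,
                              spikein_unmeth_rate = 1e-4,
                              spikein_meth_rate = 5e-6) {
  seed <- .check_seed(seed)
  stopifnot(is(genome, "SyntheticGenome"), is(truth, "MethylationTruth"),
            is(profile, "ProtocolProfile"))
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  set.seed(seed)
  read_len <- as.integer(read_len)

  seqs <- genomeSequences(genome)
  contigs <- names(seqs)
  Lc <- setNames(width(seqs), contigs)
  genomic_contigs <- setdiff(contigs, c("lambda_like", "puc19_like"))

  ## ---- pair-level draws (original molecules) ----
  n_dup <- rbinom(1L, n_pairs, profile@duplication_rate)
  n_orig <- n_pairs - n_dup
  if (n_orig < 1L) { n_orig <- 1L; n_dup <- n_pairs - 1L }

  u <- runif(n_orig)
  cls <- rep(NA_character_, n_orig)
  cls[u < spikein_unmeth_rate] <- "lambda_like"
  cls[u >= spikein_unmeth_rate &
      u < spikein_unmeth_rate + spikein_meth_rate] <- "puc19_like"
  ng <- sum(is.na(cls))
  if (ng)
    cls[is.na(cls)] <- sample(genomic_contigs, ng, replace = TRUE,
                              prob = Lc[genomic_contigs])

  mu <- profile@insert_mean; sdv <- profile@insert_sd
  sdlog <- sqrt(log1p((sdv / mu)^2))
  meanlog <- log(mu) - sdlog^2 / 2
  ins <- as.integer(round(rlnorm(n_orig, meanlog, sdlog)))
  lo <- max(35L, as.integer(ceiling(read_len / 2)))
  ins <- pmin(pmax(ins, lo), 1000L)
  ins <- pmin(ins, Lc[cls] - 1L)

  start0 <- as.integer(floor(runif(n_orig) * (Lc[cls] - ins + 1L)))
  if (profile@cgi_bias != 1) {
    isl <- regions(genomeRegions(genome), "cpg_islands")
    for (cn in intersect(unique(cls), unique(as.character(seqnames(isl))))) {
      idx <- which(cls == cn)
      isl_c <- isl[as.character(seqnames(isl)) == cn]
      Li <- sum(width(isl_c)); Ln <- Lc[[cn]]
      p_isl <- profile@cgi_bias * Li / (profile@cgi_bias * Li + (Ln - Li))
      in_isl <- runif(length(idx)) < p_isl
      k <- sum(in_isl)
      if (k) {
        wi <- sample.int(length(isl_c), k, replace = TRUE, prob = width(isl_c))
        s <- start(isl_c)[wi] - 1L +
          as.integer(floor(runif(k) * width(isl_c)[wi]))
        start0[idx[in_isl]] <- pmax(0L, pmin(s, Ln - ins[idx[in_isl]]))
      }
      k2 <- sum(!in_isl)
      if (k2) {
        gap_c <- GenomicRanges::setdiff(GRanges(cn, IRanges(1L, Ln)), isl_c,
                                        ignore.strand = TRUE)
        wg <- sample.int(length(gap_c), k2, replace = TRUE, prob = width(gap_c))
        s <- start(gap_c)[wg] - 1L +
          as.integer(floor(runif(k2) * width(gap_c)[wg]))
        start0[idx[!in_isl]] <- pmax(0L, pmin(s, Ln - ins[idx[!in_isl]]))
      }
    }
  }

  parent <- sample(c("+", "-"), n_orig, replace = TRUE)
  bs <- if (profile@strand_convention == "directional") {
    ifelse(parent == "+", "OT", "OB")
  } else {
    ifelse(parent == "+", "CTOT", "CTOB")
  }

  ## ---- molecule-level reads (coordinates shared with any duplicates) ----
  w_read <- pmin(read_len, ins)
  r1_left <- bs %in% c("OT", "CTOB")
  mol <- data.table(
    mol = rep(seq_len(n_orig), each = 2L),
    read = rep(c(1L, 2L), n_orig),
    chrom = rep(cls, each = 2L),
    isize = rep(ins, each = 2L),
    parent = rep(parent, each = 2L),
    bs_strand = rep(bs, each = 2L),
    width = rep(w_read, each = 2L))
  left_pos <- rep(start0, each = 2L)
  right_pos <- rep(start0 + ins - w_read, each = 2L)
  is_r1 <- mol$read == 1L
  r1l <- rep(r1_left, each = 2L)
  mol[, pos := fifelse(is_r1 == r1l, left_pos, right_pos)]
  mol[, reverse := (is_r1 != r1l)]

  ## ---- gather reference bytes contig by contig ----
  setorder(mol, chrom, mol, read)
  offsets <- c(0L, cumsum(as.numeric(mol$width)))
  allbytes <- raw(sum(as.numeric(mol$width)))
  for (cn in unique(mol$chrom)) {
    rows <- which(mol$chrom == cn)
    cb <- charToRaw(as.character(seqs[[cn]]))
    idx <- sequence(mol$width[rows], from = mol$pos[rows] + 1L)
    dst <- sequence(mol$width[rows], from = as.integer(offsets[rows]) + 1L)
    allbytes[dst] <- cb[idx]
  }

  ## ---- cytosine observations on the parent strand ----
  tr <- truthSites(truth)
  mol_gr <- GRanges(mol$chrom, IRanges(mol$pos + 1L, width = mol$width))
  hits <- findOverlaps(mol_gr, tr, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  same <- as.character(strand(tr))[sh] == mol$parent[qh]
  qh <- qh[same]; sh <- sh[same]
  off <- start(tr)[sh] - (mol$pos[qh] + 1L)           # 0-based offset in span
  read_pos <- ifelse(mol$reverse[qh], mol$width[qh] - off, off + 1L)
  mmv <- .mbias_vec(profile@mbias_curve, read_len)
  level <- mcols(tr)$level[sh]
  methylated <- runif(length(sh)) < level
  p_ret <- ifelse(methylated, 1 - profile@overconversion,
                  pmin(1, profile@conversion_failure * mmv[read_pos]))
  retained <- runif(length(sh)) < p_ret
  abspos <- as.integer(offsets[qh]) + off + 1L

  ## sequencing errors on non-cytosine bases only
  if (profile@error_rate > 0) {
    n_err <- rbinom(1L, length(allbytes), profile@error_rate)
    if (n_err) {
      ep <- sample.int(length(allbytes), n_err)
      ep <- ep[!ep %in% abspos]
      if (length(ep))
        allbytes[ep] <- charToRaw("ACGT")[sample.int(4L, length(ep), TRUE)]
    }
  }

  ## conversion edits (retained/converted letters depend on bisulfite strand)
  bs_hit <- mol$bs_strand[qh]
  letter <- ifelse(retained, .retained_letter[bs_hit], .converted_letter[bs_hit])
  allbytes[abspos] <- charToRaw(paste(letter, collapse = ""))

  ## Adaptase-style low-complexity tail at the start of read 2
  clip <- profile@r2_tail_clip
  if (clip > 0L) {
    r2 <- which(mol$read == 2L)
    ce <- pmin(clip, mol$width[r2])
    from0 <- ifelse(mol$reverse[r2], mol$width[r2] - ce, 0L)
    tp <- rep(as.integer(offsets[r2]), ce) + sequence(ce, from = from0 + 1L)
    allbytes[tp] <- charToRaw("ACGT")[sample.int(4L, length(tp), TRUE)]
  }

  big <- rawToChar(allbytes)
  ends_ <- as.integer(offsets[-1L]); starts_ <- as.integer(offsets[-length(offsets)]) + 1L
  mol[, seq := substring(big, starts_, ends_)]
  setorder(mol, mol, read)                             # back to molecule order

  ## ---- emit pairs: originals then duplicate re-emissions ----
  src <- c(seq_len(n_orig), if (n_dup) sample.int(n_orig, n_dup, replace = TRUE))
  dupflag <- rep(c(FALSE, TRUE), c(n_orig, n_dup))
  rows <- as.vector(rbind(2L * src - 1L, 2L * src))    # (r1, r2) per emitted pair
  reads <- mol[rows]
  reads[, pair_id := rep(seq_len(n_pairs), each = 2L)]
  reads[, dup := rep(dupflag, each = 2L)]

  ## mapping status per read fragment
  nr <- nrow(reads)
  u2 <- runif(nr)
  unmapped <- u2 < profile@frac_unmapped
  subopt <- !unmapped & u2 < profile@frac_unmapped + profile@frac_suboptimal
  reads[, mapped := !unmapped]
  reads[, mapq := fifelse(unmapped, NA_integer_,
                          fifelse(subopt, sample(0:39, nr, replace = TRUE), 60L))]
  reads[unmapped, `:=`(chrom = NA_character_, pos = NA_integer_)]

  ## fresh per-base qualities for every emitted read
  qm <- profile@qual_mean[reads$read]
  tot <- sum(reads$width)
  q <- as.integer(round(rnorm(tot, mean = rep(qm, reads$width),
                              sd = profile@qual_sd)))
  reads[, qual := intToPhred(q, reads$width)]

  reads <- reads[, c("pair_id", "read", "chrom", "pos", "width", "reverse",
                     "mapq", "mapped", "dup", "isize", "bs_strand",
                     "seq", "qual"), with = FALSE]

  manifest <- list(
    n_pairs = n_pairs, read_len = read_len, seed = seed,
    profile = profile@name, strand_convention = profile@strand_convention,
    insert_mean = mu, insert_sd = sdv,
    duplication_rate = profile@duplication_rate,
    conversion_failure = profile@conversion_failure,
    overconversion = profile@overconversion,
    cgi_bias = profile@cgi_bias, r2_tail_clip = clip,
    error_rate = profile@error_rate,
    spikein_unmeth_rate = spikein_unmeth_rate,
    spikein_meth_rate = spikein_meth_rate,
    truth = truth@manifest)

  new("FragmentSet", reads = reads, seqinfo = seqinfo(genome),
      manifest = manifest)
}
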