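## Synthetic reference genome with planted CpG islands, annotations,
## spike-in control contigs and a mappability track.

.rand_bases <- function(n, gc = 0.40) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  charToRaw("ACGT")[sample.int(4L, n, replace = TRUE, prob = probs)]
}

## mutate C->T at a fraction of CG dinucleotides (CpG depletion of the
## mammalian-like background)
.deplete_cpg <- function(b, frac) {
  if (frac <= 0) return(b)
  ib <- as.integer(b)
  p <- which(ib[-length(ib)] == .BASE_C & ib[-1L] == .BASE_G)
  if (!length(p)) return(b)
  hit <- p[runif(length(p)) < frac]
  b[hit] <- charToRaw("T")
  b
}

#' Generate a synthetic WGMS reference genome
#'
#' Builds a small reference for simulation: one or more main contigs with a
#' CpG-depleted background and planted GC-rich CpG-island segments, gene /
#' exon / repeat-masked annotations, an unmethylated lambda-like spike-in
#' contig, a methylated pUC19-like spike-in contig, and an unmethylated
#' circular mitochondria-like contig. Region annotations cover
#' `cpg_sites` (the merged CpG dinucleotide census of the main contigs),
#' `cpg_islands`, `exons`, `genes`, `intergenic`, `repeat_masked`,
#' `spikein_unmethylated`, `spikein_methylated` and `mitochondrial`.
#' Mappability defaults to 1.0 everywhere; `low_map_frac > 0` plants
#' low-mappability segments.
#'
#' Planted islands have a CpG density at least three times the depleted
#' background (GC 0.60 undepleted vs GC 0.40 with 75% of background CpGs
#' removed).
#'
#' @param contig_length Length of each main contig in bp (default 5e6).
#' @param n_contigs Number of main contigs.
#' @param n_islands CpG islands planted per main contig.
#' @param island_width Width of each planted island in bp.
#' @param gc_background,gc_island GC content of background / islands.
#' @param cpg_depletion Fraction of background CpG dinucleotides mutated away.
#' @param n_genes Genes annotated per main contig (exons drawn inside genes).
#' @param repeat_frac Approximate fraction of each main contig annotated
#'   repeat-masked.
#' @param spikein_unmeth_length,spikein_meth_length,mito_length Lengths of the
#'   lambda-like, pUC19-like and mitochondria-like contigs.
#' @param low_map_frac Fraction of main-contig bases given mappability
#'   `low_map_score` instead of 1.0 (contiguous planted segments).
#' @param low_map_score Score of planted low-mappability segments.
#' @param seed Mandatory RNG seed; the genome is byte-identical for a fixed
#'   seed.
#' @return A [SyntheticGenome-class].
#' @examples
#' g <- generateGenome(contig_length = 2e5, n_islands = 5, seed = 1)
#' genomeRegions(g)
#' @export
generateGenome <- function(contig_length = 5e6, n_contigs = 1L,
                           n_islands = 40L, island_width = 1000L,
                           gc_background = 0.40, gc_island = 0.60,
                           cpg_depletion = 0.75,
                           n_genes = 20L, repeat_frac = 0.10,
                           spikein_unmeth_length = 6000L,
                           spikein_meth_length = 2700L,
                           mito_length = 4000L,
                           low_map_frac = 0, low_map_score = 0.2,
                           seed) {
  seed <- .check_seed(seed)
  if (contig_length < 1e5)
    stop("main contigs must be at least 100 kb", call. = FALSE)
  if (n_islands * (island_width + 200L) > contig_length / 2)
    stop("island count incompatible with contig length", call. = FALSE)
  set.seed(seed)

  main_names <- paste0("chr", seq_len(n_contigs))
  seq_list <- list()
  isl_list <- list(); gene_list <- list(); exon_list <- list()
  rep_list <- list(); lowmap_list <- list()

  for (ci in seq_len(n_contigs)) {
    b <- .rand_bases(contig_length, gc_background)
    b <- .deplete_cpg(b, cpg_depletion)
    ## non-overlapping island starts: partition the contig into n_islands
    ## equal stripes and place one island uniformly inside each
    stripe <- contig_length %/% n_islands
    starts <- (seq_len(n_islands) - 1L) * stripe +
      sample.int(stripe - island_width, n_islands, replace = TRUE)
    for (s in starts)
      b[(s + 1L):(s + island_width)] <- .rand_bases(island_width, gc_island)
    seq_list[[main_names[ci]]] <- rawToChar(b)
    isl_list[[ci]] <- GRanges(main_names[ci],
                              IRanges(starts + 1L, width = island_width))

    ## genes: one per stripe-of-genes, uniform width 2-10 kb
    gs <- contig_length %/% n_genes
    gw <- pmin(sample(2000:10000, n_genes, replace = TRUE), gs - 100L)
    gstart <- (seq_len(n_genes) - 1L) * gs +
      sample.int(max(gs - max(gw) - 1L, 1L), n_genes, replace = TRUE)
    gene_list[[ci]] <- GRanges(main_names[ci], IRanges(gstart + 1L, width = gw))
    ## exons: 2-6 per gene, 100-300 bp, spread over the gene
    ex <- list()
    for (gi in seq_len(n_genes)) {
      ne <- sample(2:6, 1L)
      ew <- sample(100:300, ne, replace = TRUE)
      stripe_g <- gw[gi] %/% ne
      es <- gstart[gi] + (seq_len(ne) - 1L) * stripe_g +
        sample.int(max(stripe_g - 300L, 1L), ne, replace = TRUE)
      ex[[gi]] <- IRanges(es + 1L, width = pmin(ew, stripe_g - 1L))
    }
    exon_list[[ci]] <- GRanges(main_names[ci], do.call(c, ex))
    ## repeat-masked: contiguous 500-2000 bp segments up to repeat_frac
    target <- repeat_frac * contig_length
    nrep <- ceiling(target / 1250)
    rs <- contig_length %/% max(nrep, 1L)
    rw <- sample(500:2000, nrep, replace = TRUE)
    rstart <- (seq_len(nrep) - 1L) * rs +
      sample.int(max(rs - 2000L, 1L), nrep, replace = TRUE)
    rep_list[[ci]] <- GRanges(main_names[ci], IRanges(rstart + 1L, width = rw))
    if (low_map_frac > 0) {
      nlm <- max(1L, ceiling(low_map_frac * contig_length / 5000))
      ls <- contig_length %/% nlm
      lstart <- (seq_len(nlm) - 1L) * ls +
        sample.int(max(ls - 5000L, 1L), nlm, replace = TRUE)
      lowmap_list[[ci]] <- GRanges(main_names[ci],
                                   IRanges(lstart + 1L, width = 5000L))
    }
  }

  ## control contigs: undepleted, moderate GC, no islands
  seq_list[["lambda_like"]] <- rawToChar(.rand_bases(spikein_unmeth_length, 0.50))
  seq_list[["puc19_like"]] <- rawToChar(.rand_bases(spikein_meth_length, 0.50))
  seq_list[["mito_like"]] <- rawToChar(.rand_bases(mito_length, 0.45))

  seqs <- DNAStringSet(unlist(seq_list))
  si <- Seqinfo(seqnames = names(seqs), seqlengths = width(seqs),
                isCircular = names(seqs) == "mito_like")

  main_gr <- GRanges(main_names, IRanges(1L, width = contig_length))
  genes <- do.call(c, gene_list)
  intergenic <- GenomicRanges::setdiff(main_gr, genes, ignore.strand = TRUE)

  onSi <- function(gr) {  # harmonize seqlevels across all labels
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(si)
    seqinfo(gr) <- si
    gr
  }
  rs <- RegionSet(
    cpg_sites = onSi(cpgCensus(seqs[main_names])),
    cpg_islands = onSi(do.call(c, isl_list)),
    genes = onSi(genes),
    exons = onSi(do.call(c, exon_list)),
    intergenic = onSi(intergenic),
    repeat_masked = onSi(do.call(c, rep_list)),
    spikein_unmethylated = onSi(GRanges("lambda_like", IRanges(1L, spikein_unmeth_length))),
    spikein_methylated = onSi(GRanges("puc19_like", IRanges(1L, spikein_meth_length))),
    mitochondrial = onSi(GRanges("mito_like", IRanges(1L, mito_length))))

  all_gr <- GRanges(names(seqs), IRanges(1L, width = width(seqs)))
  if (length(lowmap_list)) {
    low <- GenomicRanges::reduce(do.call(c, lowmap_list))
    rest <- GenomicRanges::setdiff(all_gr, low, ignore.strand = TRUE)
    mcols(low)$score <- low_map_score
    mcols(rest)$score <- 1.0
    map <- MappabilityTrack(c(low, rest))
  } else {
    mcols(all_gr)$score <- 1.0
    map <- MappabilityTrack(all_gr)
  }

  new("SyntheticGenome", sequences = seqs, regions = rs, mappability = map,
      seqinfo = si,
      params = list(contig_length = contig_length, n_contigs = n_contigs,
                    n_islands = n_islands, island_width = island_width,
                    gc_background = gc_background, gc_island = gc_island,
                    cpg_depletion = cpg_depletion, seed = seed))
}

#' Assign ground-truth methylation levels
#'
#' Draws a per-CpG methylation probability for the main contigs from a Beta
#' distribution with the requested mean and concentration (both strands of a
#' palindromic CpG share one level), sets all CpA sites to `cpa_level`
#' (biological CpH methylation), CpC/CpT to 0, and pins the control contigs:
#' lambda-like and mito-like to exactly 0, pUC19-like to exactly 1.
#'
#' @param genome A [SyntheticGenome-class].
#' @param cpg_mean Mean of the CpG truth distribution (default 0.75).
#' @param cpg_concentration Beta concentration (a+b); smaller is more bimodal.
#' @param cpa_level Methylation probability of main-contig CpA sites.
#' @param seed Mandatory RNG seed.
#' @return A [MethylationTruth-class]; the manifest records distribution and
#'   seed.
#' @export
assignTruth <- function(genome, cpg_mean = 0.75, cpg_concentration = 2,
                        cpa_level = 0, seed) {
  seed <- .check_seed(seed)
  stopifnot(is(genome, "SyntheticGenome"))
  if (cpg_mean <= 0 || cpg_mean >= 1) stop("cpg_mean must be in (0, 1)")
  if (cpa_level < 0 || cpa_level > 1) stop("cpa_level must be in [0, 1]")
  set.seed(seed)

  sites <- cytosineSites(genomeSequences(genome))
  lv <- numeric(length(sites))
  ctx <- mcols(sites)$context
  chrom <- as.character(seqnames(sites))
  is_main <- !chrom %in% c("lambda_like", "puc19_like", "mito_like")

  ## one level per palindromic CpG, shared by its two strand records
  census <- regions(genomeRegions(genome), "cpg_sites")
  a <- cpg_mean * cpg_concentration
  b <- (1 - cpg_mean) * cpg_concentration
  cpg_levels <- rbeta(length(census), a, b)
  idx_cpg <- which(is_main & ctx == "CpG")
  hits <- findOverlaps(sites[idx_cpg], census, ignore.strand = TRUE)
  lv[idx_cpg[S4Vectors::queryHits(hits)]] <- cpg_levels[S4Vectors::subjectHits(hits)]

  lv[is_main & ctx == "CpA"] <- cpa_level
  lv[chrom == "puc19_like"] <- 1.0
  lv[chrom %in% c("lambda_like", "mito_like")] <- 0.0

  mcols(sites)$level <- lv
  new("MethylationTruth", sites = sites,
      manifest = list(distribution = "beta", cpg_mean = cpg_mean,
                      cpg_concentration = cpg_concentration,
                      cpa_level = cpa_level, seed = seed))
}
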