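## Orchestration: artifact writers, run configuration and the end-to-end
## simulate -> metrics -> compare pipeline with a summary report.

#' Write the synthetic genome artifacts
#'
#' Emits the reference FASTA, the region annotations as BED (0-based
#' half-open, label in the name column), the mappability track as bedGraph
#' and, when given, the per-site truth TSV (chrom, pos0, strand, context,
#' level) and a JSON manifest.
#'
#' @param genome A [SyntheticGenome-class].
#' @param dir Output directory (created if needed).
#' @param truth Optional [MethylationTruth-class].
#' @return The directory, invisibly.
#' @export
writeGenomeFiles <- function(genome, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeXStringSet(genomeSequences(genome), file.path(dir, "genome.fa"))
  rs <- genomeRegions(genome)
  bed <- rbindlist(lapply(regionLabels(rs), function(lb) {
    gr <- regions(rs, lb)
    data.table(chrom = as.character(seqnames(gr)), start = start(gr) - 1L,
               end = end(gr), label = lb)
  }))
  fwrite(bed, file.path(dir, "regions.bed"), sep = "\t", col.names = FALSE)
  mp <- mappability(genomeMappability(genome))
  fwrite(data.table(chrom = as.character(seqnames(mp)), start = start(mp) - 1L,
                    end = end(mp), score = mcols(mp)$score),
         file.path(dir, "mappability.bedGraph"), sep = "\t",
         col.names = FALSE)
  if (!is.null(truth)) {
    tr <- truthSites(truth)
    fwrite(data.table(chrom = as.character(seqnames(tr)),
                      pos = start(tr) - 1L,
                      strand = as.character(strand(tr)),
                      context = mcols(tr)$context,
                      level = mcols(tr)$level),
           file.path(dir, "truth.tsv"), sep = "\t")
    jsonlite::write_json(truth@manifest, file.path(dir, "truth_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Run configuration for the end-to-end pipeline
#'
#' All defaults are echoed by [runAll()]; the seed is mandatory because
#' every stage past genome generation is stochastic.
#'
#' @param profiles Named list of [ProtocolProfile-class] objects, one per
#'   sample.
#' @param n_pairs Read pairs simulated per sample.
#' @param read_len Read length in bp.
#' @param contig_length,n_islands Main-contig geometry passed to
#'   [generateGenome()].
#' @param cpg_mean,cpa_level Truth parameters passed to [assignTruth()].
#' @param target Subsampling target in read fragments (Eq.-style fixed-depth
#'   comparison; a library below target is kept whole).
#' @param mapq_min,end_clip,bin_width,k,bias_min_cov,bias_threshold
#'   Downstream thresholds (MAPQ filter, read-end exclusion, bin width,
#'   M-value smoothing, bias-test coverage/threshold).
#' @param seed Mandatory integer seed.
#' @param out_dir Optional output directory for TSV/JSON/BED/SAM artifacts.
#' @return A `list` of class `wgms_run_config`.
#' @export
runConfig <- function(profiles, n_pairs = 20000L, read_len = 100L,
                      contig_length = 1e6, n_islands = 20L,
                      cpg_mean = 0.75, cpa_level = 0,
                      target = 150e6, mapq_min = 40L, end_clip = 3L,
                      bin_width = 100000L, k = 0.5,
                      bias_min_cov = 20L, bias_threshold = 0.5,
                      seed, out_dir = NULL) {
  seed <- .check_seed(seed)
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    stop("profiles must be a named list", call. = FALSE)
  structure(list(profiles = profiles, n_pairs = n_pairs, read_len = read_len,
                 contig_length = contig_length, n_islands = n_islands,
                 cpg_mean = cpg_mean, cpa_level = cpa_level, target = target,
                 mapq_min = mapq_min, end_clip = end_clip,
                 bin_width = bin_width, k = k, bias_min_cov = bias_min_cov,
                 bias_threshold = bias_threshold, seed = seed,
                 out_dir = out_dir),
            class = "wgms_run_config")
}

.stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[wgmsQC] ", fmt), ...))
}

#' Run the full pipeline on simulated samples
#'
#' Generates one genome and truth, simulates each configured sample,
#' computes the raw-read and alignment metrics, subsamples to the target
#' depth, extracts and merges methylation, and assembles a summary report
#' (per sample: read-fragment count, fraction of low-quality bases per
#' read, mean insert size, duplicate rate in percent, percent of reference
#' CpGs covered, percent read-averaged CpG retention). With two or more
#' samples, Spearman concordance of 100-kb binned betas is computed for
#' every pair; with three or more, the smoothed-M-value PCA. The run is
#' deterministic for a fixed config seed; all stage parameters are echoed
#' when `verbose = TRUE`.
#'
#' @param config A [runConfig()] object.
#' @param verbose Log stages and parameters (default TRUE).
#' @return list with `report` (data.frame), `samples` (per-sample
#'   intermediates: fragments, subsampled set, site records, merged CpGs,
#'   binned betas, retention, controls), `spearman` (data.frame or NULL)
#'   and `pca` (list or NULL).
#' @export
runAll <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "wgms_run_config"))
  cfg <- config
  .stage(verbose, "genome: contig_length=%g n_islands=%d seed=%d",
         cfg$contig_length, cfg$n_islands, cfg$seed + 1L)
  genome <- generateGenome(contig_length = cfg$contig_length,
                           n_islands = cfg$n_islands, seed = cfg$seed + 1L)
  truth <- assignTruth(genome, cpg_mean = cfg$cpg_mean,
                       cpa_level = cfg$cpa_level, seed = cfg$seed + 2L)
  census <- regions(genomeRegions(genome), "cpg_sites")
  main_region <- GRanges(seqinfo(genome))
  main_region <- main_region[as.character(seqnames(main_region)) %in%
                               unique(as.character(seqnames(census)))]

  samples <- list()
  rows <- list()
  for (i in seq_along(cfg$profiles)) {
    nm <- names(cfg$profiles)[i]
    prof <- cfg$profiles[[i]]
    .stage(verbose,
           "simulate '%s': n_pairs=%d read_len=%d profile=%s seed=%d",
           nm, cfg$n_pairs, cfg$read_len, prof@name, cfg$seed + 10L + i)
    frags <- simulateFragments(genome, truth, prof, n_pairs = cfg$n_pairs,
                               read_len = cfg$read_len,
                               seed = cfg$seed + 10L + i)
    bq <- baseQualityFractions(frags)
    af <- alignmentFractions(frags, cfg$mapq_min)
    iz <- insertSizeSummary(frags)
    dr <- duplicateRate(frags, cfg$mapq_min)
    .stage(verbose, "subsample '%s': target=%g mapq_min=%d", nm,
           cfg$target, cfg$mapq_min)
    sub <- subsampleFragments(frags, target = cfg$target,
                              mapq_min = cfg$mapq_min,
                              seed = cfg$seed + 100L + i)
    .stage(verbose, "methylation '%s': end_clip=%d r2_clip=%d", nm,
           cfg$end_clip, prof@r2_tail_clip)
    ms <- extractMethylation(sub, genome, end_clip = cfg$end_clip,
                             r2_clip = prof@r2_tail_clip,
                             mapq_min = cfg$mapq_min)
    merged <- mergeCpGStrands(ms)
    ret <- retentionSummary(ms)
    ctrl <- controlReport(merged, genomeRegions(genome))
    pct <- percentCpGsCovered(merged, main_region, census)
    bins <- binBetas(merged, seqinfo(genome), cfg$bin_width)
    rows[[nm]] <- data.frame(
      sample = nm,
      n_fragments = length(frags),
      frac_low_r1 = bq$frac_low[bq$read == 1L],
      frac_low_r2 = bq$frac_low[bq$read == 2L],
      frac_optimal = af$frac_optimal,
      mean_insert = iz$mean,
      duplicate_rate_pct = 100 * dr,
      pct_cpgs_covered = 100 * pct,
      pct_cpg_retention = ret$read_averaged[ret$context == "CpG"])
    samples[[nm]] <- list(fragments = frags, subsampled = sub, sites = ms,
                          merged = merged, bins = bins, retention = ret,
                          controls = ctrl, base_quality = bq,
                          alignment = af, insert = iz)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL

  spear <- NULL
  if (length(samples) >= 2L) {
    prs <- utils::combn(names(samples), 2L)
    spear <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
      sc <- spearmanConcordance(samples[[prs[1L, j]]]$bins,
                                samples[[prs[2L, j]]]$bins)
      data.frame(sample_a = prs[1L, j], sample_b = prs[2L, j],
                 r_s = sc$r_s, n_bins = sc$n_bins)
    }))
  }
  pca <- if (length(samples) >= 3L)
    pcaProtocols(lapply(samples, `[[`, "bins"), k = cfg$k) else NULL

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    writeGenomeFiles(genome, file.path(cfg$out_dir, "genome"), truth)
    for (nm in names(samples)) {
      writeMethylationBed(samples[[nm]]$merged,
                          file.path(cfg$out_dir, paste0(nm, ".meth.bed.gz")))
      fwrite(samples[[nm]]$retention,
             file.path(cfg$out_dir, paste0(nm, ".retention.tsv")), sep = "\t")
    }
    fwrite(report, file.path(cfg$out_dir, "report.tsv"), sep = "\t")
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if (!is.null(spear))
      fwrite(spear, file.path(cfg$out_dir, "correlations.tsv"), sep = "\t")
  }

  list(report = report, samples = samples, spearman = spear, pca = pca,
       genome = genome, truth = truth)
}
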