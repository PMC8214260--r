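## Central S4 containers shared by all modules.

setOldClass(c("data.table", "data.frame"))

#' RegionSet: named collections of genomic intervals
#'
#' A `RegionSet` holds the genomic element categories used throughout the
#' coverage and methylation metrics (CpG sites, CpG islands, exons, genes,
#' intergenic, repeat-masked regions, spike-in control contigs, the
#' mitochondrial contig). Within each label the intervals are sorted and
#' non-overlapping. All coordinates are 0-based half-open on ingest/egress
#' (BED convention) and 1-based closed inside `GRanges`, converted at the
#' file boundary.
#'
#' @slot regions A named [GenomicRanges::GRangesList], one element per label.
#' @export
setClass("RegionSet", representation(regions = "GRangesList"))

setValidity("RegionSet", function(object) {
  grl <- object@regions
  nms <- names(grl)
  if (length(grl) > 0L && (is.null(nms) || anyDuplicated(nms) || any(!nzchar(nms))))
    return("region labels must be unique non-empty names")
  for (i in seq_along(grl)) {
    gr <- grl[[i]]
    if (length(gr) > 1L) {
      if (GenomicRanges::isDisjoint(gr, ignore.strand = TRUE) == FALSE)
        return(sprintf("intervals overlap within label '%s'", nms[i]))
      o <- order(as.integer(seqnames(gr)), start(gr))
      if (!identical(o, seq_along(gr)))
        return(sprintf("intervals not sorted by (chrom, start) in label '%s'", nms[i]))
    }
  }
  TRUE
})

#' Construct a RegionSet
#'
#' @param ... Named `GRanges` objects (one per label), or a single named
#'   `GRangesList`.
#' @return A [RegionSet-class] object. Each element is sorted on construction.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 100), width = 10))
#' rs <- RegionSet(cpg_islands = gr)
#' regionLabels(rs)
#' @export
RegionSet <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is(args[[1L]], "GRangesList")) {
    grl <- args[[1L]]
  } else {
    grl <- GRangesList(lapply(args, function(gr) {
      GenomicRanges::sort(gr, ignore.strand = TRUE)
    }))
  }
  new("RegionSet", regions = grl)
}

#' @describeIn RegionSet Labels present in the set.
#' @param x A `RegionSet`.
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname RegionSet
#' @export
setMethod("regionLabels", "RegionSet", function(x) names(x@regions))

#' Extract the intervals of one label
#'
#' @param x A [RegionSet-class].
#' @param label Label to extract.
#' @return A `GRanges`.
#' @export
setGeneric("regions", function(x, label) standardGeneric("regions"))

#' @rdname regions
#' @export
setMethod("regions", "RegionSet", function(x, label) {
  if (!label %in% names(x@regions))
    stop("no region label '", label, "' in RegionSet", call. = FALSE)
  x@regions[[label]]
})

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet with", length(object@regions), "labels\n")
  for (nm in names(object@regions))
    cat(sprintf("  %-22s %6d intervals, %9.0f bp\n", nm,
                length(object@regions[[nm]]),
                sum(width(object@regions[[nm]]))))
})

#' MappabilityTrack: per-interval mappability scores
#'
#' Scores in \[0, 1\] over non-overlapping intervals (bedGraph semantics).
#' Expected coverage of a region is its share of the genome-wide mappability
#' mass (the sum of score x width).
#'
#' @slot track A `GRanges` with a numeric `score` metadata column.
#' @export
setClass("MappabilityTrack", representation(track = "GRanges"))

setValidity("MappabilityTrack", function(object) {
  gr <- object@track
  if (!"score" %in% names(mcols(gr))) return("track needs a 'score' column")
  s <- mcols(gr)$score
  if (any(is.na(s)) || any(s < 0) || any(s > 1))
    return("mappability scores must lie in [0, 1]")
  if (length(gr) > 1L && !GenomicRanges::isDisjoint(gr, ignore.strand = TRUE))
    return("mappability intervals must not overlap")
  TRUE
})

#' Construct a MappabilityTrack
#' @param gr `GRanges` with a `score` column in \[0,1\].
#' @return A [MappabilityTrack-class].
#' @export
MappabilityTrack <- function(gr) {
  new("MappabilityTrack", track = GenomicRanges::sort(gr, ignore.strand = TRUE))
}

#' @describeIn MappabilityTrack Underlying scored intervals.
#' @param x A `MappabilityTrack`.
#' @export
setGeneric("mappability", function(x) standardGeneric("mappability"))

#' @rdname MappabilityTrack
#' @export
setMethod("mappability", "MappabilityTrack", function(x) x@track)

setMethod("show", "MappabilityTrack", function(object) {
  cat(sprintf("MappabilityTrack: %d intervals, %.0f scored bases, mass %.1f\n",
              length(object@track), sum(width(object@track)),
              sum(width(object@track) * mcols(object@track)$score)))
})

#' FragmentSet: aligned read fragments
#'
#' One row per read fragment (reads 1 and 2 of a pair are separate entities).
#' Positions are 0-based leftmost mapped base; `width` is the aligned span;
#' `reverse` marks reads stored reverse-complemented relative to sequencing
#' direction; `bs_strand` is the bisulfite strand (OT/OB for directional
#' libraries, CTOT/CTOB for PBAT); `isize` is the template length, recorded
#' positively on both mates; `seq`/`qual` are the aligned bases (reference
#' forward orientation) and Phred qualities.
#'
#' @slot reads A `data.frame`/`data.table` with columns `pair_id`, `read`,
#'   `chrom`, `pos`, `width`, `reverse`, `mapq`, `mapped`, `dup`, `isize`,
#'   `bs_strand`, `seq`, `qual`.
#' @slot seqinfo A [GenomeInfoDb::Seqinfo] for the reference.
#' @slot manifest Run manifest (simulation parameters and seed), possibly
#'   empty for fragments read from file.
#' @export
setClass("FragmentSet",
         representation(reads = "data.frame", seqinfo = "Seqinfo",
                        manifest = "list"))

.FRAG_COLS <- c("pair_id", "read", "chrom", "pos", "width", "reverse",
                "mapq", "mapped", "dup", "isize", "bs_strand", "seq", "qual")

setValidity("FragmentSet", function(object) {
  rd <- object@reads
  miss <- setdiff(.FRAG_COLS, names(rd))
  if (length(miss)) return(paste("missing read columns:", paste(miss, collapse = ", ")))
  if (nrow(rd)) {
    if (!all(rd$read %in% c(1L, 2L))) return("read must be 1 or 2")
    ok <- !rd$mapped | rd$mapq >= 0L
    if (!all(ok)) return("mapped reads need mapq >= 0")
    if (!all(rd$bs_strand %in% c("OT", "OB", "CTOT", "CTOB", "*")))
      return("bs_strand must be OT/OB/CTOT/CTOB (or '*')")
  }
  TRUE
})

#' Construct a FragmentSet
#' @param reads data.frame of read records (see [FragmentSet-class]).
#' @param seqinfo A `Seqinfo` describing the reference contigs.
#' @param manifest Optional run manifest list.
#' @return A [FragmentSet-class].
#' @export
FragmentSet <- function(reads, seqinfo = Seqinfo(), manifest = list()) {
  new("FragmentSet", reads = as.data.table(reads), seqinfo = seqinfo,
      manifest = manifest)
}

#' Run manifest of a FragmentSet
#'
#' Parameters and seed recorded by [simulateFragments()]; empty for
#' fragments read from file.
#' @param x A [FragmentSet-class].
#' @export
setGeneric("runManifest", function(x) standardGeneric("runManifest"))

#' @rdname runManifest
#' @export
setMethod("runManifest", "FragmentSet", function(x) x@manifest)

#' @describeIn FragmentSet Read table (copy) as a `data.table`.
#' @param x A `FragmentSet`.
#' @export
setGeneric("fragmentReads", function(x) standardGeneric("fragmentReads"))

#' @rdname FragmentSet
#' @export
setMethod("fragmentReads", "FragmentSet", function(x) data.table::copy(as.data.table(x@reads)))

#' @rdname FragmentSet
#' @export
setMethod("length", "FragmentSet", function(x) nrow(x@reads))

#' Number of read pairs (templates) in a FragmentSet
#' @param x A [FragmentSet-class].
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' @rdname nPairs
#' @export
setMethod("nPairs", "FragmentSet", function(x) length(unique(x@reads$pair_id)))

#' @describeIn FragmentSet Reference contig description.
#' @export
setMethod("seqinfo", "FragmentSet", function(x) x@seqinfo)

setMethod("show", "FragmentSet", function(object) {
  rd <- object@reads
  cat(sprintf("FragmentSet: %d read fragments (%d pairs) on %d contigs\n",
              nrow(rd), length(unique(rd$pair_id)),
              length(seqlevels(object@seqinfo))))
  if (nrow(rd))
    cat(sprintf("  mapped %.1f%% | mapq>=40 %.1f%% | duplicate-flagged %.1f%%\n",
                100 * mean(rd$mapped),
                100 * mean(rd$mapped & rd$mapq >= 40L),
                100 * mean(rd$dup)))
})

#' MethylSiteSet: per-cytosine methylation records
#'
#' One record per cytosine site: genomic position (strand `+` for cytosines
#' on the top/Watson strand, `-` for the bottom/Crick strand; `*` after
#' CpG strand merging), dinucleotide context (CpG/CpA/CpC/CpT, read 3' of the
#' cytosine on its own strand), the retained-cytosine count `M`, the
#' converted count `U`, and `beta = M / (M + U)`. Sites with zero coverage
#' are never stored.
#'
#' @slot sites A `GRanges` with metadata columns `context`, `M`, `U`.
#' @export
setClass("MethylSiteSet", representation(sites = "GRanges"))

setValidity("MethylSiteSet", function(object) {
  mc <- mcols(object@sites)
  need <- c("context", "M", "U")
  if (!all(need %in% names(mc))) return("sites need context, M, U columns")
  if (length(object@sites)) {
    if (any(mc$M < 0L) || any(mc$U < 0L)) return("M and U must be non-negative")
    if (any(mc$M + mc$U <= 0L)) return("sites with zero coverage must be absent")
    if (!all(mc$context %in% c("CpG", "CpA", "CpC", "CpT")))
      return("context must be one of CpG/CpA/CpC/CpT")
  }
  TRUE
})

#' Construct a MethylSiteSet
#' @param sites `GRanges` with `context`, `M`, `U` metadata columns.
#' @return A [MethylSiteSet-class].
#' @export
MethylSiteSet <- function(sites) new("MethylSiteSet", sites = sites)

#' @describeIn MethylSiteSet The site records as a `GRanges`.
#' @param x A `MethylSiteSet`.
#' @export
setGeneric("siteRecords", function(x) standardGeneric("siteRecords"))

#' @rdname MethylSiteSet
#' @export
setMethod("siteRecords", "MethylSiteSet", function(x) x@sites)

#' Per-site methylation beta values
#' @param x A [MethylSiteSet-class].
#' @return Numeric vector `M / (M + U)` parallel to the site records.
#' @export
setGeneric("beta", function(x) standardGeneric("beta"))

#' @rdname beta
#' @export
setMethod("beta", "MethylSiteSet", function(x) {
  mc <- mcols(x@sites)
  as.numeric(mc$M) / (as.numeric(mc$M) + as.numeric(mc$U))
})

#' @rdname MethylSiteSet
#' @export
setMethod("length", "MethylSiteSet", function(x) length(x@sites))

setMethod("show", "MethylSiteSet", function(object) {
  mc <- mcols(object@sites)
  cat(sprintf("MethylSiteSet: %d sites\n", length(object@sites)))
  if (length(object@sites)) {
    tab <- table(mc$context)
    cat("  contexts:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
    cat(sprintf("  total M=%d U=%d, mean beta %.4f\n",
                sum(mc$M), sum(mc$U), mean(mc$M / (mc$M + mc$U))))
  }
})

#' Subset a MethylSiteSet by overlap with regions
#' @param x A [MethylSiteSet-class].
#' @param region A `GRanges` of intervals.
#' @return The subset `MethylSiteSet` of sites overlapping `region`.
#' @export
setGeneric("subsetBySites", function(x, region) standardGeneric("subsetBySites"))

#' @rdname subsetBySites
#' @export
setMethod("subsetBySites", "MethylSiteSet", function(x, region) {
  MethylSiteSet(subsetByOverlaps(x@sites, region, ignore.strand = TRUE))
})

#' ProtocolProfile: simulator ground truth for one library protocol
#'
#' Captures the protocol-specific artifacts the simulator plants:
#' strand convention (directional = OT/OB, pbat = CTOT/CTOB), insert-size
#' law (log-normal, truncated to \[35, 1000\] bp), PCR duplication rate,
#' incomplete conversion (unmethylated C read as C) and over-conversion
#' (methylated C read as T), multiplicative CpG-island sampling bias,
#' a per-read-position multiplier on the conversion-failure rate (M-bias),
#' the Adaptase-style low-complexity tail length on read 2, per-mate base
#' quality parameters, a substitution error rate on non-cytosine bases,
#' and the fractions of unmapped / sub-optimally mapped reads.
#'
#' @export
setClass("ProtocolProfile", representation(
  name = "character", strand_convention = "character",
  insert_mean = "numeric", insert_sd = "numeric",
  duplication_rate = "numeric", conversion_failure = "numeric",
  overconversion = "numeric", cgi_bias = "numeric",
  mbias_curve = "numeric", r2_tail_clip = "integer",
  qual_mean = "numeric", qual_sd = "numeric",
  error_rate = "numeric", frac_unmapped = "numeric",
  frac_suboptimal = "numeric"))

setValidity("ProtocolProfile", function(object) {
  pr <- c(duplication = object@duplication_rate,
          conv_fail = object@conversion_failure,
          overconv = object@overconversion,
          err = object@error_rate,
          unmapped = object@frac_unmapped,
          subopt = object@frac_suboptimal)
  if (any(pr < 0) || any(pr > 1))
    return("all rate/probability parameters must lie in [0, 1]")
  if (!object@strand_convention %in% c("directional", "pbat"))
    return("strand_convention must be 'directional' or 'pbat'")
  if (object@insert_mean <= 0 || object@insert_sd <= 0)
    return("insert_mean and insert_sd must be positive")
  if (object@cgi_bias < 0) return("cgi_bias must be non-negative")
  if (any(object@mbias_curve < 0)) return("mbias_curve multipliers must be >= 0")
  if (object@r2_tail_clip < 0L) return("r2_tail_clip must be >= 0")
  if (length(object@qual_mean) != 2L) return("qual_mean needs one value per mate")
  TRUE
})

#' Construct a ProtocolProfile
#'
#' @param name Label for the profile.
#' @param strand_convention `"directional"` (OT/OB) or `"pbat"` (CTOT/CTOB).
#' @param insert_mean,insert_sd Insert-size mean and sd in bp (log-normal law,
#'   truncated to \[35, 1000\] bp and to at least half the read length).
#' @param duplication_rate Probability a sequenced pair is a re-emission of an
#'   earlier pair (PCR duplicate).
#' @param conversion_failure Probability an unmethylated cytosine is read as C.
#' @param overconversion Probability a methylated cytosine is read as T.
#' @param cgi_bias Multiplicative sampling weight for fragment starts inside
#'   CpG islands (>1 over-covers islands, <1 under-covers).
#' @param mbias_curve Per-read-position multipliers applied to
#'   `conversion_failure` (recycled/truncated to the read length; default flat).
#' @param r2_tail_clip Length in bp of the low-complexity Adaptase-style tail
#'   planted at the start of read 2 (0 disables).
#' @param qual_mean,qual_sd Mean Phred quality per mate (length 2) and sd.
#' @param error_rate Substitution rate on non-cytosine bases.
#' @param frac_unmapped,frac_suboptimal Fractions of reads emitted unmapped,
#'   or mapped with MAPQ < 40.
#' @return A [ProtocolProfile-class].
#' @examples
#' protocolProfile("neb-like", insert_mean = 290, duplication_rate = 0.10)
#' @export
protocolProfile <- function(name = "custom",
                            strand_convention = c("directional", "pbat"),
                            insert_mean = 290, insert_sd = 60,
                            duplication_rate = 0.10,
                            conversion_failure = 0.005,
                            overconversion = 0.01,
                            cgi_bias = 1.0,
                            mbias_curve = 1.0,
                            r2_tail_clip = 0L,
                            qual_mean = c(36, 34), qual_sd = 4,
                            error_rate = 0.001,
                            frac_unmapped = 0.02,
                            frac_suboptimal = 0.05) {
  strand_convention <- match.arg(strand_convention)
  new("ProtocolProfile", name = name, strand_convention = strand_convention,
      insert_mean = insert_mean, insert_sd = insert_sd,
      duplication_rate = duplication_rate,
      conversion_failure = conversion_failure, overconversion = overconversion,
      cgi_bias = cgi_bias, mbias_curve = as.numeric(mbias_curve),
      r2_tail_clip = as.integer(r2_tail_clip),
      qual_mean = qual_mean, qual_sd = qual_sd, error_rate = error_rate,
      frac_unmapped = frac_unmapped, frac_suboptimal = frac_suboptimal)
}

#' Preset protocol profiles
#'
#' Profiles shaped after the four benchmarked library protocols: a
#' Kapa-like WGBS kit (short inserts, high duplication, island
#' under-coverage), a NEB-like enzymatic kit (long inserts, low duplication,
#' near-uniform island coverage, low conversion failure), a PBAT-like
#' protocol (no PCR duplication, CTOT/CTOB strands, island over-coverage),
#' and a Swift-like kit (Adaptase tail on read 2). Magnitudes for the
#' island bias are free parameters chosen for direction, not fitted values.
#'
#' @param name One of `"kapa"`, `"neb"`, `"pbat"`, `"swift"`.
#' @param ... Overrides passed to [protocolProfile()].
#' @return A [ProtocolProfile-class].
#' @export
protocolPreset <- function(name = c("kapa", "neb", "pbat", "swift"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    kapa  = list(strand_convention = "directional", insert_mean = 210,
                 insert_sd = 55, duplication_rate = 0.25,
                 conversion_failure = 0.008, cgi_bias = 0.6),
    neb   = list(strand_convention = "directional", insert_mean = 290,
                 insert_sd = 60, duplication_rate = 0.10,
                 conversion_failure = 0.004, cgi_bias = 0.95),
    pbat  = list(strand_convention = "pbat", insert_mean = 300,
                 insert_sd = 70, duplication_rate = 0.0,
                 conversion_failure = 0.006, cgi_bias = 1.8,
                 frac_unmapped = 0.05, frac_suboptimal = 0.12),
    swift = list(strand_convention = "directional", insert_mean = 220,
                 insert_sd = 55, duplication_rate = 0.12,
                 conversion_failure = 0.004, cgi_bias = 0.85,
                 r2_tail_clip = 14L))
  args <- utils::modifyList(c(list(name = name), base), list(...))
  do.call(protocolProfile, args)
}

setMethod("show", "ProtocolProfile", function(object) {
  cat(sprintf("ProtocolProfile '%s' (%s)\n", object@name, object@strand_convention))
  cat(sprintf("  insert %s+-%s bp | dup %.3f | conv_fail %.4f | overconv %.4f\n",
              format(object@insert_mean), format(object@insert_sd),
              object@duplication_rate, object@conversion_failure,
              object@overconversion))
  cat(sprintf("  cgi_bias %.2f | r2_tail_clip %d bp | error %.4f\n",
              object@cgi_bias, object@r2_tail_clip, object@error_rate))
})

#' SyntheticGenome: reference, annotations and mappability for simulation
#'
#' Holds the synthetic reference sequences (main contigs with planted GC-rich
#' CpG islands, an unmethylated lambda-like spike-in, a methylated pUC19-like
#' spike-in, and an unmethylated circular mitochondria-like contig), the
#' derived [RegionSet-class] (including the genome-wide CpG site census) and
#' a [MappabilityTrack-class].
#'
#' @slot sequences A `DNAStringSet` of all contigs.
#' @slot regions A [RegionSet-class] over the contigs.
#' @slot mappability A [MappabilityTrack-class].
#' @slot seqinfo `Seqinfo` (circularity flagged for the mito-like contig).
#' @slot params The generator parameters (list), including the seed.
#' @export
setClass("SyntheticGenome", representation(
  sequences = "DNAStringSet", regions = "RegionSet",
  mappability = "MappabilityTrack", seqinfo = "Seqinfo", params = "list"))

#' @describeIn SyntheticGenome Contig sequences.
#' @param x A `SyntheticGenome`.
#' @export
setGeneric("genomeSequences", function(x) standardGeneric("genomeSequences"))

#' @rdname SyntheticGenome
#' @export
setMethod("genomeSequences", "SyntheticGenome", function(x) x@sequences)

#' @describeIn SyntheticGenome Region annotations.
#' @export
setGeneric("genomeRegions", function(x) standardGeneric("genomeRegions"))

#' @rdname SyntheticGenome
#' @export
setMethod("genomeRegions", "SyntheticGenome", function(x) x@regions)

#' @describeIn SyntheticGenome Mappability track.
#' @export
setGeneric("genomeMappability", function(x) standardGeneric("genomeMappability"))

#' @rdname SyntheticGenome
#' @export
setMethod("genomeMappability", "SyntheticGenome", function(x) x@mappability)

#' @describeIn SyntheticGenome Contig description (circularity flagged).
#' @export
setMethod("seqinfo", "SyntheticGenome", function(x) x@seqinfo)

setMethod("show", "SyntheticGenome", function(object) {
  cat(sprintf("SyntheticGenome: %d contigs, %.0f bp total\n",
              length(object@sequences), sum(width(object@sequences))))
  show(object@regions)
})

#' MethylationTruth: simulator ground-truth methylation levels
#'
#' Per-cytosine methylation probability for every strand-resolved cytosine in
#' a [SyntheticGenome-class]. Spike-in and mitochondria-like contigs are
#' pinned to exactly 0 (unmethylated lambda-like, mito-like) or 1
#' (methylated pUC19-like). The manifest records the drawing distribution
#' and seed.
#'
#' @slot sites `GRanges` (strand `+`/`-`) with `context` and `level` columns.
#' @slot manifest List of generator parameters (distribution, seed).
#' @export
setClass("MethylationTruth",
         representation(sites = "GRanges", manifest = "list"))

setValidity("MethylationTruth", function(object) {
  lv <- mcols(object@sites)$level
  if (is.null(lv)) return("truth sites need a 'level' column")
  if (any(lv < 0) || any(lv > 1)) return("truth levels must lie in [0, 1]")
  TRUE
})

#' @describeIn MethylationTruth Truth site records.
#' @param x A `MethylationTruth`.
#' @export
setGeneric("truthSites", function(x) standardGeneric("truthSites"))

#' @rdname MethylationTruth
#' @export
setMethod("truthSites", "MethylationTruth", function(x) x@sites)

setMethod("show", "MethylationTruth", function(object) {
  cat(sprintf("MethylationTruth: %d cytosine sites, mean level %.3f\n",
              length(object@sites), mean(mcols(object@sites)$level)))
})
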