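## Internal helpers shared across modules.

.BASE_C <- as.integer(charToRaw("C"))
.BASE_G <- as.integer(charToRaw("G"))
.BASE_A <- as.integer(charToRaw("A"))
.BASE_T <- as.integer(charToRaw("T"))

## context of a cytosine = base read 3' of it on its own strand;
## CpG/CpA/CpC/CpT keyed by that base.
.CTX_FROM_BASE <- c(G = "CpG", A = "CpA", C = "CpC", T = "CpT")

.check_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is required for reproducibility", call. = FALSE)
  as.integer(seed)
}

## Strand-resolved cytosine census over a DNAStringSet.
## Returns GRanges (1-based, width 1) with strand '+' for top-strand C,
## '-' for bottom-strand C (a 'G' in the top-strand reference), and a
## 'context' column. Cytosines whose 3'-neighbour is off-contig or not
## A/C/G/T are excluded.
cytosineSites <- function(seqs) {
  stopifnot(is(seqs, "DNAStringSet"))
  out <- vector("list", length(seqs))
  lv <- names(seqs)
  for (i in seq_along(seqs)) {
    b <- as.integer(charToRaw(as.character(seqs[[i]])))
    n <- length(b)
    ## top strand: C at p, context base b[p+1]
    p_top <- which(b == .BASE_C)
    p_top <- p_top[p_top < n]
    nb_top <- b[p_top + 1L]
    ctx_top <- character(length(p_top))
    ctx_top[nb_top == .BASE_G] <- "CpG"
    ctx_top[nb_top == .BASE_A] <- "CpA"
    ctx_top[nb_top == .BASE_C] <- "CpC"
    ctx_top[nb_top == .BASE_T] <- "CpT"
    keep_t <- nzchar(ctx_top)
    ## bottom strand: C where top has G at p; 3' neighbour on bottom is the
    ## complement of top's base at p-1
    p_bot <- which(b == .BASE_G)
    p_bot <- p_bot[p_bot > 1L]
    nb_bot <- b[p_bot - 1L]
    ctx_bot <- character(length(p_bot))
    ctx_bot[nb_bot == .BASE_C] <- "CpG"
    ctx_bot[nb_bot == .BASE_T] <- "CpA"
    ctx_bot[nb_bot == .BASE_G] <- "CpC"
    ctx_bot[nb_bot == .BASE_A] <- "CpT"
    keep_b <- nzchar(ctx_bot)
    out[[i]] <- data.table(
      chrom = lv[i],
      pos = c(p_top[keep_t], p_bot[keep_b]),
      strand = c(rep("+", sum(keep_t)), rep("-", sum(keep_b))),
      context = c(ctx_top[keep_t], ctx_bot[keep_b]))
  }
  dt <- rbindlist(out)
  gr <- GRanges(factor(dt$chrom, levels = lv), IRanges(dt$pos, width = 1L),
                strand = dt$strand, context = dt$context,
                seqlengths = setNames(width(seqs), lv))
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

## Merged (palindromic) CpG dinucleotide census: width-2 ranges anchored at
## the top-strand C of each CG.
cpgCensus <- function(seqs) {
  hits <- vmatchPattern("CG", seqs)
  lv <- names(seqs)
  chrom <- rep(lv, S4Vectors::elementNROWS(hits))
  ir <- unlist(IRanges::IRangesList(hits), use.names = FALSE)
  gr <- GRanges(factor(chrom, levels = lv), ir,
                seqlengths = setNames(width(seqs), lv))
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

## Phred string <-> integer vector (offset 33)
phredToInt <- function(qual) {
  if (!length(qual)) return(integer(0))
  as.integer(charToRaw(paste(qual, collapse = ""))) - 33L
}

intToPhred <- function(q, widths) {
  big <- rawToChar(as.raw(pmin(pmax(q, 0L), 60L) + 33L))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  substring(big, starts, ends)
}

## byte vector of a character vector of sequences, concatenated
seqBytes <- function(s) {
  if (!length(s)) return(integer(0))
  as.integer(charToRaw(paste(s, collapse = "")))
}

## Sum of mappability mass (score x width) over an optional region restriction.
.mapMass <- function(track, region = NULL) {
  gr <- mappability(track)
  if (is.null(region)) return(sum(width(gr) * mcols(gr)$score))
  hits <- findOverlaps(gr, region, ignore.strand = TRUE)
  if (!length(hits)) return(0)
  pi_ <- pintersect(gr[S4Vectors::queryHits(hits)],
                    region[S4Vectors::subjectHits(hits)], ignore.strand = TRUE)
  sum(width(pi_) * mcols(gr)$score[S4Vectors::queryHits(hits)])
}
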