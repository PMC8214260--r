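## Plain-text SAM dialect reader/writer for FragmentSet objects.
##
## Standard SAM columns and FLAG bits (0x1 paired, 0x4 unmapped, 0x10
## reverse, 0x40/0x80 first/second in pair, 0x400 duplicate); the bisulfite
## strand travels in a ZB:Z tag. CIGARs are simple <width>M matches, SEQ is
## stored in reference-forward orientation as SAM requires.

#' Write a FragmentSet as SAM text
#'
#' @param frags A [FragmentSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSam <- function(frags, path) {
  rd <- fragmentReads(frags)
  si <- seqinfo(frags)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", seqlevels(si),
                   unname(seqlengths(si))))
  setorder(rd, pair_id, read)
  mate <- rd[, .(pair_id, read = 3L - read, mate_mapped = mapped,
                 mate_pos = pos, mate_chrom = chrom, mate_reverse = reverse)]
  rd <- merge(rd, mate, by = c("pair_id", "read"), sort = TRUE)
  flag <- 1L +                                     # paired
    fifelse(rd$mapped, 0L, 4L) +
    fifelse(rd$mate_mapped, 0L, 8L) +
    fifelse(rd$reverse, 16L, 0L) +
    fifelse(rd$mate_reverse, 32L, 0L) +
    fifelse(rd$read == 1L, 64L, 128L) +
    fifelse(rd$dup, 1024L, 0L)
  ## template length kept (signed) even on unmapped records so the set
  ## round-trips; sign follows the leftmost-mate convention where defined
  tlen <- fifelse(rd$mapped & rd$mate_mapped,
                  fifelse(rd$pos <= rd$mate_pos, rd$isize, -rd$isize),
                  fifelse(rd$read == 1L, rd$isize, -rd$isize))
  rec <- paste(paste0("frag", rd$pair_id), flag,
               fifelse(rd$mapped, rd$chrom, "*"),
               fifelse(rd$mapped, rd$pos + 1L, 0L),
               fifelse(rd$mapped, rd$mapq, 0L),
               fifelse(rd$mapped, paste0(rd$width, "M"), "*"),
               fifelse(rd$mate_mapped, "=", "*"),
               fifelse(rd$mate_mapped, rd$mate_pos + 1L, 0L),
               tlen, rd$seq, rd$qual,
               paste0("ZB:Z:", rd$bs_strand),
               sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a SAM text file into a FragmentSet
#'
#' Accepts the dialect written by [writeSam()]: paired records with simple
#' match CIGARs and a ZB:Z bisulfite-strand tag. A record referencing a
#' contig without an @SQ header line is an error.
#'
#' @param path Path to the SAM file.
#' @return A [FragmentSet-class]; round-trips losslessly with [writeSam()].
#' @export
readSam <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "@")
  sq <- lines[startsWith(lines, "@SQ")]
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  si <- Seqinfo(sn, ln)
  rec <- lines[!is_hdr]
  if (!length(rec))
    return(FragmentSet(data.table(pair_id = integer(0), read = integer(0),
                                  chrom = character(0), pos = integer(0),
                                  width = integer(0), reverse = logical(0),
                                  mapq = integer(0), mapped = logical(0),
                                  dup = logical(0), isize = integer(0),
                                  bs_strand = character(0),
                                  seq = character(0), qual = character(0)),
                       si))
  f <- data.table::tstrsplit(rec, "\t", fixed = TRUE)
  flag <- as.integer(f[[2]])
  mapped <- bitwAnd(flag, 4L) == 0L
  chrom <- f[[3]]
  bad <- mapped & !chrom %in% sn
  if (any(bad))
    stop("record references contig without @SQ header: ",
         chrom[which(bad)[1L]], call. = FALSE)
  zb <- rep("*", length(rec))
  for (i in 12:length(f)) {
    hit <- !is.na(f[[i]]) & startsWith(f[[i]], "ZB:Z:")
    zb[hit] <- substring(f[[i]][hit], 6L)
  }
  rd <- data.table(
    pair_id = as.integer(sub("^frag", "", f[[1]])),
    read = fifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L),
    chrom = fifelse(mapped, chrom, NA_character_),
    pos = fifelse(mapped, as.integer(f[[4]]) - 1L, NA_integer_),
    width = nchar(f[[10]]),
    reverse = bitwAnd(flag, 16L) > 0L,
    mapq = fifelse(mapped, as.integer(f[[5]]), NA_integer_),
    mapped = mapped,
    dup = bitwAnd(flag, 1024L) > 0L,
    isize = abs(as.integer(f[[9]])),
    bs_strand = zb,
    seq = f[[10]],
    qual = f[[11]])
  FragmentSet(rd, si)
}
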