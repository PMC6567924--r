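# Paired-end alignment I/O. The in-memory representation of aligned pairs is
# a plain data.frame with one row per pair:
#   qname, chrom, strand ("+"/"-", read one), read1_5prime (0-based 5' base of
#   read one), mate_5prime (0-based 5' base of read two, the tagmentation
#   end; NA for single-end input), mapq, secondary, supplementary, duplicate,
#   clip5 (TRUE when read one's 5' end is soft-clipped, making its ligation
#   origin ambiguous).
# Read one is the ligation-derived read; read two the tagmentation-derived.

# Reference-consumed width of a CIGAR (M/D/N/=/X ops).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1L]]
    tok <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
    n <- as.integer(sub("[A-Z=]$", "", tok))
    op <- sub("^\\d+", "", tok)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# Is the 5' end of the read soft-clipped? (leading S for +, trailing S for -)
cigar_clip5 <- function(cigar, strand) {
  lead <- grepl("^\\d+S", cigar)
  trail <- grepl("\\d+S$", cigar)
  ifelse(strand == "+", lead, trail)
}

#' Read aligned pairs from SAM/BAM
#'
#' Loads primary paired-end alignments and pairs mates by name, returning one
#' row per pair in the aligned-pair data.frame layout used by
#' \code{\link{classify_reads}}. Read one's biological 5' origin is the
#' leftmost aligned base on the forward strand and the rightmost on the
#' reverse strand (computed from the CIGAR reference width); the same rule
#' gives the mate's tagmentation end. SAM input is converted on the fly with
#' \code{Rsamtools::asBam}.
#'
#' @param file Path to a BAM or SAM file (coordinate- or name-sorted; no
#'   order is assumed).
#' @return A data.frame of aligned pairs. Pairs whose first read is unmapped
#'   are dropped; a missing/unmapped mate yields \code{mate_5prime = NA}
#'   (tagmentation statistics are then unavailable, counting still works).
#' @export
read_alignment_pairs <- function(file) {
  if (!file.exists(file)) stop("alignment file not found: ", file)
  bam <- file
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  what <- c("qname", "flag", "rname", "strand", "pos", "cigar", "mapq")
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1L]]
  if (!length(res$qname)) {
    return(empty_pair_frame())
  }
  flag <- res$flag
  df <- data.frame(
    qname = res$qname,
    chrom = as.character(res$rname),
    strand = as.character(res$strand),
    pos = res$pos - 1L, # to 0-based leftmost
    cigar = res$cigar,
    mapq = res$mapq,
    first = bitwAnd(flag, 64L) > 0L,
    unmapped = bitwAnd(flag, 4L) > 0L,
    secondary = bitwAnd(flag, 256L) > 0L,
    supplementary = bitwAnd(flag, 2048L) > 0L,
    duplicate = bitwAnd(flag, 1024L) > 0L,
    stringsAsFactors = FALSE
  )
  df$five_prime <- ifelse(df$strand == "-",
                          df$pos + cigar_ref_width(df$cigar) - 1L,
                          df$pos)
  r1 <- df[df$first & !df$unmapped & !df$secondary & !df$supplementary, ]
  r2 <- df[!df$first & !df$unmapped & !df$secondary & !df$supplementary, ]
  m <- match(r1$qname, r2$qname)
  out <- data.frame(
    qname = r1$qname,
    chrom = r1$chrom,
    strand = r1$strand,
    read1_5prime = r1$five_prime,
    mate_5prime = r2$five_prime[m],
    mapq = r1$mapq,
    secondary = FALSE,
    supplementary = FALSE,
    duplicate = r1$duplicate,
    clip5 = cigar_clip5(r1$cigar, r1$strand),
    stringsAsFactors = FALSE
  )
  # secondary/supplementary read-one records are kept as rows so the filter
  # can count them as rejections rather than silently dropping them
  rs <- df[df$first & !df$unmapped & (df$secondary | df$supplementary), ]
  if (nrow(rs)) {
    out <- rbind(out, data.frame(
      qname = rs$qname, chrom = rs$chrom, strand = rs$strand,
      read1_5prime = rs$five_prime, mate_5prime = NA_integer_,
      mapq = rs$mapq, secondary = rs$secondary,
      supplementary = rs$supplementary, duplicate = rs$duplicate,
      clip5 = cigar_clip5(rs$cigar, rs$strand), stringsAsFactors = FALSE
    ))
  }
  rownames(out) <- NULL
  out
}

empty_pair_frame <- function() {
  data.frame(
    qname = character(0), chrom = character(0), strand = character(0),
    read1_5prime = integer(0), mate_5prime = integer(0), mapq = integer(0),
    secondary = logical(0), supplementary = logical(0),
    duplicate = logical(0), clip5 = logical(0), stringsAsFactors = FALSE
  )
}

#' Write simulated read pairs as SAM
#'
#' Emits a valid headered SAM file (two lines per pair, fixed-length
#' \code{<read_length>M} alignments, sequence field omitted as \code{*}) from
#' the aligned-pair data.frame produced by \code{\link{generate_reads}}. The
#' output round-trips through \code{\link{read_alignment_pairs}}.
#'
#' @param pairs Aligned-pair data.frame (needs \code{qname}, \code{chrom},
#'   \code{strand}, \code{read1_5prime}, \code{mate_5prime}, \code{mapq}).
#' @param chrom_lengths Named integer vector for the \code{@SQ} header lines.
#' @param path Output path.
#' @param read_length Reported aligned length of each read in bp. Must not
#'   exceed the simulator's minimum fragment length or mates could overhang
#'   chromosome ends.
#' @return \code{path}, invisibly.
#' @export
write_sam <- function(pairs, chrom_lengths, path, read_length = 50L) {
  if (is.null(names(chrom_lengths))) stop("`chrom_lengths` must be named")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                     as.integer(chrom_lengths)), con)
  if (!nrow(pairs)) return(invisible(path))
  w <- as.integer(read_length)
  fwd1 <- pairs$strand == "+"
  # leftmost (0-based) of each mate; read two faces the opposite way
  left1 <- ifelse(fwd1, pairs$read1_5prime, pairs$read1_5prime - w + 1L)
  left2 <- ifelse(fwd1, pairs$mate_5prime - w + 1L, pairs$mate_5prime)
  flag1 <- 1L + 2L + 64L + ifelse(fwd1, 32L, 16L)
  flag2 <- 1L + 2L + 128L + ifelse(fwd1, 16L, 32L)
  tlen <- ifelse(fwd1,
                 (left2 + w) - left1,
                 -((left1 + w) - left2))
  cg <- sprintf("%dM", w)
  l1 <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*",
                pairs$qname, flag1, pairs$chrom, left1 + 1L, pairs$mapq, cg,
                left2 + 1L, tlen)
  l2 <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t=\t%d\t%d\t*\t*",
                pairs$qname, flag2, pairs$chrom, left2 + 1L, pairs$mapq, cg,
                left1 + 1L, -tlen)
  writeLines(c(rbind(l1, l2)), con)
  invisible(path)
}
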