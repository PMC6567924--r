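# Cut-site read filtering and per-GATC counting. A read pair is kept only if
# read one's 5' origin coincides exactly (or within `slack` bp) with a DpnI
# cut origin; everything else is presumed non-specific ligation onto broken
# DNA ends. Retained reads are summed per GATC, with left- and right-flank
# reads of one site pooled into a single count.

#' Classify aligned pairs against the cut-site convention
#'
#' A pair is accepted iff it is a primary alignment, \code{mapq >= mapq_min},
#' its chromosome is indexed, its read-one 5' end is not soft-clipped (an
#' ambiguous ligation junction) and \code{\link{locate_cut}} matches the 5'
#' origin to a site flank. Rejections carry one of the reasons
#' \code{secondary}, \code{low_mapq}, \code{unknown_chrom},
#' \code{no_cut_site_match} (checked in that order).
#'
#' @param pairs Aligned-pair data.frame (see
#'   \code{\link{read_alignment_pairs}}; the \code{qname}, \code{duplicate}
#'   and \code{clip5} columns are optional).
#' @param index A \code{\link{gatc_index}}.
#' @param mapq_min Minimum mapping quality (default 10; aligners emit up to
#'   60, and a modest threshold suppresses multimappers).
#' @param slack Matching tolerance in bp around the exact cut origin
#'   (default 0, the exact filter; positive values accept origins within
#'   \code{slack} bp of a valid one and assign the nearest site).
#' @return The input with added columns \code{accepted}, \code{reason}
#'   (NA when accepted), \code{site}, \code{flank}.
#' @export
classify_reads <- function(pairs, index, mapq_min = 10, slack = 0) {
  stopifnot(inherits(index, "gatc_index"))
  pairs <- as.data.frame(pairs)
  n <- nrow(pairs)
  if (!all(c("chrom", "strand", "read1_5prime", "mapq") %in% names(pairs)))
    stop("`pairs` needs columns chrom, strand, read1_5prime, mapq")
  if (is.null(pairs$secondary)) pairs$secondary <- rep(FALSE, n)
  if (is.null(pairs$supplementary)) pairs$supplementary <- rep(FALSE, n)
  if (is.null(pairs$clip5)) pairs$clip5 <- rep(FALSE, n)
  if (is.null(pairs$mate_5prime)) pairs$mate_5prime <- rep(NA_integer_, n)
  pairs$strand <- normalize_strand(pairs$strand)

  reason <- rep(NA_character_, n)
  site <- rep(NA_integer_, n)
  flank <- rep(NA_character_, n)

  sec <- pairs$secondary | pairs$supplementary
  lowq <- !sec & pairs$mapq < mapq_min
  unk <- !sec & !lowq & !(pairs$chrom %in% names(index$sites))
  open <- !sec & !lowq & !unk
  reason[sec] <- "secondary"
  reason[lowq] <- "low_mapq"
  reason[unk] <- "unknown_chrom"

  todo <- which(open & !pairs$clip5)
  if (length(todo)) {
    loc <- locate_cut(index, pairs$chrom[todo], pairs$read1_5prime[todo],
                      pairs$strand[todo])
    site[todo] <- loc$site
    flank[todo] <- loc$flank
    if (slack > 0) {
      miss <- todo[is.na(loc$site)]
      if (length(miss)) {
        near <- nearest_origin(index, pairs$chrom[miss],
                               pairs$read1_5prime[miss], pairs$strand[miss],
                               slack)
        site[miss] <- near$site
        flank[miss] <- near$flank
      }
    }
  }
  reason[open & is.na(site)] <- "no_cut_site_match"
  pairs$accepted <- open & !is.na(site)
  pairs$reason <- reason
  pairs$site <- site
  pairs$flank <- flank
  pairs
}

# Nearest valid cut origin within +/- slack bp (used only when slack > 0).
nearest_origin <- function(index, chrom, pos, strand, slack) {
  n <- length(pos)
  site <- rep(NA_integer_, n)
  flank <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    s <- index$sites[[ch]]
    sel <- which(chrom == ch)
    if (!length(s)) next
    cand <- ifelse(strand[sel] == "+", pos[sel] - 2L, pos[sel] - 1L)
    i <- findInterval(cand, s)
    lo <- pmax(i, 1L)
    hi <- pmin(i + 1L, length(s))
    dlo <- abs(cand - s[lo])
    dhi <- abs(cand - s[hi])
    best <- ifelse(dhi < dlo, s[hi], s[lo])
    dist <- pmin(dlo, dhi)
    ok <- dist <= slack
    site[sel[ok]] <- best[ok]
    flank[sel[ok]] <- ifelse(strand[sel][ok] == "+", "right", "left")
  }
  list(site = site, flank = flank)
}

#' Filter aligned pairs to cut-site reads
#'
#' Applies \code{\link{classify_reads}} and splits the result into the
#' accepted cut-site reads and retention statistics. Output order follows
#' input order, so the result is deterministic for a given stream.
#'
#' @inheritParams classify_reads
#' @return A list with \code{reads} (data.frame: \code{chrom}, \code{site},
#'   \code{flank}, \code{tagmentation_pos}, plus \code{qname} if present) and
#'   \code{stats} (list: \code{aligned_pairs}, \code{passing_pairs},
#'   \code{retention}, \code{unique_tagmentation_fraction},
#'   \code{rejections} by reason). An empty stream yields zero counts and
#'   \code{NaN} retention.
#' @export
filter_alignments <- function(pairs, index, mapq_min = 10, slack = 0) {
  cl <- classify_reads(pairs, index, mapq_min = mapq_min, slack = slack)
  acc <- cl[cl$accepted, , drop = FALSE]
  reads <- data.frame(
    chrom = acc$chrom,
    site = acc$site,
    flank = acc$flank,
    tagmentation_pos = acc$mate_5prime,
    stringsAsFactors = FALSE
  )
  if (!is.null(acc$qname)) reads$qname <- acc$qname
  aligned <- nrow(cl)
  passing <- nrow(acc)
  stats <- list(
    aligned_pairs = aligned,
    passing_pairs = passing,
    retention = if (aligned > 0) passing / aligned else NaN,
    unique_tagmentation_fraction =
      if (passing > 0) unique_tagmentation_fraction(reads) else NaN,
    rejections = table(factor(
      cl$reason[!cl$accepted],
      levels = c("secondary", "low_mapq", "unknown_chrom", "no_cut_site_match")
    ))
  )
  list(reads = reads, stats = stats)
}

tuple_key <- function(reads) {
  paste(reads$chrom, reads$site, reads$flank, reads$tagmentation_pos, sep = "\r")
}

#' Fraction of reads with a unique tagmentation end
#'
#' Because the second fragment end is placed by Tn5 at a random position,
#' independent methylation events at one site almost always differ in their
#' (site, flank, tagmentation position) tuple; repeated tuples are PCR
#' duplicates. The fraction of distinct tuples among all reads measures how
#' many reads represent unique in-vivo methylation events.
#'
#' @param reads Cut-site read data.frame (from \code{\link{filter_alignments}}).
#' @return Distinct tuples / total reads; \code{NaN} for empty input. Reads
#'   with an unavailable mate (\code{tagmentation_pos} NA) are excluded with a
#'   warning.
#' @seealso \code{\link{dedup_tagmentation}}
#' @export
unique_tagmentation_fraction <- function(reads) {
  if (!nrow(reads)) return(NaN)
  if (anyNA(reads$tagmentation_pos)) {
    warning("reads without mate coordinates excluded from tagmentation uniqueness")
    reads <- reads[!is.na(reads$tagmentation_pos), , drop = FALSE]
    if (!nrow(reads)) return(NaN)
  }
  length(unique(tuple_key(reads))) / nrow(reads)
}

#' Collapse reads to unique tagmentation tuples
#'
#' Keeps the first read per (site, flank, tagmentation position) tuple.
#'
#' @inheritParams unique_tagmentation_fraction
#' @return Deduplicated read data.frame.
#' @export
dedup_tagmentation <- function(reads) {
  reads[!duplicated(tuple_key(reads)), , drop = FALSE]
}

#' Sum cut-site reads into a per-GATC count track
#'
#' Left- and right-flank reads of one site are pooled: both flanks report the
#' same methylated adenine pair of the palindromic site. Every indexed site
#' gets a count (absent sites are zero), and the total equals the number of
#' contributing reads.
#'
#' @param reads Cut-site read data.frame.
#' @param index The \code{\link{gatc_index}} the reads were classified against.
#' @param dedup_mode \code{"raw"} (default: every read counts, matching the
#'   protocol that sums all cut-site reads and reports uniqueness separately)
#'   or \code{"unique_tagmentation"} (collapse PCR-duplicate tuples first).
#' @param sample Sample identifier stored on the track.
#' @param stats Optional retention statistics to attach.
#' @return An object of class \code{gatc_track}: list with \code{sample},
#'   \code{counts} (named list of numeric vectors parallel to
#'   \code{index$sites}), \code{index}, \code{stats}, \code{dedup_mode}.
#' @export
count_per_site <- function(reads, index, dedup_mode = c("raw", "unique_tagmentation"),
                           sample = "sample", stats = NULL) {
  stopifnot(inherits(index, "gatc_index"))
  dedup_mode <- match.arg(dedup_mode)
  if (dedup_mode == "unique_tagmentation") reads <- dedup_tagmentation(reads)
  counts <- lapply(index$sites, function(s) numeric(length(s)))
  if (nrow(reads)) {
    bad <- !(reads$chrom %in% names(index$sites))
    if (any(bad))
      stop("internal consistency error: reads on unindexed chromosome(s): ",
           paste(unique(reads$chrom[bad]), collapse = ", "))
    for (ch in unique(reads$chrom)) {
      s <- index$sites[[ch]]
      pos <- reads$site[reads$chrom == ch]
      m <- match(pos, s)
      if (anyNA(m))
        stop("internal consistency error: read at unindexed site on ", ch)
      counts[[ch]] <- counts[[ch]] + tabulate(m, nbins = length(s))
    }
  }
  gatc_track(counts, index, sample = sample, stats = stats,
             dedup_mode = dedup_mode)
}

#' Construct a per-GATC count track
#'
#' Low-level constructor used by \code{\link{count_per_site}} and by the
#' simulator to expose truth counts as a track.
#'
#' @param counts Named list of non-negative numeric vectors parallel to
#'   \code{index$sites}, or a data.frame with columns \code{chrom},
#'   \code{pos}, \code{count}.
#' @inheritParams count_per_site
#' @return A \code{gatc_track}.
#' @export
gatc_track <- function(counts, index, sample = "sample", stats = NULL,
                       dedup_mode = "raw") {
  stopifnot(inherits(index, "gatc_index"))
  if (is.data.frame(counts)) {
    df <- counts
    counts <- lapply(index$sites, function(s) numeric(length(s)))
    for (ch in unique(df$chrom)) {
      m <- match(df$pos[df$chrom == ch], index$sites[[ch]])
      if (anyNA(m)) stop("count at unindexed site on ", ch)
      counts[[ch]][m] <- df$count[df$chrom == ch]
    }
  }
  if (!identical(names(counts), names(index$sites)) ||
      !all(lengths(counts) == lengths(index$sites)))
    stop("`counts` must parallel the index site lists")
  if (any(unlist(counts, use.names = FALSE) < 0))
    stop("negative counts")
  structure(list(sample = sample, counts = counts, index = index,
                 stats = stats, dedup_mode = dedup_mode),
            class = "gatc_track")
}

#' @export
print.gatc_track <- function(x, ...) {
  tot <- sum(unlist(x$counts, use.names = FALSE))
  nz <- sum(unlist(x$counts, use.names = FALSE) > 0)
  cat(sprintf("GATC count track '%s': %d sites, %s reads (%d sites non-zero), mode=%s\n",
              x$sample, sum(lengths(x$counts)), format(tot, big.mark = ","),
              nz, x$dedup_mode))
  if (!is.null(x$stats) && is.finite(x$stats$retention))
    cat(sprintf("  retention %.3f (%d/%d), unique tagmentation %.3f\n",
                x$stats$retention, x$stats$passing_pairs,
                x$stats$aligned_pairs, x$stats$unique_tagmentation_fraction))
  invisible(x)
}

#' @export
as.data.frame.gatc_track <- function(x, ...) {
  st <- site_table(x$index)
  st$count <- unlist(x$counts, use.names = FALSE)
  st
}

#' Write a count track as bedGraph
#'
#' One line per non-zero site: \code{chrom}, \code{p}, \code{p+4},
#' \code{count}.
#'
#' @param track A \code{gatc_track} (or normalised track; scores are written).
#' @param path Output path.
#' @param all_sites Write zero-count sites too (default FALSE).
#' @return \code{path}, invisibly.
#' @export
write_track_bedgraph <- function(track, path, all_sites = FALSE) {
  df <- as.data.frame(track)
  val <- if ("count" %in% names(df)) df$count else df$score
  keep <- if (all_sites) rep(TRUE, nrow(df)) else val != 0
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom[keep],
    ranges = IRanges::IRanges(start = df$pos[keep] + 1L, width = 4L),
    score = val[keep],
    seqlengths = track$index$chrom_lengths
  )
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph count track against an index
#'
#' @param path bedGraph file of 4-bp GATC intervals.
#' @param index The \code{\link{gatc_index}} to align counts to; intervals at
#'   unindexed positions are an error.
#' @param sample Sample identifier.
#' @return A \code{gatc_track}.
#' @export
read_track_bedgraph <- function(path, index, sample = "sample") {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    pos = GenomicRanges::start(gr) - 1L,
    count = GenomicRanges::mcols(gr)$score,
    stringsAsFactors = FALSE
  )
  gatc_track(df, index, sample = sample)
}
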