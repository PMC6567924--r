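# GATC coordinate backbone: every downstream count, track and profile is
# anchored to the positions produced here. Coordinates are 0-based, half-open;
# a site is identified by the position p of its G. DpnI cuts GA^TC, so the two
# valid ligation-derived read-one origins at a site are p+2 on the forward
# strand (right flank) and p+1 as the 5' base of a reverse-strand read (left
# flank).

#' Scan a nucleotide sequence for GATC sites
#'
#' Returns the 0-based start position of every occurrence of the tetramer
#' \code{GATC} (case-insensitive). \code{GATC} cannot overlap itself, so a
#' non-overlapping search is exhaustive. Windows containing \code{N} never
#' match; soft-masked (lowercase) bases are scanned normally, since masking is
#' annotation, not absence of sequence.
#'
#' @param sequence A single character string over the alphabet
#'   \code{A,C,G,T,N} (either case).
#' @return Integer vector of 0-based positions of the \code{G} of each site.
#' @examples
#' scan_gatc("GATCGATC")  # 0 4
#' scan_gatc("ACGTACGT")  # integer(0)
#' @export
scan_gatc <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("`sequence` must be a single character string")
  bad <- regexpr("[^ACGTNacgtn]", sequence)
  if (bad > 0L)
    stop(sprintf("malformed sequence: invalid character '%s' at position %d (1-based)",
                 substr(sequence, bad, bad), as.integer(bad)))
  if (nchar(sequence) < 4L) return(integer(0))
  m <- gregexpr("GATC", toupper(sequence), fixed = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' Build a genome-wide GATC index
#'
#' Scans each chromosome independently (no cross-contig motifs) and records
#' the sorted 0-based start positions of every GATC, together with chromosome
#' lengths. This index is the coordinate backbone for read filtering,
#' counting and all spatial diagnostics.
#'
#' @param genome One of: a path to a FASTA file (optionally gzipped), a
#'   \code{Biostrings::DNAStringSet}, or a named character vector of
#'   sequences. Chromosome names must be unique; FASTA names are truncated at
#'   the first whitespace.
#' @return An object of class \code{gatc_index}: a list with \code{sites} (a
#'   named list of strictly increasing integer vectors, one per chromosome)
#'   and \code{chrom_lengths} (named integer vector).
#' @examples
#' idx <- gatc_index(c(chr1 = "AAGATCAAGATCAA", chr2 = "GATC"))
#' idx$sites$chr1  # 2 8
#' @export
gatc_index <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome))) {
    if (!file.exists(genome)) stop("FASTA file not found: ", genome)
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    nms <- sub("\\s.*$", "", names(genome))
    seqs <- as.character(genome)
    names(seqs) <- nms
    genome <- seqs
  }
  if (!is.character(genome) || is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("`genome` must be a FASTA path, DNAStringSet, or named character vector")
  if (length(genome) == 0L) stop("empty genome: no chromosomes")
  if (anyDuplicated(names(genome)))
    stop("duplicate chromosome names: ",
         paste(unique(names(genome)[duplicated(names(genome))]), collapse = ", "))
  sites <- lapply(genome, scan_gatc)
  lens <- vapply(genome, nchar, integer(1))
  structure(list(sites = sites, chrom_lengths = lens), class = "gatc_index")
}

#' @export
print.gatc_index <- function(x, ...) {
  n <- sum(lengths(x$sites))
  L <- sum(as.numeric(x$chrom_lengths))
  cat(sprintf("GATC index: %d sites on %d chromosome(s), %.3g bp total (%.2f sites/kb)\n",
              n, length(x$sites), L, if (L > 0) 1000 * n / L else NA_real_))
  invisible(x)
}

#' Genome-wide GATC site density
#'
#' @param index A \code{\link{gatc_index}}.
#' @return A list with \code{sites_per_kb} (1000 x total sites / total genome
#'   length) and \code{per_bp_frequency} (\code{sites_per_kb / 1000}). In the
#'   mouse genome GATCs occur at roughly 2.6 sites per kb; an i.i.d.
#'   uniform-base sequence has expected per-bp frequency 4^-4.
#' @export
site_density <- function(index) {
  stopifnot(inherits(index, "gatc_index"))
  L <- sum(as.numeric(index$chrom_lengths))
  if (L == 0) stop("zero-length genome")
  spk <- 1000 * sum(lengths(index$sites)) / L
  list(sites_per_kb = spk, per_bp_frequency = spk / 1000)
}

#' Map a read-one 5' origin to its DpnI cut site
#'
#' DpnI leaves a blunt cut between positions p+1 and p+2 of the site GA^TC,
#' so a ligation-derived read one must start either at p+2 on the forward
#' strand (right flank) or with its 5' base at p+1 on the reverse strand
#' (left flank). Anything else is no match. Lookup is by binary search
#' (\code{findInterval}) on the sorted per-chromosome site vector.
#'
#' @param index A \code{\link{gatc_index}}.
#' @param chrom Chromosome name(s), recycled against positions.
#' @param five_prime_pos Integer vector of 0-based 5' alignment coordinates.
#' @param strand Character vector, \code{"+"}/\code{"forward"} or
#'   \code{"-"}/\code{"reverse"}, recycled.
#' @return A data.frame with columns \code{site} (0-based GATC start, NA if no
#'   match) and \code{flank} (\code{"right"}, \code{"left"}, or NA).
#' @examples
#' idx <- gatc_index(c(chr1 = paste0(strrep("A", 100), "GATC", strrep("A", 100))))
#' locate_cut(idx, "chr1", 102, "+")  # site 100, right flank
#' locate_cut(idx, "chr1", 101, "-")  # site 100, left flank
#' locate_cut(idx, "chr1", 101, "+")  # no match
#' @export
locate_cut <- function(index, chrom, five_prime_pos, strand) {
  stopifnot(inherits(index, "gatc_index"))
  n <- max(length(chrom), length(five_prime_pos), length(strand))
  chrom <- rep_len(as.character(chrom), n)
  five_prime_pos <- rep_len(as.integer(five_prime_pos), n)
  strand <- rep_len(normalize_strand(strand), n)
  unknown <- setdiff(unique(chrom), names(index$sites))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  site <- rep(NA_integer_, n)
  flank <- rep(NA_character_, n)
  cand <- ifelse(strand == "+", five_prime_pos - 2L, five_prime_pos - 1L)
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    s <- index$sites[[ch]]
    if (!length(s)) next
    i <- findInterval(cand[sel], s)
    hit <- i > 0L & s[pmax(i, 1L)] == cand[sel]
    site[sel[hit]] <- cand[sel][hit]
    flank[sel[hit]] <- ifelse(strand[sel[hit]] == "+", "right", "left")
  }
  data.frame(site = site, flank = flank, stringsAsFactors = FALSE)
}

# "+"/"-" canonical form; accepts forward/reverse spellings.
normalize_strand <- function(strand) {
  s <- as.character(strand)
  s[s %in% c("forward", "fwd", "F")] <- "+"
  s[s %in% c("reverse", "rev", "R")] <- "-"
  if (!all(s %in% c("+", "-")))
    stop("strand must be '+'/'forward' or '-'/'reverse'")
  s
}

# Flat data.frame of all indexed sites, in chromosome order.
site_table <- function(index) {
  data.frame(
    chrom = rep(names(index$sites), lengths(index$sites)),
    pos = unlist(index$sites, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Write a GATC index as BED4
#'
#' One line per site: \code{chrom}, \code{p}, \code{p+4}, \code{"GATC"}.
#'
#' @param index A \code{\link{gatc_index}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_index_bed <- function(index, path) {
  stopifnot(inherits(index, "gatc_index"))
  st <- site_table(index)
  # plain 4-column BED (rtracklayer::export.bed pads to BED6)
  write.table(data.frame(st$chrom, st$pos, st$pos + 4L, "GATC"),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED4 GATC index
#'
#' @param path BED file written by \code{\link{write_index_bed}} (or any BED
#'   of 4-bp GATC intervals).
#' @param chrom_lengths Named integer vector of chromosome lengths. Required:
#'   BED does not carry them.
#' @return A \code{\link{gatc_index}}.
#' @export
read_index_bed <- function(path, chrom_lengths) {
  if (is.null(names(chrom_lengths)))
    stop("`chrom_lengths` must be a named vector")
  gr <- rtracklayer::import(path, format = "BED")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  pos <- GenomicRanges::start(gr) - 1L
  unknown <- setdiff(unique(chrom), names(chrom_lengths))
  if (length(unknown))
    stop("BED chromosomes missing from `chrom_lengths`: ",
         paste(unknown, collapse = ", "))
  sites <- lapply(names(chrom_lengths), function(ch) sort(pos[chrom == ch]))
  names(sites) <- names(chrom_lengths)
  idx <- structure(
    list(sites = sites,
         chrom_lengths = setNames(as.integer(chrom_lengths), names(chrom_lengths))),
    class = "gatc_index"
  )
  validate_index(idx)
  idx
}

validate_index <- function(index) {
  for (ch in names(index$sites)) {
    s <- index$sites[[ch]]
    if (!length(s)) next
    if (any(diff(s) < 4L)) stop("sites overlap on ", ch, " (spacing < 4)")
    if (s[1L] < 0L || s[length(s)] > index$chrom_lengths[[ch]] - 4L)
      stop("site out of chromosome bounds on ", ch)
  }
  invisible(index)
}
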