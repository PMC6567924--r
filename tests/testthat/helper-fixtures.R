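# Shared fixtures and independent oracles, all built in code.

# Brute-force sliding-window GATC scan on raw bytes: the independent oracle
# for scan_gatc (which uses a non-overlapping fixed-string search).
brute_scan <- function(sequence) {
  n <- nchar(sequence)
  if (n < 4L) return(integer(0))
  r <- charToRaw(toupper(sequence))
  g <- charToRaw("G"); a <- charToRaw("A"); tt <- charToRaw("T"); cc <- charToRaw("C")
  i <- seq_len(n - 3L)
  which(r[i] == g & r[i + 1L] == a & r[i + 2L] == tt & r[i + 3L] == cc) - 1L
}

random_seq <- function(n, with_n = FALSE) {
  ab <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  pr <- if (with_n) c(0.24, 0.24, 0.24, 0.24, 0.04) else rep(0.25, 4)
  paste(sample(ab, n, replace = TRUE, prob = pr), collapse = "")
}

revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

# Index with S sites on a regular lattice (no sequence behind it); used by
# quantify/spatial unit tests that only need coordinates.
lattice_index <- function(n_sites, spacing = 100L, chrom = "chrT",
                          offset = 0L) {
  sites <- offset + (seq_len(n_sites) - 1L) * as.integer(spacing)
  len <- sites[n_sites] + as.integer(spacing)
  structure(list(sites = setNames(list(sites), chrom),
                 chrom_lengths = setNames(as.integer(len), chrom)),
            class = "gatc_index")
}

track_from_counts <- function(counts, index, sample = "t") {
  gatc_track(setNames(list(as.numeric(counts)), names(index$sites)),
             index, sample = sample)
}

# Aligned-pair rows regenerated from accepted cut-site reads (for
# idempotence checks): right flank -> forward read at p+2, left flank ->
# reverse read with 5' base at p+1.
pairs_from_reads <- function(reads, mapq = 60L) {
  data.frame(
    chrom = reads$chrom,
    strand = ifelse(reads$flank == "right", "+", "-"),
    read1_5prime = ifelse(reads$flank == "right", reads$site + 2L,
                          reads$site + 1L),
    mate_5prime = reads$tagmentation_pos,
    mapq = mapq,
    stringsAsFactors = FALSE
  )
}

# One forward aligned pair at the right-flank cut origin of `site`.
pair_at <- function(chrom, site, strand = "+", offset = 0L, mapq = 60L,
                    mate = 500L, ...) {
  pos <- if (strand == "+") site + 2L + offset else site + 1L + offset
  data.frame(chrom = chrom, strand = strand, read1_5prime = pos,
             mate_5prime = mate, mapq = mapq, ..., stringsAsFactors = FALSE)
}

total_counts <- function(track) sum(unlist(track$counts, use.names = FALSE))
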