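# Cross-sample comparison of per-GATC count tracks: correlation over all
# genomic GATCs, normalisation against an unfused Dam control, top-site
# ranking, and signal matrices around ranked sites.

track_values <- function(track) {
  if (inherits(track, "gatc_norm_track"))
    unlist(track$scores, use.names = FALSE)
  else
    unlist(track$counts, use.names = FALSE)
}

check_same_sites <- function(a, b) {
  if (!identical(a$index$sites, b$index$sites))
    stop("mismatched site lists: tracks were built against different indexes")
}

#' Site-by-sample matrix from count tracks
#'
#' @param tracks Named list of \code{gatc_track}s (or normalised tracks)
#'   sharing one index.
#' @return Numeric matrix, rows = all indexed sites (named
#'   \code{chrom:pos}), columns = samples.
#' @export
sample_matrix <- function(tracks) {
  if (!length(tracks)) stop("no tracks")
  for (t in tracks[-1]) check_same_sites(tracks[[1]], t)
  m <- vapply(tracks, track_values, numeric(sum(lengths(tracks[[1]]$index$sites))))
  if (is.null(colnames(m)))
    colnames(m) <- vapply(tracks, function(t) t$sample, character(1))
  st <- site_table(tracks[[1]]$index)
  rownames(m) <- paste(st$chrom, st$pos, sep = ":")
  m
}

#' Pearson correlation between samples over all genomic GATCs
#'
#' Raw-count correlation across the full site list, joint zeros included
#' (every genomic GATC is an observation); \code{nonzero_only} restricts to
#' sites with signal in at least one sample for sensitivity analysis.
#'
#' @param x A site-by-sample matrix or a named list of tracks.
#' @param method Only \code{"pearson"}.
#' @param nonzero_only Drop sites that are zero in every sample.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlate_samples <- function(x, method = "pearson", nonzero_only = FALSE) {
  method <- match.arg(method, "pearson")
  if (!is.matrix(x)) x <- sample_matrix(x)
  if (ncol(x) < 2) stop("need at least 2 samples")
  if (nonzero_only) x <- x[rowSums(x != 0) > 0, , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 sites")
  v <- apply(x, 2, sd)
  if (any(v == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(x)[v == 0], collapse = ", "))
  cor(x, method = method)
}

#' Normalise a fusion track to its unfused Dam control
#'
#' Unfused Dam methylates open chromatin non-specifically; dividing the
#' fusion signal by a depth-scaled control is the conventional background
#' correction. Per site s the score is
#' \deqn{\log_2\frac{(f_s + \psi)\,N_c}{(c_s + \psi)\,N_f}}
#' with \eqn{N} the total counts of each track and \eqn{\psi} a pseudocount
#' guarding empty sites. Swapping the roles of fusion and control negates
#' every score. \code{mode = "subtract"} instead returns the difference of
#' counts-per-million.
#'
#' @param fusion,control \code{gatc_track}s over the same index, each with
#'   total count > 0.
#' @param pseudocount \eqn{\psi}, default 1 (log-ratio mode only).
#' @param mode \code{"log2_ratio"} (default) or \code{"subtract"}.
#' @return An object of class \code{gatc_norm_track}: list with
#'   \code{scores} (named list parallel to the index), \code{index},
#'   \code{pseudocount}, \code{scaling} (the two totals), \code{mode},
#'   \code{sample}.
#' @export
normalize_to_control <- function(fusion, control, pseudocount = 1,
                                 mode = c("log2_ratio", "subtract")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fusion, "gatc_track"), inherits(control, "gatc_track"))
  check_same_sites(fusion, control)
  nf <- sum(unlist(fusion$counts, use.names = FALSE))
  nc <- sum(unlist(control$counts, use.names = FALSE))
  if (nf <= 0 || nc <= 0) stop("both tracks must have total counts > 0")
  scores <- lapply(names(fusion$counts), function(ch) {
    f <- fusion$counts[[ch]]
    c0 <- control$counts[[ch]]
    if (mode == "log2_ratio")
      log2(((f + pseudocount) * nc) / ((c0 + pseudocount) * nf))
    else
      f * 1e6 / nf - c0 * 1e6 / nc
  })
  names(scores) <- names(fusion$counts)
  structure(list(
    sample = paste0(fusion$sample, "_vs_", control$sample),
    scores = scores, index = fusion$index,
    pseudocount = if (mode == "log2_ratio") pseudocount else NA_real_,
    scaling = c(fusion_total = nf, control_total = nc), mode = mode
  ), class = "gatc_norm_track")
}

#' @export
print.gatc_norm_track <- function(x, ...) {
  v <- unlist(x$scores, use.names = FALSE)
  cat(sprintf("Normalised GATC track '%s' (%s, psi=%s): %d sites, score range [%.2f, %.2f]\n",
              x$sample, x$mode, format(x$pseudocount), length(v),
              min(v), max(v)))
  invisible(x)
}

#' @export
as.data.frame.gatc_norm_track <- function(x, ...) {
  st <- site_table(x$index)
  st$score <- unlist(x$scores, use.names = FALSE)
  st
}

#' Top methylated sites
#'
#' Ranks sites by decreasing count (or normalised score), breaking ties by
#' (chrom, position) for determinism. For raw count tracks only non-zero
#' sites are rankable: asking for more yields all of them with a warning.
#'
#' @param track A \code{gatc_track} or \code{gatc_norm_track}.
#' @param n Number of sites requested (>= 1).
#' @return data.frame \code{chrom}, \code{pos}, \code{score}, \code{rank},
#'   ordered best-first.
#' @export
top_sites <- function(track, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("`n` must be >= 1")
  df <- as.data.frame(track)
  names(df)[3] <- "score"
  if (!inherits(track, "gatc_norm_track")) {
    df <- df[df$score > 0, , drop = FALSE]
    if (n > nrow(df)) {
      warning(sprintf("only %d non-zero sites available (requested %d)",
                      nrow(df), as.integer(n)))
      n <- nrow(df)
    }
  } else if (n > nrow(df)) {
    warning(sprintf("only %d sites available (requested %d)", nrow(df),
                    as.integer(n)))
    n <- nrow(df)
  }
  o <- order(-df$score, df$chrom, df$pos)
  out <- df[o[seq_len(n)], , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Signal matrix around ranked sites
#'
#' For heatmap-style displays of an external signal (e.g. ChIP-seq coverage)
#' around the top methylated GATCs: row i is the mean signal per bin in
#' \code{[site_i - half_window, site_i + half_window)}, rows in the input
#' ranking order. Bins extending past a chromosome end are NA, never
#' silently truncated.
#'
#' @param sites data.frame with \code{chrom} and \code{pos} (e.g. from
#'   \code{\link{top_sites}}), in display order.
#' @param signal Interval signal: a data.frame \code{chrom}, \code{start},
#'   \code{end} (0-based half-open), \code{value}, or a \code{GRanges} with a
#'   \code{score} column. Uncovered positions count as 0.
#' @param half_window Window half-width in bp (default 2000).
#' @param bin Bin width in bp (default 50); must divide \code{half_window}.
#' @param chrom_lengths Optional named lengths; defaults to the furthest
#'   extent implied by signal and windows (in which case no NA padding
#'   occurs at the right edge).
#' @return Numeric matrix, rows = sites, columns = 2*half_window/bin bins;
#'   column names give bin start offsets relative to the site.
#' @export
signal_matrix <- function(sites, signal, half_window = 2000, bin = 50,
                          chrom_lengths = NULL) {
  if (half_window %% bin != 0) stop("`half_window` must be a multiple of `bin`")
  if (is.data.frame(signal)) {
    signal <- GenomicRanges::GRanges(
      seqnames = signal$chrom,
      ranges = IRanges::IRanges(start = signal$start + 1L, end = signal$end),
      score = signal$value
    )
  }
  chroms <- unique(sites$chrom)
  missing_chroms <- setdiff(chroms, as.character(
    GenomicRanges::seqnames(GenomicRanges::seqinfo(signal))))
  if (length(missing_chroms))
    stop("signal does not cover chromosome(s): ",
         paste(missing_chroms, collapse = ", "))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) {
      max(max(GenomicRanges::end(signal[GenomicRanges::seqnames(signal) == ch])),
          max(sites$pos[sites$chrom == ch]) + half_window)
    }, numeric(1))
  }
  cov <- GenomicRanges::coverage(signal, weight = "score")
  nb <- as.integer(2 * half_window / bin)
  out <- matrix(NA_real_, nrow = nrow(sites), ncol = nb)
  offs <- seq(-half_window, half_window - bin, by = bin)
  colnames(out) <- as.character(offs)
  for (ch in chroms) {
    rows <- which(sites$chrom == ch)
    len <- chrom_lengths[[ch]]
    rl <- cov[[ch]]
    if (length(rl) < len)
      rl <- c(rl, S4Vectors::Rle(0, len - length(rl)))
    starts0 <- rep(sites$pos[rows], each = nb) + rep(offs, length(rows))
    ends0 <- starts0 + bin
    ok <- starts0 >= 0 & ends0 <= len
    vals <- rep(NA_real_, length(starts0))
    if (any(ok)) {
      v <- IRanges::Views(rl, start = starts0[ok] + 1L, end = ends0[ok])
      vals[ok] <- IRanges::viewMeans(v)
    }
    out[rows, ] <- matrix(vals, ncol = nb, byrow = TRUE)
  }
  rownames(out) <- paste(sites$chrom, sites$pos, sep = ":")
  out
}
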