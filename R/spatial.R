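# Spatial-resolution diagnostics. The decay profile averages per-GATC
# methylation as a function of distance from peak midpoints (both sides
# folded), in non-overlapping 20 bp windows, so at typical GATC spacing each
# window holds at most one site. The half-decay distance - where the profile
# first falls to half its midpoint value - is the resolution metric; the
# binned autocorrelation is its peak-free counterpart.

#' Methylation decay profile around peak midpoints
#'
#' For each peak, every GATC within \code{max_dist} of the midpoint
#' contributes its count to the distance bin \code{|pos - midpoint|}; a
#' peak-bin value is the mean over its GATCs, and the profile is the mean
#' over all peak-bins that contain at least one GATC (bins of background
#' sequence without GATCs are excluded, not counted as zero). Sides are
#' folded by default; per-peak normalisation is not applied, so the profile
#' is an aggregate mean.
#'
#' @param track A \code{gatc_track}.
#' @param peaks data.frame \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open) or a \code{GRanges}. Midpoint = \code{floor((start+end)/2)}.
#' @param bin_width Window width in bp (default 20).
#' @param max_dist Maximum distance in bp (default 5000); must be a multiple
#'   of \code{bin_width}.
#' @param fold Fold the two sides together (default TRUE). Unfolded profiles
#'   carry signed distances and cannot be fed to
#'   \code{\link{half_decay_distance}}.
#' @return An object of class \code{decay_profile}: list with
#'   \code{bin_width}, \code{distances} (bin centers), \code{mean_signal},
#'   \code{smoothed} (centered 3-bin running mean; at the fold the first bin
#'   is reflected, since the folded profile is even), \code{n} (contributing
#'   peak-bins per bin), \code{n_peaks}, \code{reference_value} (smoothed
#'   value of the midpoint bin), \code{fold}.
#' @export
decay_profile <- function(track, peaks, bin_width = 20, max_dist = 5000,
                          fold = TRUE) {
  stopifnot(inherits(track, "gatc_track"))
  if (methods::is(peaks, "GRanges")) {
    peaks <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(peaks)),
      start = GenomicRanges::start(peaks) - 1L,
      end = GenomicRanges::end(peaks),
      stringsAsFactors = FALSE
    )
  }
  if (!nrow(peaks)) stop("need at least one peak")
  if (any(peaks$start >= peaks$end)) stop("peaks must satisfy start < end")
  if (max_dist %% bin_width != 0)
    stop("`max_dist` must be a multiple of `bin_width`")
  mid <- (peaks$start + peaks$end) %/% 2L
  nb <- as.integer(max_dist / bin_width)

  pk_id <- integer(0); b <- integer(0); v <- numeric(0)
  for (ch in unique(peaks$chrom)) {
    s <- track$index$sites[[ch]]
    if (is.null(s)) stop("peak chromosome not in index: ", ch)
    if (!length(s)) next
    cnt <- track$counts[[ch]]
    rows <- which(peaks$chrom == ch)
    for (r in rows) {
      m <- mid[r]
      lo <- findInterval(m - max_dist, s) + 1L   # first site > m - max_dist
      hi <- findInterval(m + max_dist - 1L, s)   # last site <= m + max_dist - 1
      if (hi < lo) next
      d <- s[lo:hi] - m
      if (fold) {
        bb <- abs(d) %/% bin_width + 1L
      } else {
        bb <- (d + max_dist) %/% bin_width + 1L  # 1 .. 2*nb
      }
      pk_id <- c(pk_id, rep.int(r, hi - lo + 1L))
      b <- c(b, bb)
      v <- c(v, cnt[lo:hi])
    }
  }
  if (!length(v))
    stop("no GATC within max_dist of any peak")
  nbins <- if (fold) nb else 2L * nb
  # per peak-bin mean, then mean over peak-bins
  key <- pk_id * (nbins + 1L) + b
  pb_mean <- tapply(v, key, mean)
  pb_bin <- as.integer(as.numeric(names(pb_mean)) %% (nbins + 1L))
  mean_signal <- rep(NA_real_, nbins)
  nvec <- integer(nbins)
  agg <- tapply(as.numeric(pb_mean), pb_bin, mean)
  cntb <- table(pb_bin)
  mean_signal[as.integer(names(agg))] <- as.numeric(agg)
  nvec[as.integer(names(cntb))] <- as.integer(cntb)
  distances <- if (fold) (seq_len(nb) - 0.5) * bin_width
               else (seq_len(2L * nb) - 0.5) * bin_width - max_dist
  sm <- smooth3(mean_signal, reflect_left = fold)
  ref <- if (fold) sm[1L] else sm[nb] # midpoint bin
  structure(list(bin_width = bin_width, max_dist = max_dist,
                 distances = distances, mean_signal = mean_signal,
                 smoothed = sm, n = nvec, n_peaks = nrow(peaks),
                 reference_value = ref, fold = fold),
            class = "decay_profile")
}

# Centered 3-bin running mean over available (non-NA) neighbours. A folded
# profile is an even function of distance, so its left edge is smoothed with
# the first bin reflected across the fold instead of a truncated window
# (truncation would bias the midpoint reference low).
smooth3 <- function(x, reflect_left = FALSE) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- if (i == 1L && reflect_left) x[c(1L, 1L, min(n, 2L))]
         else x[max(1L, i - 1L):min(n, i + 1L)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' @export
print.decay_profile <- function(x, ...) {
  cat(sprintf("Decay profile: %d peaks, %d x %d bp bins (%s), midpoint reference %.3g\n",
              x$n_peaks, length(x$distances), x$bin_width,
              if (x$fold) "folded" else "two-sided", x$reference_value))
  invisible(x)
}

#' @export
as.data.frame.decay_profile <- function(x, ...) {
  data.frame(distance = x$distances, mean_signal = x$mean_signal,
             smoothed = x$smoothed, n = x$n)
}

#' Half-decay distance of a profile
#'
#' The smallest distance at which the smoothed profile first falls below
#' half its midpoint reference, linearly interpolated between the straddling
#' bin centers; bins with no GATC content are skipped. Scale-invariant:
#' multiplying the track by any positive constant leaves it unchanged.
#'
#' @param profile A folded \code{\link{decay_profile}}.
#' @return Distance in bp, or \code{Inf} when the profile never falls below
#'   half within \code{max_dist} (the "beyond max_dist" sentinel).
#' @export
half_decay_distance <- function(profile) {
  stopifnot(inherits(profile, "decay_profile"))
  if (!profile$fold) stop("half-decay is defined on folded profiles")
  ref <- profile$reference_value
  if (is.na(ref) || ref <= 0) stop("reference value must be > 0")
  ok <- !is.na(profile$smoothed)
  d <- profile$distances[ok]
  v <- profile$smoothed[ok]
  below <- which(v < ref / 2)
  if (!length(below)) return(Inf)
  j <- below[1L]
  if (j == 1L) return(d[1L])
  d[j - 1L] + (v[j - 1L] - ref / 2) / (v[j - 1L] - v[j]) * (d[j] - d[j - 1L])
}

#' Residual methylation at a distance
#'
#' Smoothed profile value at \code{at} bp from the midpoint (interpolated
#' between bin centers, clamped at the ends) divided by the midpoint
#' reference. E.g. a half-life-150 bp exponential evaluates to
#' \code{2^(-1000/150)} at 1 kb, about 1%.
#'
#' @param profile A folded \code{\link{decay_profile}}.
#' @param at Distance in bp, \code{<= max_dist}.
#' @return Fraction of the reference value.
#' @export
residual_fraction <- function(profile, at) {
  stopifnot(inherits(profile, "decay_profile"))
  if (!profile$fold) stop("residual fraction is defined on folded profiles")
  if (at > profile$max_dist) stop("`at` exceeds max_dist")
  ref <- profile$reference_value
  if (is.na(ref) || ref <= 0) stop("reference value must be > 0")
  ok <- !is.na(profile$smoothed)
  d <- profile$distances[ok]
  v <- profile$smoothed[ok]
  if (length(d) == 1L) return(v / ref)
  approx(d, v, xout = at, rule = 2)$y / ref
}

#' Genome-wide binned autocorrelation of methylation counts
#'
#' Counts are summed into consecutive fixed-width bins per chromosome
#' (zero-count bins included: the genome between sites carries information
#' about signal spread), Pearson autocorrelation is computed at each lag
#' within chromosomes only, and chromosomes are combined by a
#' bin-count-weighted average. Unchanged by adding any constant to the
#' track.
#'
#' @param track A \code{gatc_track}.
#' @param bin_width Bin width in bp (default 100).
#' @param max_lag Maximum lag in bins (default 50).
#' @param gatc_bins_only Restrict the series to bins containing at least one
#'   indexed GATC (lags then step over that subsequence; default FALSE).
#' @return An object of class \code{gatc_autocorr}: data.frame with
#'   \code{lag} (bins), \code{lag_bp}, \code{r}.
#' @export
binned_autocorrelation <- function(track, bin_width = 100, max_lag = 50,
                                   gatc_bins_only = FALSE) {
  stopifnot(inherits(track, "gatc_track"))
  series <- list()
  for (ch in names(track$counts)) {
    len <- track$index$chrom_lengths[[ch]]
    nbins <- as.integer(ceiling(len / bin_width))
    if (nbins < 2L) next
    s <- track$index$sites[[ch]]
    if (!length(s)) next
    x <- numeric(nbins)
    bi <- s %/% bin_width + 1L
    agg <- rowsum(track$counts[[ch]], bi)
    x[as.integer(rownames(agg))] <- agg[, 1L]
    if (gatc_bins_only) x <- x[sort(unique(bi))]
    series[[ch]] <- x
  }
  if (!length(series)) stop("no chromosome has enough bins")
  usable <- vapply(series, function(x) sd(x) > 0, logical(1))
  if (!any(usable)) stop("zero variance on all chromosomes")
  series <- series[usable]
  lags <- seq_len(max_lag)
  r <- vapply(lags, function(k) {
    num <- 0; den <- 0
    for (x in series) {
      n <- length(x)
      if (n < k + 2L) next
      a <- x[seq_len(n - k)]
      b <- x[seq_len(n - k) + k]
      if (sd(a) == 0 || sd(b) == 0) next
      num <- num + cor(a, b) * n
      den <- den + n
    }
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
  structure(data.frame(lag = lags, lag_bp = lags * bin_width, r = r),
            class = c("gatc_autocorr", "data.frame"),
            bin_width = bin_width)
}
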