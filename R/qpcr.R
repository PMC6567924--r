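# Locus-specific methylation by qPCR. Split a genomic DNA sample, digest one
# half with DpnI (cuts methylated GATC) and the other with DpnII (cuts
# unmethylated GATC), then amplify across the site: the methylated fraction
# follows from the difference in amplification cycle counts of the two
# digests, because each digest removes its half of the templates.

#' Methylated fraction from DpnI/DpnII cycle counts
#'
#' \deqn{f = \frac{1}{1 + 2^{c_{II} - c_I}}}
#' where \code{c_I} is the qPCR cycle count after DpnI digestion and
#' \code{c_II} after DpnII. Equal cycle counts give 0.5; the function is
#' strictly decreasing in \code{c_II - c_I} and satisfies
#' \code{f(delta) + f(-delta) = 1}.
#'
#' @param c_I,c_II Finite numeric cycle counts (vectorised).
#' @return Fraction(s) in (0, 1).
#' @examples
#' methylated_fraction(20, 20)      # 0.5
#' methylated_fraction(20, 17)      # 8/9: 3 cycles earlier after DpnII
#' @export
methylated_fraction <- function(c_I, c_II) {
  if (!all(is.finite(c_I)) || !all(is.finite(c_II)))
    stop("cycle counts must be finite")
  1 / (1 + 2^(c_II - c_I))
}

#' Read a qPCR cycle-count table
#'
#' Long-format TSV with columns \code{site_label}, \code{class}
#' (\code{positive}/\code{negative}), \code{digest} (\code{DpnI}/\code{DpnII}),
#' \code{replicate}, \code{cycles}. Each (site, replicate) must carry both
#' digests.
#'
#' @param path TSV path.
#' @return Wide data.frame: \code{site_label}, \code{class},
#'   \code{replicate}, \code{c_I}, \code{c_II}.
#' @export
read_qpcr_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("site_label", "class", "digest", "replicate", "cycles")
  if (!all(need %in% names(x)))
    stop("qPCR table needs columns: ", paste(need, collapse = ", "))
  if (!all(x$digest %in% c("DpnI", "DpnII")))
    stop("digest must be 'DpnI' or 'DpnII'")
  a <- x[x$digest == "DpnI", c("site_label", "class", "replicate", "cycles")]
  b <- x[x$digest == "DpnII", c("site_label", "replicate", "cycles")]
  names(a)[4] <- "c_I"
  names(b)[3] <- "c_II"
  out <- merge(a, b, by = c("site_label", "replicate"))
  if (nrow(out) * 2L != nrow(x))
    stop("each (site, replicate) must have exactly one DpnI and one DpnII row")
  out[order(out$site_label, out$replicate),
      c("site_label", "class", "replicate", "c_I", "c_II")]
}

#' Summarise a qPCR methylation assay
#'
#' Fractions are computed per replicate first (averaging cycle counts before
#' transforming would bias through the nonlinearity), then summarised as
#' mean and SD per site, then averaged without weighting across the sites of
#' each class. Fold enrichment is the positive-class mean over the
#' negative-class mean.
#'
#' @param assays Wide data.frame as returned by \code{\link{read_qpcr_table}}
#'   (columns \code{site_label}, \code{class}, \code{replicate}, \code{c_I},
#'   \code{c_II}), or a long one with a \code{digest} column, or a data.frame
#'   with a precomputed \code{fraction} column.
#' @return An object of class \code{qpcr_summary}: list with \code{sites}
#'   (per-site mean/SD/replicate count), \code{classes} (per-class mean),
#'   and \code{fold_enrichment}. A negative-class mean of exactly zero
#'   yields \code{Inf} with a warning.
#' @export
summarize_qpcr <- function(assays) {
  x <- as.data.frame(assays)
  if ("digest" %in% names(x) && !("c_I" %in% names(x))) {
    tmp <- tempfile(fileext = ".tsv")
    write.table(x, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
    x <- read_qpcr_table(tmp)
    unlink(tmp)
  }
  if (!("fraction" %in% names(x))) {
    if (!all(c("c_I", "c_II") %in% names(x)))
      stop("need either a `fraction` column or `c_I`/`c_II` columns")
    x$fraction <- methylated_fraction(x$c_I, x$c_II)
  }
  if (!all(x$class %in% c("positive", "negative")))
    stop("class must be 'positive' or 'negative'")
  sites <- do.call(rbind, lapply(split(x, x$site_label), function(d) {
    data.frame(site_label = d$site_label[1L], class = d$class[1L],
               mean_fraction = mean(d$fraction),
               sd_fraction = if (nrow(d) > 1L) sd(d$fraction) else NA_real_,
               n_replicates = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(sites) <- NULL
  classes <- vapply(split(sites$mean_fraction, sites$class), mean, numeric(1))
  if (!all(c("positive", "negative") %in% names(classes)))
    stop("need at least one site per class for fold enrichment")
  if (classes[["negative"]] == 0) {
    warning("negative-class mean is 0; fold enrichment reported as Inf")
    fold <- Inf
  } else {
    fold <- classes[["positive"]] / classes[["negative"]]
  }
  structure(list(sites = sites,
                 classes = data.frame(class = names(classes),
                                      mean_fraction = unname(classes),
                                      stringsAsFactors = FALSE),
                 fold_enrichment = fold),
            class = "qpcr_summary")
}

#' @export
print.qpcr_summary <- function(x, ...) {
  cat("qPCR methylation summary\n")
  for (i in seq_len(nrow(x$classes)))
    cat(sprintf("  %-8s class mean fraction %.4g\n",
                x$classes$class[i], x$classes$mean_fraction[i]))
  cat(sprintf("  fold enrichment (positive/negative): %.3g\n",
              x$fold_enrichment))
  invisible(x)
}

#' Bundled Tcf7l2 qPCR site panel
#'
#' Locations and primer pairs of the eight assay sites used for
#' locus-specific validation: four positive sites inside clear Tcf7l2
#' ChIP-seq peaks and four negative sites at least 20 kb from any Tcf
#' binding yet within DNase-hypersensitive open chromatin (mm10
#' coordinates). Shipped for documentation and format tests; no primer
#' design logic is included.
#'
#' @return data.frame: \code{site_label}, \code{class}, \code{chrom},
#'   \code{start}, \code{end}, \code{forward_primer}, \code{reverse_primer}.
#' @export
qpcr_site_panel <- function() {
  read.delim(system.file("extdata", "tcf7l2_qpcr_sites.tsv",
                         package = "gatcseq"),
             stringsAsFactors = FALSE)
}
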