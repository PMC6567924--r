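# Generative model of the DamID-seq experiment. Methylation is seeded per
# cell at each GATC with probability A * 2^(-d/lambda) + B (d = distance to
# the nearest planted binding site; B depends on open-chromatin membership),
# each seeded event extends processively across adjacent GATCs with a
# geometric run, site states are OR-ed within a cell (saturation), and counts
# are summed over cells. Reads are then emitted per event: read one anchored
# at the DpnI cut, read two at a random tagmentation position within the
# fragment-length bounds, plus PCR duplicates and a configurable fraction of
# non-specific reads from uniform random break points. Ground truth labels
# ride along at every stage.

#' Simulation configuration
#'
#' All randomness derives from \code{seed}: \code{\link{generate_genome}}
#' uses \code{seed}, \code{\link{simulate_methylation}} \code{seed + 1},
#' \code{\link{generate_reads}} \code{seed + 2}, so stages are independently
#' reproducible.
#'
#' Presets sketch the two enzyme regimes the assay distinguishes:
#' \code{"wild_type"} (long-range kernel \code{decay_half_distance = 600} bp,
#' high processivity \code{rho = 0.7}, high open-chromatin background)
#' reflects strongly DNA-bound, processive Dam; \code{"mutant"}
#' (\code{150} bp, \code{rho = 0.1}, low background) reflects the
#' reduced-binding, low-processivity mutants. They are illustrative regimes,
#' not kinetic fits.
#'
#' @param genome_length Chromosome length in bp (>= 10 kb).
#' @param gc_content GC fraction of the i.i.d. genome (default 0.5).
#' @param n_binding_sites Planted binding sites, uniformly placed at least
#'   \code{2 * decay_half_distance} apart.
#' @param decay_half_distance Kernel half-distance lambda in bp: seed
#'   probability halves every lambda bp from a binding site.
#' @param peak_amplitude Per-cell seed probability A at distance 0.
#' @param processivity Continuation probability rho of extending a seeded
#'   event to the next adjacent GATC (per step, each side; mean extension
#'   \code{1/(1-rho) - 1} sites per side).
#' @param background_open,background_closed Per-cell per-site seed
#'   probabilities inside/outside open-chromatin tracts
#'   (\code{background_open >= background_closed}).
#' @param open_fraction Fraction phi of the genome in open tracts; tracts
#'   cover all binding sites.
#' @param n_cells Cells pooled in the library.
#' @param capture_efficiency Probability epsilon that a methylation event
#'   yields a fragment.
#' @param nonspecific_fraction Fraction eta of reads originating at uniform
#'   random break points (non-specific ligation onto broken ends).
#' @param duplication_rate Expected extra PCR copies per fragment (each
#'   fragment is emitted \code{1 + Poisson(duplication_rate)} times).
#' @param fragment_min,fragment_max Tagmentation insert bounds in bp.
#' @param seed Integer seed.
#' @param chrom_name Name of the simulated chromosome.
#' @param preset \code{NULL}, \code{"wild_type"} or \code{"mutant"}; explicit
#'   arguments override preset values.
#' @return An object of class \code{sim_config} (validated named list).
#' @export
sim_config <- function(genome_length = 5e6,
                       gc_content = 0.5,
                       n_binding_sites = 200,
                       decay_half_distance = 150,
                       peak_amplitude = 0.3,
                       processivity = 0.1,
                       background_open = 0.002,
                       background_closed = 5e-4,
                       open_fraction = 0.1,
                       n_cells = 300,
                       capture_efficiency = 1,
                       nonspecific_fraction = 0,
                       duplication_rate = 0,
                       fragment_min = 150,
                       fragment_max = 600,
                       seed = 1L,
                       chrom_name = "chrSim",
                       preset = NULL) {
  cfg <- list(genome_length = genome_length, gc_content = gc_content,
              n_binding_sites = n_binding_sites,
              decay_half_distance = decay_half_distance,
              peak_amplitude = peak_amplitude, processivity = processivity,
              background_open = background_open,
              background_closed = background_closed,
              open_fraction = open_fraction, n_cells = n_cells,
              capture_efficiency = capture_efficiency,
              nonspecific_fraction = nonspecific_fraction,
              duplication_rate = duplication_rate,
              fragment_min = fragment_min, fragment_max = fragment_max,
              seed = as.integer(seed), chrom_name = chrom_name)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("wild_type", "mutant"))
    pv <- if (preset == "wild_type") {
      list(decay_half_distance = 600, processivity = 0.7,
           background_open = 0.01, background_closed = 0.002)
    } else {
      list(decay_half_distance = 150, processivity = 0.1,
           background_open = 0.002, background_closed = 5e-4)
    }
    supplied <- names(match.call())[-1]
    for (nm in names(pv)) if (!(nm %in% supplied)) cfg[[nm]] <- pv[[nm]]
    cfg$preset <- preset
  }
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c("gc_content", "peak_amplitude", "processivity",
             "background_open", "background_closed", "open_fraction",
             "capture_efficiency", "nonspecific_fraction")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("`%s` must be a probability in [0, 1]", p))
  }
  if (cfg$processivity >= 1) stop("`processivity` must be < 1")
  if (cfg$decay_half_distance <= 0) stop("`decay_half_distance` must be > 0")
  if (cfg$background_open < cfg$background_closed)
    stop("`background_open` must be >= `background_closed`")
  if (cfg$genome_length < 1e4) stop("`genome_length` must be >= 10 kb")
  if (cfg$fragment_min < 10 || cfg$fragment_max < cfg$fragment_min)
    stop("fragment bounds must satisfy 10 <= fragment_min <= fragment_max")
  if (cfg$duplication_rate < 0) stop("`duplication_rate` must be >= 0")
  if (cfg$n_cells < 1 || cfg$n_binding_sites < 0) stop("counts must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "DamID simulation config%s: %.3g bp genome, %d binding sites\n",
    "  kernel: A=%.2g halving every %g bp; processivity rho=%.2g\n",
    "  background: open %.2g / closed %.2g (phi=%.2g); %d cells\n",
    "  reads: epsilon=%.2g, eta=%.2g, duplication=%.2g, fragments %d-%d bp, seed %d\n"),
    if (is.null(x$preset)) "" else sprintf(" [%s]", x$preset),
    x$genome_length, x$n_binding_sites, x$peak_amplitude,
    x$decay_half_distance, x$processivity, x$background_open,
    x$background_closed, x$open_fraction, x$n_cells, x$capture_efficiency,
    x$nonspecific_fraction, x$duplication_rate, x$fragment_min,
    x$fragment_max, x$seed))
  invisible(x)
}

#' Generate a synthetic genome with binding sites and open tracts
#'
#' Draws an i.i.d. sequence at the requested GC content, indexes its GATCs,
#' places binding sites uniformly with minimum spacing
#' \code{2 * decay_half_distance}, and lays open-chromatin tracts covering
#' about \code{open_fraction} of the genome, always containing every binding
#' site (unless \code{open_fraction} is 0). Deterministic given
#' \code{config$seed}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List: \code{genome} (named character), \code{index}
#'   (\code{\link{gatc_index}}), \code{binding_sites} (0-based positions),
#'   \code{open_tracts} (data.frame \code{start}, \code{end}, 0-based
#'   half-open, disjoint sorted).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- as.integer(config$genome_length)
  gc <- config$gc_content
  seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
               collapse = "")
  genome <- setNames(seq, config$chrom_name)
  index <- gatc_index(genome)

  nb <- config$n_binding_sites
  minsep <- 2 * config$decay_half_distance
  binding <- integer(0)
  if (nb > 0) {
    if (nb * minsep > 0.9 * L)
      stop(sprintf("infeasible spacing: %d sites with %g bp separation on %d bp",
                   nb, minsep, L))
    slack <- L - nb * minsep
    u <- sort(runif(nb, 0, slack))
    binding <- as.integer(floor(u + (seq_len(nb) - 1) * minsep + minsep / 2))
  }

  tracts <- data.frame(start = integer(0), end = integer(0))
  if (config$open_fraction > 0) {
    target <- config$open_fraction * L
    # tract width sized so binding-site tracts alone stay near the target
    # coverage, clamped to a DNase-hypersensitive-like 0.5-5 kb scale
    W <- as.integer(if (nb > 0) min(5000, max(500, floor(target / nb)))
                    else 2000)
    starts <- pmax(0L, binding - W %/% 2L)
    n_extra <- max(0, round((target - nb * W) / W))
    if (n_extra > 0)
      starts <- c(starts, as.integer(floor(runif(n_extra, 0, L - W))))
    ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, width = W))
    tracts <- data.frame(start = IRanges::start(ir) - 1L,
                         end = pmin(IRanges::end(ir), L))
  }
  list(genome = genome, index = index, binding_sites = binding,
       open_tracts = tracts)
}

#' Simulate per-GATC methylation events
#'
#' Per cell, each GATC at distance d from the nearest binding site is seeded
#' with probability \code{min(1, A * 2^(-d/lambda) + B)} (B by open-tract
#' membership); every seed extends to consecutive neighbouring GATCs in both
#' directions with per-step continuation probability rho (geometric runs);
#' a site methylated by any event in a cell counts once (saturation).
#' Counts are summed over \code{n_cells}.
#'
#' @param config A \code{\link{sim_config}}.
#' @param index The genome's \code{\link{gatc_index}} (single chromosome).
#' @param binding_sites 0-based binding positions.
#' @param open_tracts data.frame \code{start}, \code{end} (0-based half-open).
#' @param keep_events Also return the per-cell methylated site indices
#'   (data.frame \code{cell}, \code{site_index}); memory-heavy, for small
#'   simulations and run-length diagnostics.
#' @return An object of class \code{sim_truth}: list with \code{counts}
#'   (named list per chromosome, parallel to the index), \code{truth_track}
#'   (the same as a \code{\link{gatc_track}}), \code{binding_sites},
#'   \code{open_tracts}, \code{n_cells}, and optionally \code{events}.
#' @export
simulate_methylation <- function(config, index, binding_sites, open_tracts,
                                 keep_events = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(index, "gatc_index"))
  if (length(index$sites) != 1L)
    stop("the simulator models a single chromosome")
  set.seed(config$seed + 1L)
  ch <- names(index$sites)[1L]
  s <- index$sites[[ch]]
  S <- length(s)
  if (!S) stop("genome contains no GATC site")

  d <- rep(Inf, S)
  if (length(binding_sites)) {
    bs <- sort(binding_sites)
    i <- findInterval(s, bs)
    dl <- ifelse(i >= 1L, s - bs[pmax(i, 1L)], Inf)
    dr <- ifelse(i < length(bs), bs[pmin(i + 1L, length(bs))] - s, Inf)
    d <- pmin(dl, dr)
  }
  open <- rep(FALSE, S)
  if (nrow(open_tracts)) {
    j <- findInterval(s, open_tracts$start)
    open <- j >= 1L & s < open_tracts$end[pmax(j, 1L)]
  }
  p_seed <- pmin(1, config$peak_amplitude * 2^(-d / config$decay_half_distance) +
                   ifelse(open, config$background_open, config$background_closed))

  rho <- config$processivity
  counts <- numeric(S)
  events <- if (keep_events) vector("list", config$n_cells) else NULL
  for (cell in seq_len(config$n_cells)) {
    seeds <- which(runif(S) < p_seed)
    if (!length(seeds)) next
    k <- length(seeds)
    if (rho > 0) {
      lo <- pmax(1L, seeds - rgeom(k, 1 - rho))
      hi <- pmin(S, seeds + rgeom(k, 1 - rho))
    } else {
      lo <- seeds; hi <- seeds
    }
    meth <- logical(S)
    for (j in seq_len(k)) meth[lo[j]:hi[j]] <- TRUE
    counts <- counts + meth
    if (keep_events) events[[cell]] <- which(meth)
  }
  cl <- setNames(list(counts), ch)
  out <- list(counts = cl,
              truth_track = gatc_track(cl, index, sample = "truth"),
              binding_sites = binding_sites, open_tracts = open_tracts,
              n_cells = config$n_cells)
  if (keep_events)
    out$events <- data.frame(
      cell = rep(seq_along(events), lengths(events)),
      site_index = unlist(events, use.names = FALSE))
  structure(out, class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cnt <- x$counts[[1L]]
  cat(sprintf("Simulated methylation truth: %d sites, %d cells, %s events (%.1f%% sites hit)\n",
              length(cnt), x$n_cells, format(sum(cnt), big.mark = ","),
              100 * mean(cnt > 0)))
  invisible(x)
}

#' Generate aligned read pairs from methylation truth
#'
#' Every methylation event yields, with probability
#' \code{capture_efficiency}, one fragment: a flank is drawn (left/right,
#' equal odds, falling back to the feasible side near chromosome ends), read
#' one's 5' origin sits at the DpnI cut coordinate of that flank, and the
#' tagmentation end lies a uniform fragment length away, directed away from
#' the cut. Each fragment is emitted \code{1 + Poisson(duplication_rate)}
#' times with identical coordinates (PCR duplicates share the tuple but not
#' the read name). Non-specific reads, a fraction
#' \code{nonspecific_fraction} of the library, start at uniform random break
#' points on either strand. Output rows are valid aligned pairs for
#' \code{\link{classify_reads}} and \code{\link{write_sam}}, with truth
#' labels alongside.
#'
#' @param truth A \code{\link{simulate_methylation}} result.
#' @param config The same \code{\link{sim_config}}.
#' @param index The same \code{\link{gatc_index}}.
#' @return List: \code{pairs} (aligned-pair data.frame with extra columns
#'   \code{label} in \{specific, duplicate, nonspecific\}, \code{true_site}),
#'   \code{n_dropped_edge} (events with no feasible fragment),
#'   \code{n_specific}, \code{n_nonspecific}.
#' @export
generate_reads <- function(truth, config, index) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  ch <- names(index$sites)[1L]
  s <- index$sites[[ch]]
  L <- index$chrom_lengths[[ch]]
  fmin <- as.integer(config$fragment_min)
  fmax <- as.integer(config$fragment_max)
  cnt <- truth$counts[[ch]]

  ncap <- if (config$capture_efficiency >= 1) as.integer(cnt)
          else rbinom(length(cnt), as.integer(cnt), config$capture_efficiency)
  site_idx <- rep(seq_along(s), ncap)
  p2 <- s[site_idx] + 2L
  left_cap <- pmin(fmax, p2)          # max fragment length leftward
  right_cap <- pmin(fmax, L - p2)     # rightward
  left_ok <- left_cap >= fmin
  right_ok <- right_cap >= fmin
  u <- runif(length(site_idx))
  go_left <- ifelse(left_ok & right_ok, u < 0.5, left_ok)
  feasible <- left_ok | right_ok
  n_dropped <- sum(!feasible)
  site_idx <- site_idx[feasible]
  p2 <- p2[feasible]
  go_left <- go_left[feasible]
  cap <- ifelse(go_left, left_cap[feasible], right_cap[feasible])
  len <- fmin + floor(runif(length(p2)) * (cap - fmin + 1))
  spec <- data.frame(
    qname = sprintf("frag%07d", seq_along(p2)),
    chrom = ch,
    strand = ifelse(go_left, "-", "+"),
    read1_5prime = as.integer(ifelse(go_left, p2 - 1L, p2)),
    mate_5prime = as.integer(ifelse(go_left, p2 - len, p2 + len - 1L)),
    mapq = 60L,
    label = "specific",
    true_site = s[site_idx],
    stringsAsFactors = FALSE
  )
  if (config$duplication_rate > 0 && nrow(spec)) {
    copies <- 1L + rpois(nrow(spec), config$duplication_rate)
    idx <- rep(seq_len(nrow(spec)), copies)
    dup <- duplicated(idx)
    spec <- spec[idx, , drop = FALSE]
    spec$label[dup] <- "duplicate"
    spec$qname <- sprintf("%s.%d", spec$qname,
                          sequence(copies))
    rownames(spec) <- NULL
  }

  eta <- config$nonspecific_fraction
  n_spec <- nrow(spec)
  n_ns <- if (eta <= 0) 0L
          else if (eta >= 1) max(n_spec, 1000L)
          else as.integer(round(n_spec * eta / (1 - eta)))
  ns <- NULL
  if (n_ns > 0) {
    fwd <- runif(n_ns) < 0.5
    # uniform origins restricted to positions where a fragment fits
    pos <- ifelse(fwd,
                  floor(runif(n_ns) * (L - fmin + 1)),
                  fmin - 1L + floor(runif(n_ns) * (L - fmin + 1)))
    cap_ns <- ifelse(fwd, pmin(fmax, L - pos), pmin(fmax, pos + 1L))
    len_ns <- fmin + floor(runif(n_ns) * (cap_ns - fmin + 1))
    ns <- data.frame(
      qname = sprintf("brk%07d", seq_len(n_ns)),
      chrom = ch,
      strand = ifelse(fwd, "+", "-"),
      read1_5prime = as.integer(pos),
      mate_5prime = as.integer(ifelse(fwd, pos + len_ns - 1L, pos - len_ns + 1L)),
      mapq = 60L,
      label = "nonspecific",
      true_site = NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  pairs <- if (eta >= 1) ns else rbind(spec, ns)
  if (is.null(pairs)) pairs <- spec
  pairs$secondary <- FALSE
  pairs$supplementary <- FALSE
  pairs$duplicate <- FALSE
  pairs$clip5 <- FALSE
  rownames(pairs) <- NULL
  list(pairs = pairs, n_dropped_edge = n_dropped,
       n_specific = if (eta >= 1) 0L else n_spec,
       n_nonspecific = if (is.null(ns)) 0L else nrow(ns))
}

#' Run the full DamID simulation
#'
#' \code{\link{generate_genome}}, \code{\link{simulate_methylation}} and
#' \code{\link{generate_reads}} in sequence.
#'
#' @param config A \code{\link{sim_config}}.
#' @param keep_events Passed to \code{\link{simulate_methylation}}.
#' @return An object of class \code{damid_sim}: list with \code{config},
#'   \code{genome}, \code{index}, \code{binding_sites}, \code{open_tracts},
#'   \code{truth} (\code{sim_truth}), \code{reads}
#'   (\code{\link{generate_reads}} result).
#' @export
simulate_damid <- function(config, keep_events = FALSE) {
  g <- generate_genome(config)
  truth <- simulate_methylation(config, g$index, g$binding_sites,
                                g$open_tracts, keep_events = keep_events)
  reads <- generate_reads(truth, config, g$index)
  structure(list(config = config, genome = g$genome, index = g$index,
                 binding_sites = g$binding_sites,
                 open_tracts = g$open_tracts, truth = truth, reads = reads),
            class = "damid_sim")
}

#' @export
print.damid_sim <- function(x, ...) {
  print(x$config)
  print(x$truth)
  cat(sprintf("  %d read pairs (%d specific, %d non-specific, %d edge-dropped events)\n",
              nrow(x$reads$pairs), x$reads$n_specific, x$reads$n_nonspecific,
              x$reads$n_dropped_edge))
  invisible(x)
}

#' Write simulation outputs to a directory
#'
#' FASTA genome, BED binding sites and open tracts, SAM read pairs, TSV
#' truth counts and read labels, JSON config echo.
#'
#' @param sim A \code{\link{simulate_damid}} result.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "damid_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$genome), file.path(dir, "genome.fa"))
  ch <- names(sim$index$sites)[1L]
  if (length(sim$binding_sites))
    write.table(data.frame(ch, sim$binding_sites, sim$binding_sites + 1L),
                file.path(dir, "binding_sites.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (nrow(sim$open_tracts))
    write.table(cbind(ch, sim$open_tracts),
                file.path(dir, "open_tracts.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_sam(sim$reads$pairs, sim$index$chrom_lengths,
            file.path(dir, "reads.sam"),
            read_length = min(50L, sim$config$fragment_min))
  truth_df <- as.data.frame(sim$truth$truth_track)
  write.table(truth_df, file.path(dir, "truth_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$reads$pairs, file.path(dir, "read_labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(sim$config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
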