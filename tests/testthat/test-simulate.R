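no_tracts <- data.frame(start = integer(0), end = integer(0))

test_that("sim_config validates parameters and applies presets", {
  expect_error(sim_config(peak_amplitude = 1.5), "probability")
  expect_error(sim_config(background_open = 0.001, background_closed = 0.01),
               "background_open")
  expect_error(sim_config(genome_length = 5000), "10 kb")
  expect_error(sim_config(fragment_min = 300, fragment_max = 200), "fragment")
  wt <- sim_config(preset = "wild_type")
  mu <- sim_config(preset = "mutant")
  expect_equal(wt$decay_half_distance, 600)
  expect_equal(wt$processivity, 0.7)
  expect_equal(mu$decay_half_distance, 150)
  expect_equal(mu$processivity, 0.1)
  expect_gt(wt$background_open, mu$background_open)
  # explicit arguments override the preset
  over <- sim_config(preset = "wild_type", processivity = 0.2)
  expect_equal(over$processivity, 0.2)
})

test_that("generate_genome is deterministic and respects its contract", {
  cfg <- sim_config(genome_length = 1e5, n_binding_sites = 12, seed = 5)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$binding_sites, g2$binding_sites)
  expect_identical(g1$open_tracts, g2$open_tracts)
  # binding sites spaced >= 2 * lambda
  expect_true(all(diff(g1$binding_sites) >= 2 * cfg$decay_half_distance))
  # open tracts disjoint, cover all binding sites, area near phi * L
  tr <- g1$open_tracts
  expect_true(all(tr$start < tr$end))
  if (nrow(tr) > 1) expect_true(all(tr$start[-1] > tr$end[-nrow(tr)]))
  covered <- vapply(g1$binding_sites, function(b)
    any(b >= tr$start & b < tr$end), logical(1))
  expect_true(all(covered))
  area <- sum(tr$end - tr$start) / cfg$genome_length
  expect_gt(area, 0.5 * cfg$open_fraction)
  expect_lt(area, 2.0 * cfg$open_fraction)
})

test_that("generate_genome handles edge configurations", {
  closed <- generate_genome(sim_config(genome_length = 5e4, open_fraction = 0,
                                       n_binding_sites = 5, seed = 6))
  expect_identical(nrow(closed$open_tracts), 0L)
  expect_error(generate_genome(
    sim_config(genome_length = 1e4, n_binding_sites = 40,
               decay_half_distance = 600, seed = 6)), "infeasible")
})

test_that("seeding probability follows the binomial expectation at d = 0", {
  idx <- structure(list(sites = list(chrS = 1000L),
                        chrom_lengths = c(chrS = 10000L)),
                   class = "gatc_index")
  cfg <- sim_config(genome_length = 1e4, peak_amplitude = 0.3,
                    processivity = 0, background_open = 0,
                    background_closed = 0, n_cells = 10000,
                    n_binding_sites = 1, seed = 12)
  truth <- simulate_methylation(cfg, idx, binding_sites = 1000L, no_tracts)
  cnt <- truth$counts$chrS
  expect_lt(abs(cnt - 3000), 3 * sqrt(10000 * 0.3 * 0.7))
})

test_that("no amplitude and no background yields zero events", {
  idx <- lattice_index(500, spacing = 50L, chrom = "chrS")
  cfg <- sim_config(genome_length = 1e5, peak_amplitude = 0,
                    background_open = 0, background_closed = 0,
                    n_cells = 100, seed = 13)
  truth <- simulate_methylation(cfg, idx, integer(0), no_tracts)
  expect_true(all(truth$counts[[1]] == 0))
})

test_that("processive runs are geometric with the configured mean", {
  idx <- lattice_index(20000, spacing = 50L, chrom = "chrS")
  rho <- 0.8
  cfg <- sim_config(genome_length = 1e6, peak_amplitude = 0,
                    background_open = 5e-4, background_closed = 5e-4,
                    processivity = rho, n_cells = 60, seed = 14)
  truth <- simulate_methylation(cfg, idx, integer(0), no_tracts,
                                keep_events = TRUE)
  ev <- truth$events
  # run lengths of consecutive methylated site indices, per cell
  runs <- unlist(lapply(split(ev$site_index, ev$cell), function(s) {
    rle(cumsum(c(TRUE, diff(s) != 1L)))$lengths
  }), use.names = FALSE)
  # total run = 1 + Geom(left) + Geom(right); mean 1 + 2*rho/(1-rho) = 9
  m <- 1 + 2 * rho / (1 - rho)
  se <- sqrt(2 * rho / (1 - rho)^2) / sqrt(length(runs))
  expect_gt(length(runs), 300)
  expect_lt(abs(mean(runs) - m), 3 * se + 0.15) # slack for rare run merges
})

test_that("reads regenerate truth counts exactly at full capture", {
  cfg <- sim_config(genome_length = 2e5, n_binding_sites = 15, n_cells = 120,
                    capture_efficiency = 1, nonspecific_fraction = 0,
                    duplication_rate = 0, seed = 15)
  sim <- simulate_damid(cfg)
  expect_identical(sim$reads$n_dropped_edge, 0L)
  counted <- count_per_site(
    filter_alignments(sim$reads$pairs, sim$index)$reads, sim$index)
  expect_equal(unname(counted$counts[[1]]), unname(sim$truth$counts[[1]]))
  # every specific read's assigned site equals its true site
  cl <- classify_reads(sim$reads$pairs, sim$index)
  expect_identical(cl$site, cl$true_site)
})

test_that("capture efficiency thins reads binomially", {
  cfg1 <- sim_config(genome_length = 1e5, n_binding_sites = 10, n_cells = 200,
                     seed = 16)
  full <- simulate_damid(cfg1)
  n_events <- sum(full$truth$counts[[1]])
  cfg2 <- sim_config(genome_length = 1e5, n_binding_sites = 10, n_cells = 200,
                     capture_efficiency = 0.5, seed = 16)
  half <- simulate_damid(cfg2)
  n_reads <- nrow(half$reads$pairs)
  expect_lt(abs(n_reads - 0.5 * n_events), 3 * sqrt(n_events * 0.25))
})

test_that("a pure non-specific library passes the filter at the cut-origin rate", {
  cfg <- sim_config(genome_length = 2e5, n_binding_sites = 10, n_cells = 100,
                    nonspecific_fraction = 1, seed = 17)
  sim <- simulate_damid(cfg)
  expect_true(all(sim$reads$pairs$label == "nonspecific"))
  fl <- filter_alignments(sim$reads$pairs, sim$index)
  p <- site_density(sim$index)$per_bp_frequency
  n <- nrow(sim$reads$pairs)
  expect_lt(abs(fl$stats$retention - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("read generation is byte-identical under a fixed seed", {
  cfg <- sim_config(genome_length = 5e4, n_binding_sites = 5, n_cells = 50,
                    duplication_rate = 0.5, nonspecific_fraction = 0.2,
                    seed = 18)
  s1 <- simulate_damid(cfg)
  s2 <- simulate_damid(cfg)
  expect_identical(s1$reads$pairs, s2$reads$pairs)
  f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
  write_sam(s1$reads$pairs, s1$index$chrom_lengths, f1)
  write_sam(s2$reads$pairs, s2$index$chrom_lengths, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("surviving non-specific reads are uniform over cut origins", {
  cfg <- sim_config(genome_length = 1e6, n_binding_sites = 50, n_cells = 300,
                    nonspecific_fraction = 0.9, seed = 19)
  sim <- simulate_damid(cfg)
  cl <- classify_reads(sim$reads$pairs, sim$index)
  hits <- cl$site[cl$accepted & cl$label == "nonspecific"]
  # chi-square goodness of fit over 20 equal site-rank bins
  expect_gt(length(hits), 200)
  bin <- cut(match(hits, sim$index$sites[[1]]), breaks = 20)
  expect_gt(chisq.test(table(bin))$p.value, 0.01)
})

test_that("write_sim emits the full text bundle", {
  cfg <- sim_config(genome_length = 2e4, n_binding_sites = 3, n_cells = 20,
                    seed = 20)
  sim <- simulate_damid(cfg)
  d <- tempfile("simout")
  write_sim(sim, d)
  expect_true(all(file.exists(file.path(d, c(
    "genome.fa", "binding_sites.bed", "open_tracts.bed", "reads.sam",
    "truth_counts.tsv", "read_labels.tsv", "config.json")))))
  cfg_echo <- jsonlite::read_json(file.path(d, "config.json"))
  expect_equal(cfg_echo$seed, 20)
  idx2 <- gatc_index(file.path(d, "genome.fa"))
  expect_identical(idx2$sites, sim$index$sites)
  unlink(d, recursive = TRUE)
})
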