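# One small genome shared across filter tests: GATCs at known positions.
filter_genome <- function() {
  set.seed(11)
  s <- strsplit(strrep("A", 4000), "")[[1]]
  for (p in c(100L, 500L, 1000L, 2500L)) s[(p + 1):(p + 4)] <- c("G", "A", "T", "C")
  gatc_index(c(chrF = paste(s, collapse = "")))
}

test_that("classify_reads accepts exact cut origins and enumerates rejections", {
  idx <- filter_genome()
  pairs <- rbind(
    pair_at("chrF", 100L, "+"),                    # right flank
    pair_at("chrF", 500L, "-"),                    # left flank
    pair_at("chrF", 100L, "+", offset = 1L),       # 1 bp off
    pair_at("chrF", 1000L, "+", mapq = 5L),        # low mapq
    pair_at("chrF", 2500L, "+")
  )
  pairs$secondary <- c(FALSE, FALSE, FALSE, FALSE, TRUE)
  cl <- classify_reads(pairs, idx, mapq_min = 10)
  expect_identical(cl$accepted, c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(cl$site[1:2], c(100L, 500L))
  expect_identical(cl$flank[1:2], c("right", "left"))
  expect_identical(cl$reason[3:5], c("no_cut_site_match", "low_mapq", "secondary"))

  unk <- pair_at("chrZ", 100L, "+")
  expect_identical(classify_reads(unk, idx)$reason, "unknown_chrom")

  clip <- pair_at("chrF", 100L, "+", clip5 = TRUE)
  expect_identical(classify_reads(clip, idx)$reason, "no_cut_site_match")
})

test_that("slack matching accepts near-miss origins and assigns the nearest site", {
  idx <- filter_genome()
  off <- pair_at("chrF", 100L, "+", offset = 2L)
  expect_false(classify_reads(off, idx)$accepted)
  cl <- classify_reads(off, idx, slack = 2)
  expect_true(cl$accepted)
  expect_identical(cl$site, 100L)
})

test_that("filter_alignments reports retention and handles the empty stream", {
  idx <- filter_genome()
  empty <- classify_reads(pair_at("chrF", 100L, "+")[0, ], idx)
  fl <- filter_alignments(empty, idx)
  expect_identical(fl$stats$aligned_pairs, 0L)
  expect_true(is.nan(fl$stats$retention))
  expect_identical(nrow(fl$reads), 0L)

  seven <- do.call(rbind, lapply(1:7, function(i)
    pair_at("chrF", c(100L, 500L, 1000L, 2500L)[(i %% 4) + 1],
            if (i %% 2) "+" else "-", mate = 300L + i)))
  fl7 <- filter_alignments(seven, idx)
  expect_identical(fl7$stats$passing_pairs, 7L)
  expect_equal(fl7$stats$retention, 1.0)
})

test_that("filtering already-filtered reads changes nothing", {
  cfg <- sim_config(genome_length = 1e5, n_binding_sites = 8, n_cells = 60,
                    seed = 21)
  sim <- simulate_damid(cfg)
  fl1 <- filter_alignments(sim$reads$pairs, sim$index)
  fl2 <- filter_alignments(pairs_from_reads(fl1$reads), sim$index)
  expect_equal(fl2$stats$retention, 1.0)
  expect_identical(fl2$reads$site, fl1$reads$site)
  expect_identical(fl2$reads$flank, fl1$reads$flank)
})

test_that("retention on a half-specific library matches the analytic expectation", {
  cfg <- sim_config(genome_length = 2e5, n_binding_sites = 20, n_cells = 150,
                    nonspecific_fraction = 0.5, seed = 31)
  sim <- simulate_damid(cfg)
  fl <- filter_alignments(sim$reads$pairs, sim$index)
  dens <- site_density(sim$index)$per_bp_frequency
  n <- nrow(sim$reads$pairs)
  expected <- 0.5 + 0.5 * dens
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(fl$stats$retention - expected), 3 * se)
  # every simulator-labelled specific read passes; survivors among the
  # non-specific are exactly those hitting a valid cut origin
  cl <- classify_reads(sim$reads$pairs, sim$index)
  expect_true(all(cl$accepted[cl$label != "nonspecific"]))
  ns_pass <- cl$accepted[cl$label == "nonspecific"]
  se_ns <- sqrt(dens * (1 - dens) / length(ns_pass))
  expect_lt(abs(mean(ns_pass) - dens), 3 * se_ns)
})

test_that("unique_tagmentation_fraction counts distinct tuples", {
  r3 <- data.frame(chrom = "chrF", site = 100L, flank = "right",
                   tagmentation_pos = 400L)[rep(1, 3), ]
  expect_equal(unique_tagmentation_fraction(r3), 1 / 3)
  expect_identical(nrow(dedup_tagmentation(r3)), 1L)
  rd <- data.frame(chrom = "chrF", site = c(100L, 100L, 500L),
                   flank = c("right", "left", "right"),
                   tagmentation_pos = c(400L, 400L, 900L))
  expect_equal(unique_tagmentation_fraction(rd), 1.0)
  expect_true(is.nan(unique_tagmentation_fraction(rd[0, ])))
})

test_that("PCR duplication shifts tagmentation uniqueness as expected", {
  # each fragment emitted 1 + Poisson(1) times: E[total] = 2 E[fragments]
  cfg <- sim_config(genome_length = 1e5, n_binding_sites = 10, n_cells = 400,
                    duplication_rate = 1, seed = 41)
  sim <- simulate_damid(cfg)
  fl <- filter_alignments(sim$reads$pairs, sim$index)
  n_frag <- sum(sim$reads$pairs$label == "specific")
  f <- fl$stats$unique_tagmentation_fraction
  # fraction ~ n_frag / total; 3 SE from Var(total) = n_frag * Var(Pois(1))
  expect_gt(n_frag, 1000)
  expect_lt(abs(f - 0.5), 3 * 0.5 / sqrt(n_frag) + 0.01)
})

test_that("count_per_site pools flanks and conserves reads", {
  idx <- filter_genome()
  reads <- data.frame(
    chrom = "chrF",
    site = c(rep(100L, 5), 500L),
    flank = c("left", "left", "right", "right", "right", "left"),
    tagmentation_pos = c(401:405, 900L)
  )
  tr <- count_per_site(reads, idx)
  expect_equal(tr$counts$chrF[idx$sites$chrF == 100L], 5)
  expect_equal(tr$counts$chrF[idx$sites$chrF == 500L], 1)
  expect_equal(total_counts(tr), nrow(reads))

  zero <- count_per_site(reads[0, ], idx)
  expect_true(all(unlist(zero$counts) == 0))

  bad <- data.frame(chrom = "chrF", site = 123L, flank = "right",
                    tagmentation_pos = 1L)
  expect_error(count_per_site(bad, idx), "consistency")
})

test_that("count conservation holds in both dedup modes", {
  cfg <- sim_config(genome_length = 1e5, n_binding_sites = 10, n_cells = 200,
                    duplication_rate = 0.7, seed = 51)
  sim <- simulate_damid(cfg)
  fl <- filter_alignments(sim$reads$pairs, sim$index)
  raw <- count_per_site(fl$reads, sim$index, "raw")
  ded <- count_per_site(fl$reads, sim$index, "unique_tagmentation")
  expect_equal(total_counts(raw), nrow(fl$reads))
  expect_equal(total_counts(ded), length(unique(
    paste(fl$reads$chrom, fl$reads$site, fl$reads$flank,
          fl$reads$tagmentation_pos))))
  expect_true(total_counts(ded) <= total_counts(raw))
})

test_that("SAM output round-trips through the BAM reader", {
  cfg <- sim_config(genome_length = 5e4, n_binding_sites = 5, n_cells = 40,
                    seed = 61)
  sim <- simulate_damid(cfg)
  sam <- tempfile(fileext = ".sam")
  write_sam(sim$reads$pairs, sim$index$chrom_lengths, sam)
  back <- read_alignment_pairs(sam)
  expect_equal(nrow(back), nrow(sim$reads$pairs))
  o1 <- order(sim$reads$pairs$qname)
  o2 <- order(back$qname)
  expect_identical(back$read1_5prime[o2], sim$reads$pairs$read1_5prime[o1])
  expect_identical(back$mate_5prime[o2], sim$reads$pairs$mate_5prime[o1])
  expect_identical(back$strand[o2], sim$reads$pairs$strand[o1])
  # counts from the file equal counts from the in-memory pairs
  t1 <- count_per_site(filter_alignments(back, sim$index)$reads, sim$index)
  expect_equal(unname(t1$counts[[1]]), unname(sim$truth$counts[[1]]))
  unlink(sam)
})

test_that("bedGraph track output round-trips against the index", {
  cfg <- sim_config(genome_length = 5e4, n_binding_sites = 5, n_cells = 40,
                    seed = 71)
  sim <- simulate_damid(cfg)
  bg <- tempfile(fileext = ".bedGraph")
  write_track_bedgraph(sim$truth$truth_track, bg)
  tr <- read_track_bedgraph(bg, sim$index)
  expect_equal(tr$counts, sim$truth$truth_track$counts)
  unlink(bg)
})
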