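# gatcseq — single-GATC resolution DamID-seq analysis

DamID maps protein–DNA interactions by tethering the *E. coli* adenine
methyltransferase Dam to a protein of interest: wherever the fusion binds,
nearby **GATC** tetramers acquire N6-adenine methylation. Low-processivity
Dam mutants make that methylation focal enough that the natural readout is
no longer a broad peak but a count at each individual GATC. This package is
the computational side of that readout, for genomics researchers analysing
DamID-seq of transcription factors (or validating constructs by qPCR):

* **Cut-site index.** DpnI cleaves every methylated GATC between the A and
  T (GA^TC, blunt). `gatc_index()` locates every site in a FASTA reference
  (0-based; a site is the position *p* of its G), and `locate_cut()` maps a
  read-one 5′ origin to a site flank: forward reads start at *p*+2 (right
  flank), reverse reads have their 5′ base at *p*+1 (left flank).
* **Cut-site filter and per-GATC counts.** In the sequencing protocol, an
  adapter is ligated directly onto DpnI blunt ends and a second adapter is
  placed nearby by Tn5 tagmentation, so read one of every genuine fragment
  begins exactly at a cut. `filter_alignments()` removes everything else
  (non-specific ligation onto broken ends), `count_per_site()` sums the
  survivors per site, and `unique_tagmentation_fraction()` uses the random
  tagmentation end to tell independent methylation events from PCR
  duplicates.
* **Cross-sample comparison.** Pearson correlation over all genomic GATCs
  (`correlate_samples()`), depth-scaled log2 normalisation to an unfused
  Dam control (`normalize_to_control()`), ranked top sites and signal
  matrices around them (`top_sites()`, `signal_matrix()`).
* **Spatial resolution.** `decay_profile()` averages methylation in 20 bp
  windows by distance from binding-peak midpoints; `half_decay_distance()`
  — the distance at which the smoothed profile first falls to half its
  midpoint value — is the resolution metric, with `residual_fraction()`
  and genome-wide `binned_autocorrelation()` as companions.
* **Locus-specific qPCR.** After parallel DpnI / DpnII digests, the
  methylated fraction at a site is `1 / (1 + 2^(c_II − c_I))` from the two
  cycle counts; `summarize_qpcr()` turns replicate tables into site and
  class summaries and positive/negative fold enrichment.
* **Generative simulator.** `simulate_damid()` models the whole assay —
  focal methylation decaying exponentially with distance from planted
  binding sites, processive extension across adjacent GATCs, elevated
  open-chromatin background, saturation across cells, fragment-length
  draws, PCR duplicates and non-specific reads — and carries ground-truth
  labels through to aligned read pairs, so every pipeline stage is testable
  against truth.

## Worked example

Simulate a small experiment, run the pipeline, and measure resolution:

```r
library(gatcseq)

cfg   <- sim_config(genome_length = 2e5, n_binding_sites = 15,
                    n_cells = 150, seed = 42)
sim   <- simulate_damid(cfg)
fl    <- filter_alignments(sim$reads$pairs, sim$index)
track <- count_per_site(fl$reads, sim$index, sample = "demo", stats = fl$stats)
track
#> GATC count track 'demo': 836 sites, 1,368 reads (179 sites non-zero), mode=raw
#>   retention 1.000 (1368/1368), unique tagmentation 0.990

peaks <- data.frame(chrom = "chrSim", start = sim$binding_sites,
                    end = sim$binding_sites + 1L)
prof  <- decay_profile(track, peaks, bin_width = 20, max_dist = 2000)
half_decay_distance(prof)   # 201.3 bp
residual_fraction(prof, 1000)  # 0.0304
```

Every read passed the filter because this library contains no non-specific
reads (`nonspecific_fraction = 0`); with real libraries the retention
statistic is the first quality check. The half-decay of ~200 bp reflects
the planted 150 bp kernel plus the small upward bias of binning, smoothing
and mild processive spreading — see the vignette
(`vignettes/single-gatc-damid.Rmd`) for the estimator's behaviour and the
simulator's model.

The qPCR estimator, on a replicate table of DpnI/DpnII cycle counts:

```r
cycles <- data.frame(
  site_label = rep(c("p1", "p2", "n1", "n2"), each = 3),
  class      = rep(c("positive", "positive", "negative", "negative"), each = 3),
  replicate  = 1:3, c_I = 22,
  c_II       = 22 + rep(log2(1 / c(0.42, 0.38, 0.018, 0.012) - 1), each = 3))
summarize_qpcr(cycles)
#> qPCR methylation summary
#>   negative class mean fraction 0.015
#>   positive class mean fraction 0.4
#>   fold enrichment (positive/negative): 26.7
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/gatcseq.R` (subcommands `index`, `count`, `qpcr`, `decay`,
`autocorr`, `simulate`).

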