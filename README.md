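# tn5prefer

Measure, dissect and correct the insertion preference of the Tn5 transposase.

## Who this is for

Tn5 tagmentation underlies ATAC-seq and most modern accessibility assays, but
the enzyme is not a neutral probe: on naked DNA it favors particular
nucleotide compositions (a ~9-bp core motif with G/C-preferred edges),
particular DNA shapes, and — context-dependently — methylated cytosines. Anyone
quantifying chromatin accessibility from Tn5 cut-site density inherits this
bias. `tn5prefer` is an R package for epigenomics analysts who want to
(1) quantify that preference in their own data, (2) attribute it to motif,
shape, nucleotide-dependence or methylation, and (3) remove it from
single-base insertion signal before downstream analysis.

## What it computes

* **Insertion sites from fragments** — the +4/−5 shift onto the center of the
  9-bp target-site duplication; paired-fragment selection (two adjacent
  fragments overlapping by exactly 9 bp evidence one insertion event).
* **Feature enrichment** — per feature set,
  `E = feature length × (total sites / mappable genome size)`,
  `log2(O/E)`, a two-cell chi-square goodness of fit (df = 1) and
  Benjamini–Hochberg FDR (< 0.001), plus complete-linkage sample clustering.
* **The Tn5 motif** — a PWM from center-aligned windows around insertion
  sites; genome-wide scanning with *exact* p-values (dynamic programming over
  a discretized score grid) and BH q-values (< 0.001); the
  inside/outside × used/unused taxonomy of sites and motif hits.
* **Feature encodings** — 14 DNA-shape vectors via sliding-pentamer lookup
  (with seeded shuffled-table controls), per-position PWM score vectors, and
  mono/di/trinucleotide one-hot vectors over 51-bp windows.
* **Elastic-net classification** — penalized logistic regression (10-fold CV,
  features min–max standardized to [0, 1], accuracy =
  (TP+TN)/(TP+TN+FP+FN)) separating insertion sites from random genomic
  controls, with shuffled-sequence / shuffled-table negative controls,
  cross-sample 70/30 transfer, and coefficient-importance maps.
* **Context-dependent methylation analysis** — 9-bp genome tiling, four-group
  two-condition classification (A-only / B-only / Both / None), per-9-mer
  insertion averaging, the shared-9-mer filter, per-condition Z-scaling, and
  the 11-level methylation stratification.
* **k-mer bias correction** — per-context insertion rates
  (`scale = mean rate / context rate`, default k = 19, maskable), corrected
  single-base tracks with exact conservation of total signal.
* **Synthetic data with planted truth** — genomes, insertion events,
  methylation tracks and fragment pairs whose motif / dinucleotide /
  methylation preference is known exactly, so every stage is testable by
  parameter recovery.

## A worked example

Simulate a 100-kb genome with a planted Tn5-like motif (1 250 embedded
consensus instances, moderate energy weight), rebuild the motif from the
sampled insertion sites, scan the genome, and correct the signal:

```r
library(tn5prefer)

cfg <- sim_config(genome_length = 100000, planted_pwm = default_planted_pwm(),
                  motif_weight = 0.6, n_insertions = 20000,
                  n_planted_motifs = 1250, seed = 1)
genome <- simulate_genome(cfg)
ins <- simulate_insertions(genome, cfg)
nrow(ins$sites)
#> [1] 10781

pwm <- build_pwm(ins$sites, genome, window = 9)
pwm
#> tn5_pwm: width 9 consensus GCATATAGC

hits <- scan_pwm(pwm, genome, q_threshold = 0.001)
nrow(hits)
#> [1] 1251
usage <- usage_summary(merge_site_strands(ins$sites), hits)
round(unlist(usage), 3)
#>  frac_insert_inside frac_insert_outside     frac_motif_used   frac_motif_unused
#>               0.165               0.835               0.998               0.002

model <- build_bias_model(ins$sites, genome, k = 7)
corrected <- correct_signal(ins$sites, model, genome)
c(raw = sum(ins$sites$count), corrected = round(sum(corrected$value), 4))
#>       raw corrected
#>     20000     20000
```

Reading the numbers: 20 000 insertion events land on 10 781 distinct sites;
the PWM rebuilt from center-aligned windows recovers the planted consensus
`GCATATAGC`; the genome scan finds the 1 250 embedded instances (plus one
background hit) at q < 0.001; 16.5% of insertion events fall inside predicted
motifs while 99.8% of motif instances are used — the real-data regime in which
the motif is *necessary but far from sufficient* to explain where Tn5 cuts.
The k-mer-corrected track conserves the raw signal total exactly.

The end-to-end demonstration (2-Mb AT-rich genome, 100 000 insertions, all
stages, deterministic outputs) is one call:

```r
res <- run_pipeline(run_demo_config(seed = 1), "demo_out")
```

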