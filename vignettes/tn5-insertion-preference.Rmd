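---
title: "Dissecting and correcting Tn5 insertion preference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting and correcting Tn5 insertion preference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tn5prefer)
```

# The problem

Tn5 transposase, the enzyme behind ATAC-seq and most tagmentation protocols,
does not cut naked DNA uniformly. Its insertion events are biased by the local
nucleotide composition (a roughly 9-bp core motif with G/C favored at the
edges), by the physical shape of the DNA (minor groove width, propeller twist,
roll, helix twist and the other pentamer-derived descriptors), and —
context-dependently — by cytosine methylation. Because chromatin accessibility
is read off the *density of Tn5 insertion events*, this intrinsic preference
contaminates every downstream quantity: feature-level enrichment, footprints,
and peak calls.

`tn5prefer` implements the full chain of analyses needed to measure this
preference and to remove it from single-base signal, plus a synthetic-data
generator with *planted, known* preference structure, so that every stage can
be validated by parameter recovery rather than by eyeballing.

# The model, stage by stage

## From fragments to insertion-event centers

Tn5 transposition duplicates a 9-bp target site. The center of that
duplication is recovered from a sequenced fragment by shifting the forward
5' end by +4 bp and the reverse end by −5 bp (on half-open coordinates both
shifted ends of one event coincide). `shift_fragments()` applies this rule and
rejects fragments shorter than 9 bp, which cannot span a full duplication.

Two adjacent fragments whose coordinates overlap by *exactly* 9 bp evidence a
single insertion event seen from both sides; `paired_fragment_sites()` selects
these high-confidence events. Only the coordinate criterion is enforced: for
double-stranded coordinates reverse complementarity of the overlap is
automatic. All internal coordinates are 0-based half-open (BED convention) —
the +4/end−5 arithmetic is self-consistent only under one fixed convention.

## Feature enrichment

For each genomic feature set, the expected insertion count under uniformity is

```
E = merged feature length × (total insertion sites / mappable genome size)
```

and the observed count `O` is summed from strand-merged site counts inside the
merged intervals. Each feature is tested with a two-cell (inside/outside)
chi-square goodness of fit on one degree of freedom — the minimal
goodness-of-fit consistent with one `O/E` pair per feature — and p-values are
Benjamini–Hochberg adjusted across the features of a sample, with
significance at FDR < 0.001. `log2(O/E)` is the enrichment statistic
(positive = enrichment). Overlapping intervals are merged before measuring so
nothing is double counted; no continuity correction is applied by default
(counts are large in intended use; a Yates flag exists for small toys).
Sample-by-feature matrices are ordered by complete-linkage clustering on
Euclidean distance between sample rows; clustering uses the unmasked values,
because distances over NA-masked rows are undefined, and the significance mask
is applied to the returned display matrix only.

## The Tn5 motif

Because windows are center-aligned at the insertion-event center, the PWM is
estimated by direct positional base frequencies over fixed-width windows —
there is no alignment or discovery step left for an EM motif finder to do, so
this is a deliberate simplification of running a motif-discovery tool on the
same windows. Sites recorded on the '−' strand contribute the reverse
complement of their window; strand-merged sites contribute the forward window.
The default background is the genome base composition, and a pseudocount
(default 1) keeps log-odds finite.

`scan_pwm()` scores every window on both strands with the log2-odds score and
computes, for each score, the *exact* tail probability under the i.i.d.
background model via dynamic programming on a discretized score grid (the
grain defaults to 1e−4 of the score range; the same integer grid is used for
scanning and for the null distribution, so the p-values are exact for the
scores actually assigned). Benjamini–Hochberg q-values are computed over all
scanned windows and hits are reported at q < 0.001. Width is capped at 30,
where the DP stays cheap at the default grain.

A practical note baked into the synthetic generator: on an i.i.d. random
genome a genome-wide scan correctly finds *nothing* at q < 0.001 — there is no
enrichment of high-scoring windows above the null, so BH cannot call any hit.
Real genomes contain abundant motif occurrences. The generator therefore
supports embedding consensus motif instances (`n_planted_motifs`), which
reproduces the real-data regime in which a minority of insertion events fall
inside predicted motifs while a large fraction of predicted motifs are used.

## Feature encodings and the classification framework

The quantitative dissection asks: how well do motif, shape, or plain
nucleotide-dependence encodings of the 51-bp window around a site separate
insertion sites from random genomic controls?

* **motif vector** — the per-position log2-odds of the observed base under a
  51-bp-wide PWM (51 values; summing them gives the full-window scan score,
  an identity used as a cross-module test). Per-position log-odds was chosen
  over column probabilities as the natural additive decomposition of the scan
  score.
* **shape vectors** — for each of the 14 pentamer-table shapes, one value per
  position with a full pentamer context (47 values per shape for a 51-bp
  window; 658 features). Intra-base-pair shapes use the pentamer value
  directly; inter-base-pair (step) shapes average the two central step values
  of the pentamer so all shapes yield equal-length, center-aligned vectors.
  Window edges without a pentamer are dropped, not imputed — imputation would
  inject information the encoding does not define.
* **k-mer one-hot** — mono-, di-, and trinucleotide indicators per start
  position (51×4, 50×16, 49×64 columns), stored sparse.
* **methylation vector** (optional) — per-position percent methylation.

Rows are sites (label 1) then controls (label 0); every feature is min–max
standardized to [0, 1] — shapes, log-odds and indicators live on incomparable
scales, and the [0, 1] range makes absolute coefficients comparable as
importance measures. Bounds are stored so held-out data can be standardized
with the *training* bounds. N-containing windows are dropped (shape and PWM
tables are undefined on N).

The classifier is an elastic-net penalized logistic regression: alpha defaults
to 0.5 (an even L1/L2 mix, exposed as an argument since nothing pins it),
lambda is selected on a 50-value grid spanning four decades below the smallest
all-zero lambda, at minimum 10-fold cross-validated deviance, with the fold
assignment seeded. Features are *not* re-standardized internally — only the
explicit [0, 1] scaling is applied, so coefficients stay interpretable.
Reported accuracy is `(TP + TN) / (TP + TN + FP + FN)` at probability
threshold 0.5, computed from the prevalidated CV predictions (each row is
predicted by the fold model that did not see it). Classes are balanced by
construction (equal site and control counts), so no reweighting is applied. A
fully degenerate design (all features constant) short-circuits to an
intercept-only majority-rate fit.

Negative controls mirror the design of the study this reproduces: shuffling
each window's characters destroys positional information while keeping
composition; shuffling the pentamer shape table (a seeded permutation of the
1024 pentamer values, multiset preserved exactly) destroys the
sequence–shape relationship while keeping the value distribution.
Coefficient importance is summarized by `importance_map()` as absolute
coefficients summed per parameter (row) and per window position (column).

## The context-dependent methylation procedure

The genome is tiled into 9-bp bins. Per condition, bin methylation is the
unweighted mean percent methylation over covered cytosines — bins with no
covered cytosine are *absent*, not zero, so bisulfite coverage gaps cannot
masquerade as unmethylated DNA (the unweighted mean was chosen because a
coverage-weighted mean is not defined for percent-only tracks). Bins eligible
in both conditions are classified into four groups by the literal > 0 / = 0
rule: A-only, B-only, Both, None. Insertion frequency is averaged per unique
9-mer within each group, 9-mers that do not occur in *all four* groups are
dropped (equalizing sequence context across groups), and the retained means
are Z-scaled per condition so insertion frequencies from differently sized
libraries are comparable. 9-mers are not reverse-complement collapsed — no
collapsing rule is defined for this procedure — and raw within-condition
counts are used as insertion frequency, since the per-condition Z-score
absorbs library scale.

The 11-level stratification puts exactly-unmethylated bins (mean 0%) in level
0 and splits (0, 100] into ten equal-width left-open levels — the only reading
consistent with an unmethylated class plus methylated levels 1–10. Boxplot
summaries use the standard 1.5 × IQR whisker rule, and exports can trim the
top and bottom 1% of the heavily skewed count distributions.

## k-mer bias model and signal correction

For every (optionally masked) k-mer context centered on a genome position,

```
rate(w)  = (site counts with context w + pseudocount) /
           (genome occurrences of w + pseudocount)
scale(w) = mean rate / rate(w)
```

and the corrected value at a site is its raw count times the scale of its
context, after which the whole track is rescaled so the corrected total equals
the raw total — downstream tools are sensitive to global depth, so
conservation preserves threshold semantics. Contexts are the '+'-strand k-mer
at the strand-merged position (corrected tracks are strand-merged signals);
k defaults to 19, reflecting the observation that a 19-bp window around the
duplication carries preference information. Contexts are stored sparsely
(observed k-mers only): a full 4^19 table is neither feasible nor necessary.
On desk-scale genomes a 19-bp full mask makes nearly every context unique —
the scale table then just memorizes the data — so the demonstration uses
k = 7, and spaced masks (`X`/`.` strings) are supported for larger k. The
pseudocount defaults to 0.5 to keep rare-context scales defined. An all-dot
mask collapses every position into one context, making correction the
identity — a useful null. The normalization here (rate-ratio scaling with
conservation) is this package's own definition of the k-mer correction idea.

# The synthetic-data generator

`simulate_insertions()` draws insertion events multinomially (with
replacement, so multi-count sites occur, as in real pileups) from a
per-position propensity

```
propensity(i) ∝ exp( motif_weight · s_pwm(i)
                   + Σ dinucleotide step weights over the 19-bp window
                   + methylation_effect · meth(i)/100 )
```

where `s_pwm` is the natural-log odds score of a planted PWM centered at `i`.
The exact propensity vector is recorded as ground truth. Three properties make
the generator a useful oracle:

* With `motif_weight = 1` and the PWM background equal to the genome
  composition, the column distributions of sampled windows equal the planted
  PWM columns, so `build_pwm()` recovers the planted matrix exactly in
  expectation — the basis of the parameter-recovery tests.
* The dinucleotide term mirrors the finding that adjacent-base dependence can
  mimic shape information: the bundled synthetic shape table is itself built
  from dinucleotide step parameters (plus a small pentamer-specific term), so
  planting its step weights creates signal a *true*-table encoding can read
  and a *shuffled*-table encoding cannot.
* One master seed fans out to fixed per-stage child seeds, so stages are
  independently reproducible.

What the generator deliberately does **not** emulate: nucleosomes and
chromatin structure, PCR duplicates and sequencing error, mappability
artifacts, repeat families, and genome-scale 9-mer recurrence. Passing tests
therefore demonstrate the *statistical machinery* is correct and recovers
planted structure; they do not certify effect sizes on real chromatin.

Two desk-scale accommodations are worth stating plainly. First, the shipped
pentamer shape table is synthetic (generated in code, labelled as such);
its values do not reproduce any published table, but its
dinucleotide-dominated structure reproduces the property that matters for the
analyses. Published tables can be dropped in via `read_shape_table()`. Second,
the context-dependent methylation procedure needs 9-mers to recur across
groups, which at genome scale is guaranteed by sheer bin count; at desk scale
the demonstration uses an AT-rich (80% AT), low-complexity genome — the
regime of the most AT-rich genomes Tn5 has been profiled on — to obtain
recurring 9-mers from a 2-Mb simulation.

# Numerical choices and degenerate inputs

* Scan p-values: score grain = 1e−4 of the score range; DP and scanning share
  one integer grid; BH family = all scanned windows on both strands.
* Chi-square enrichment: features with `E = 0` or `E = total` are reported
  untestable (NA) and excluded from the BH family.
* Min–max standardization: zero-variance features map to 0 with a warning and
  degenerate bounds are recorded.
* Subsampling ties: sites are sampled without replacement under a child seed
  and re-sorted by position, so output is order-deterministic.
* Empty hit sets: insertion-inside fraction is 0 and motif-usage fractions are
  reported absent (NA) rather than 0/0.
* Bins whose 9-mer contains N are dropped; sites whose context crosses a
  contig edge are excluded from both numerator and denominator of the bias
  model and emitted uncorrected (flagged) by `correct_signal()`.

# Problem sizes used in the shipped validation

The test-suite and acceptance-script simulations use 100-kb to 2-Mb genomes,
20 000–120 000 insertion events, 20 000 + 20 000 training rows with 10-fold
CV, and k = 7 bias contexts — sizes chosen so the full validation runs on a
laptop-class single core in minutes while keeping every estimate comfortably
inside its tolerance (for example, planted-PWM recovery lands near 0.01
total-variation distance against a 0.05 bound).

# Limitations

* The elastic-net solver is `glmnet`; the module contract (penalized logistic
  likelihood, seeded folds, deviance-minimizing lambda) is what the package
  guarantees, not a particular solver path.
* MEME/FIMO-compatible behavior is limited to center-aligned PWM building,
  exact-p scanning and q-value thresholding; no de novo discovery.
* Peak calling, alignment, duplicate marking and bisulfite processing are out
  of scope; the correction module emits signal for external peak callers and
  `compare_interval_sets()` partitions their outputs (≥ 1 bp overlap =
  shared).
* Cross-sample validation assumes samples share an encoding window and
  feature blocks; it applies training-set standardization bounds to held-out
  encodings, as any honest transfer evaluation must.
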