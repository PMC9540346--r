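---
title: "Methods: calling and decoding regeneration-responsive enhancers"
author: "regenhancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling and decoding regeneration-responsive enhancers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

During zebrafish inner-ear hair-cell regeneration, support cells (SC),
progenitor cells (PC) and nascent hair cells (HC) open thousands of new
chromatin regions. regenhancer implements the downstream computational
pipeline for such an experiment: it takes differential single-cell ATAC
peaks from regenerating and untreated tissue, calls
*regeneration-responsive elements* (RREs, peaks present only during
regeneration), links them to differentially expressed (DE) genes, tests the
overlap statistics, learns sequence grammar with a small convolutional
network, and classifies enhancers by their Sox/Six motif content.
Every stage can be exercised against synthetic data with a known truth
manifest, which is how the test suite validates parameter recovery.

# Differential accessibility

Per peak, cells of two groups are compared with a two-sided Wilcoxon
rank-sum test: midranks for ties, tie-corrected variance, 0.5 continuity
correction — numerically identical to `wilcox.test(exact = FALSE, correct =
TRUE)`. A peak passes when `p < 0.1`, `avg_log2FC >= 0.25` and `max(pct1,
pct2) >= 0.025` (detection in either group). The fold change is
`log2((mean1 + 1)/(mean2 + 1))` on raw counts: the pseudocount keeps it
finite at zero counts and monotone in the data; no exact equality with any
external tool's internal formula is claimed. Raw p-values are filtered
without multiple-testing correction, deliberately: the pass filter is a
screening step whose false positives are later removed by the
shared-peak subtraction.

A caveat established during testing: for the very smallest groups (2v2,
2v3) or heavily tied tiny samples, the normal approximation deviates from
the exact permutation p by more than 0.05 (2v2 extreme case: exact 1/3,
approximation 0.245). This is a property of the approximation itself, not
of the implementation; agreement with enumeration within 0.05 holds for
untied data at group sizes >= 3.

# RRE calling

Peaks are matched by **center distance**: two peaks correspond when their
centers lie within d = 100 bp on the same chromosome (the merge distance of
the standard peak-merging tools; whether the original analysis used center
or edge distance is not documentable, so center semantics were chosen and
are stated here). Emerging peaks are treated-condition peaks with no
control-condition center within d. Organ sets (saccule, utricle) are
combined by collapsing connected components of the proximity graph to the
peak with the smallest p-value. The Venn partition across cell types also
uses connected components, which makes membership independent of input
order; on sorted centers, components are exactly maximal runs with
consecutive gaps <= d, which is what the implementation exploits. All of it
is tested against an all-pairs O(N^2) oracle.

# Peak-to-gene linking and enrichment

Gene windows are gene bodies extended 50 kb on each side (strand-swapped
for asymmetric extensions, though the default is symmetric), clipped at
chromosome ends. A link requires >= 1 bp overlap between peak and window
under the 0-based half-open convention — bookended intervals do not touch.

Overlap significance uses the upper-tail hypergeometric probability
P(X >= m) with a universe of n genes (default 25,592, the GRCz11
coding-gene count; synthetic runs pass their own universe). It is computed
as a log-space sum of exact log-binomial terms, so results like
log10 p = -310 are returned exactly where a difference of `phyper` CDFs
underflows to zero. Equality with the CDF-difference form is unit-tested at
moderate p, and with `phyper(log.p = TRUE)` at the extremes.

# The synthetic world

The generator emits everything the pipeline reads, with ground truth:

* **Genome**: 10 chromosomes x 2 Mb, 150 genes of 1-5 kb placed uniformly
  without overlap. The density (1 gene / 130 kb) is deliberately sparse
  enough that ±50 kb windows do not tile the genome; with a denser first
  draft (400 genes / 10 Mb) ~95% of RREs were DE-linked and the CNE
  concentration test was nearly vacuous. Real vertebrate proportions leave
  a proper subset, and so does this world (~60% of RREs DE-linked).
* **Peaks**: 300 shared + 40 emerging per cell type (SC, PC, HC), widths
  200-500 bp, centers >= 250 bp apart; 60% of emerging peaks are placed
  within 50 kb of a gene body.
* **Counts**: Poisson per cell per peak. Background rate 0.5 per cell;
  emerging peaks draw rate 0.5 x 4 in treated cells and 0.05 x background
  in control cells (never exactly zero, keeping the rank test
  non-degenerate). Poisson rather than negative binomial: the Wilcoxon
  stage is rank-based, so overdispersion adds nothing to the tested
  surface. The real control-count distribution is unknown; this is a
  stand-in, not an inference.
* **DE genes**: genes within 50 kb of an emerging peak become DE with
  probability 0.6 (mirroring the ~60% linkage the source experiments
  report), all others with probability 0.05.
* **CNEs**: half of the emerging peaks receive an overlapping conserved
  element, chosen preferentially among DE-linked peaks — conservation is
  modelled as concentrating on functional enhancers, which is exactly the
  alternative hypothesis the CNE enrichment test must be able to detect.
* **Sequence elements**: one 400 nt element per emerging peak (order-0
  background, GC 0.40). With probability 0.9 a positive receives the
  co-occurring Sox-like/Six-like pair at start-to-start distance <= 60 bp,
  and independently (same probability) exactly one of two decoy motifs
  (Fox-like or Gata-like) — never both, so the decoy pair is structurally
  non-co-occurring. All instances lie inside the central 300 bp. The plant
  frequency of 0.9 encodes the assumption that called enhancers are
  *selected for* motif content; it was fixed a priori because a mostly
  background positive set cannot support the module's stated recovery
  contracts. Motifs are 9 bp, dominant base probability 0.85 (~10.4 bits).

Identical config + seed produces byte-identical files; every stage derives
a private RNG stream from the master seed.

What a green recovery test does **not** establish: robustness to
overdispersed counts, to correlated cells, to fragment-model artifacts, to
motif families with variable spacing or width, or to real-genome sequence
composition. The world is intentionally the simplest one in which each
stage's contract is falsifiable.

# The enhancer CNN

The classifier is the fixed four-convolutional-layer network with exactly
59,785 trainable parameters: input 4 x 300 one-hot (central 300 bp of each
400 bp element, 50 bp ends excluded); conv1 64 filters of width 9, stride 3
(the de novo motif layer: 64 is the motif cap, the 9-mer window and 3 bp
step define motif sites); three k2/s2 max pools around conv2/conv3 (64
filters, width 5) and conv4 (8 filters, width 5); global max pool; dense
8 -> 1376 -> 1 with a sigmoid. The odd 8 -> 1376 expansion is an artifact
of matching the printed parameter count and is treated as pinned. Valid
(unpadded) convolutions reproduce the documented conv3 geometry: 18 units,
each seeing 90 bp of input with a 12 bp jump (receptive-field recurrence
9 + 1·3 + 4·6 + 1·6 + 4·12 = 90, jump 3·2·2 = 12), verified empirically by
perturbation.

Training is from scratch — no pretrained accessibility features are in
scope — with binary cross-entropy, AdamW (lr 1e-3, decoupled weight decay
1e-4), batch 64, up to 30 epochs, early stopping (patience 2) on a 10%
validation split, and the 10:1 class imbalance left unweighted. Three
further protocol choices were found **necessary**, not cosmetic, during
development, and are documented because a naive protocol fails outright
(AUROC ~ 0.5 with confident memorization):

1. **Augmentation.** Each training view is randomly reverse-complemented
   and its 300 bp crop is shifted by up to ±15 bp within the 400 bp
   element. Both invariances hold for the biology (motifs are
   strand-symmetric and position-free) and together they suppress
   sequence memorization, which otherwise wins the gradient race.
2. **Delta-style initialization of conv2-conv4.** A randomly initialized
   stack of three valid convolutions and three max pools erases the weak
   per-window signal conv1 emits (the best 8-dimensional embedding readout
   of a random stack is near chance even when conv1 contains a perfect
   motif filter). conv2/conv3 start as per-channel identity taps plus
   small noise; conv4 taps each input channel into its congruent output
   channel. Tap kernel positions are staggered across channels because
   with valid convolutions a center-only identity chain sees just the
   middle ~125 bp of the input.
3. **k-mer seeding and head warm start.** The first 48 conv1 filters are
   initialized from the 9-mers most enriched in training positives versus
   training controls (both strands, near-duplicates removed) — the CNN
   analogue of seeding a de novo motif search with over-represented
   k-mers; purely a function of the training split, never of the truth
   manifest or test data. The dense head is then warm-started at the
   logistic regression fit on the 8-dimensional embedding (the head can
   represent that fit exactly), so backprop begins with a correctly
   oriented readout.

Despite all of this, the architecture's global-max bottleneck (64 filters
compressed into 8 channel-sums before the head) loses most of the
per-filter information: a logistic readout of the 64 conv1 filter maxima
reaches AUROC ~0.94 on the same data for which the 8-dimensional embedding
readout yields ~0.63. Training narrows that gap only slowly. On the default
synthetic world (2,001 positives), held-out AUROC after 30 unconstrained
epochs is 0.86 (0.88 with test-time averaging over shifted and
reverse-complemented views; observed offline — epoch-3 runs as used in the
timed acceptance suite reach ~0.65-0.75). The
acceptance criterion of AUROC >= 0.90 in 4/5 seeds is therefore **not
met** by this implementation under desk-scale training; the source
analysis pretrained on a large accessibility compendium, which is
explicitly out of scope here. The criterion is left red rather than
weakened; motif recovery and co-occurrence detection (below) do meet their
contracts, because they depend on the first-layer filters rather than on
the classification head.

## De novo motifs, matching, co-occurrence

For each conv1 filter, every 9-mer window activating at >= 0.7 of that
filter's maximum over the positive set contributes its one-hot counts;
counts + 1 pseudocount are column-normalized into a 4 x 9 PWM; filters
with < 10 sites are dropped; at most 64 motifs (the filter count) can be
emitted. On the synthetic world the planted Sox-like and Six-like PWMs are
recovered at mean column correlation ~1.0.

PWM-vs-PWM matching scores the mean per-column Pearson correlation,
maximized over alignment offsets and strands; the null rescores shuffled
copies of the query (column order permuted and base identities permuted
within each column) against the same target, and a Gaussian fit gives the
upper-tail p. Two deviations from the first-draft recipe were forced by
the identity example (a motif must match itself at p < 1e-5): a pure
column-order shuffle leaves low-complexity motifs near score 1 (the Sox
consensus is 5/9 T), and with >= 5-column alignments the max-statistic
null is so heavy that a perfect match only reaches p ~ 3e-4; the null
therefore also permutes within columns, and matching requires >= 7 aligned
columns (shifts of up to 2 are still found).

Co-occurrence follows the third-layer receptive-field reading: a motif
pair co-occurs in a sequence iff some conv3 window (90 bp, step 12)
contains an activating conv1 hit of both filters. "Same filter in the
third layer" is ambiguous between channel and spatial unit; the spatial
reading is implemented because it is the one that encodes the documented
~100 bp proximity scale. Per pair, positive frequency is compared with the
control-set frequency by one-sided Fisher's exact test; a pair is
significant at raw p < 0.001 with a higher positive rate. The background
set is the control sequences (configurable); shuffled positives would be
the main alternative.

# Motif categories

`scan_pwm` scores log2 odds against a uniform background with a 1e-3
pseudocount on motif probabilities, on both strands, calling hits at 80%
of the PWM's maximum achievable score; N bases contribute 0. Note that at
that threshold only near-consensus instances are called for 9 bp
near-one-hot PWMs (one mismatch costs ~4 bits of ~16): planted-recovery
tests therefore plant consensus instances. Peaks partition into
`sox_only` / `six_only` / `both` / `neither`; DE genes are then counted
per category through the peak-gene links (a gene linked to peaks of
several categories counts in each).

# Numerical and degenerate-input policy

* Wilcoxon with zero variance (all values tied) returns p = 1.
* `hypergeom_upper_tail(m = 0)` returns log10 p = 0 exactly; `m >
  min(n1, n2)` is an error.
* Uniform (zero-variance) PWM columns contribute correlation 0 in
  matching, so an all-0.25 motif scores 0 and never matches.
* Motif extraction on a model with no positive conv1 activation (e.g. an
  all-zero model) is an error, not an empty result.
* All interval logic is 0-based half-open; bookended intervals never
  overlap; peaks on different chromosomes never match at any distance.
* Seeds: every stochastic step (generator stages, control sampling,
  training shuffles, shuffle nulls) derives a private stream from one
  master seed; two runs with the same seed are bit-identical.

# Known limitations

* The classifier does not meet the 0.90 held-out AUROC target at
  desk-scale training, as discussed above; first-layer motif recovery and
  co-occurrence do meet theirs.
* The acceptance-suite CNN runs are scaled to 3 epochs (batch 256) to fit
  a single-CPU budget; unconstrained training is reported here, not
  asserted in tests.
* The Wilcoxon normal approximation is outside the 0.05 enumeration band
  for 2v2/2v3 or heavily tied tiny samples (counterexamples in the test
  comments); it is everywhere identical to the reference implementation.
* Synthetic realism limits are listed in the synthetic-world section.
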