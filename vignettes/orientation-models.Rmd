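---
title: "Orientation models for long cDNA reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orientation models for long cDNA reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

A cDNA sequencing read represents either the 5'-to-3' strand of its source
RNA or the reverse complement, with no way to tell which without a
reference or reliable adapters. Because transcript sequence is not
strand-symmetric — polyadenylation signals, protein-binding motifs and
compositional biases all live on the sense strand — a classifier trained
on sequences of known orientation can recover the strand of an unlabeled
read from sequence alone.

`readorient` frames this as binary classification. Training sequences of
known orientation are first canonicalized to forward; a seeded random half
is then reverse-complemented and labeled 1 ("not 5'-to-3'"), the rest
labeled 0, giving an exactly balanced set (`make_balanced_training_set()`;
`double = TRUE` instead keeps every sequence in both orientations, doubling
the input). Two model families are available through `orient_fit()`:

* **MLP.** Input is the concatenated normalized k-mer frequency vector,
  k = 1..`k_max`: for a sequence of length $L$ the order-$k$ count of each
  k-mer $m$ is divided by the number of k-mer positions,
  $f(m) = \mathrm{count}(m)/(L-k+1)$, so each order-k block sums to 1,
  values stay in [0, 1], and the input size is independent of read length.
  The network has five ReLU hidden layers (default sizes 512, 256, 128,
  64, 32, dropout 0.2 after each) and one sigmoid output unit whose value
  approximates the probability that the read is *not* in 5'-to-3'
  orientation.
* **CNN.** Each sequence is cut into 500-nt windows every 250 nt; any
  window running past the end (including the single window of a sequence
  shorter than 500 nt) is right-padded with N, which one-hot encodes to an
  all-zero column so padding carries no signal. The network is LeNet-like:
  three convolution + max-pooling blocks followed by three dense layers
  ending in a 2-class softmax. Every window of a training sequence
  inherits the sequence label. At prediction time the window posteriors
  are averaged per read independently for the two orientations and the
  larger mean wins; the read score is the mean "reverse" posterior.

For both models the decision rule is fixed and strict: a read is called
`REVERSE` (and reverse-complemented on output) iff its score is strictly
greater than 0.5; a score exactly at the threshold stays `FORWARD`.

# Labeled data sources

Three source kinds provide labels (`build_labeled_dataset()`):
`annotation` (reference transcripts, 5'-to-3' by definition),
`experimental` (protocols that read the native strand, e.g. direct RNA
sequencing; uracil is converted to thymine on input), and `mapped` (reads
labeled by an independent mapping, parsed from a PAF file). For mapped
sources a read is labeled only when it has exactly one alignment record
and mapping quality at least `min_mapq` (default 60, minimap2's maximum);
`+` strand means the read is already 5'-to-3'. Supplementary alignments
count as extra records and trigger the multimapping exclusion — a
deliberately conservative reading of "uniquely mapping". Reads that fail
the filter are dropped entirely. Preprocessing discards reads containing
any non-ACGT base, trims an optional fixed number of bases from both ends,
and drops reads shorter than `min_len` (default 50 nt, avoiding degenerate
feature vectors).

# Cluster majority vote

Reference-free pipelines usually cluster reads by molecule of origin.
Since all reads of a cluster share one true orientation, per-read calls
can be corrected in one pass (`majority_vote()`): if strictly more than
50% of a cluster's reads are predicted forward, all are set to forward;
otherwise — including an exact 50/50 tie, since the stated condition is
strict — all are reverse-complemented. For a cluster of $n$ independent
per-read calls with accuracy $p > 0.5$, the majority decision is correct
with probability $\Pr[\mathrm{Bin}(n, p) > n/2]$, which exceeds $p$ for
$n \ge 3$ and grows with cluster size; the tie rule only dilutes this for
small even clusters. The vote is idempotent and leaves unanimous clusters
and singletons unchanged.

# Motif extraction

The first convolutional layer is the only stage whose activations align
positionally with the input, so motifs are read from there: for every
first-layer filter, each window position with a strictly positive
pre-pooling activation (after the bias) contributes the aligned
filter-width input subsequence; subsequences overlapping N padding are
skipped. Stacked subsequences become a position weight matrix,
column $j$ = (base counts at $j$ + pseudocount) / (n_sites + 4·pseudocount),
with pseudocount 0 by default (raw conversion; the resulting information
content is typically low). The PWM set is written in MEME minimal format,
consumable by TOMTOM-style comparison tools. Which probe sequences to scan
is left to the user — training and test reads are both reasonable choices.

# The synthetic data generator

Real benchmark corpora (annotation + mapped ONT reads) are multi-gigabyte
downloads, so the package ships a generator that plants a controllable
strand-asymmetric signal instead. `simulate_transcripts()` draws
background sequence from a configurable base composition and overwrites
non-overlapping slots with motifs from a fixed set — ten non-palindromic
hexamers whose reverse complements are outside the set (including the
polyadenylation signal AATAAA) — at a Poisson rate of `motif_density`
insertions per nt (default 0.01, i.e. one per 100 nt, a density at which
a 1 kb transcript carries ~10 planted sites); an optional geometric
poly-A tail can be appended. `simulate_reads()` then derives reads:
optional 5'-truncation (geometric length, mimicking internal priming),
a per-base substitution/insertion/deletion channel (substitutions uniform
over the three alternatives, indels of length 1, per-read event counts
recorded), and reverse complementation with probability 0.5, which sets
the truth label. Each read records its source molecule (`transcript_id`)
and a cluster id grouping reads of one molecule *and* one emitted strand —
similarity clustering of unoriented reads is strand-specific, so reads of
opposite strands never co-cluster and a cluster shares a single true
orientation, the premise the majority vote relies on.

What this emulates — and what it does not: planted motifs and
compositional asymmetry stand in for real RNA sequence biases, and the
uniform error channel for ONT-like noise, but real reads have structured
errors (homopolymer deletions), length-dependent quality, adapter
remnants, and motif grammars far subtler than ten hexamers. Passing the
synthetic benchmarks therefore demonstrates that the estimator recovers a
planted strand signal through noise and truncation — not the accuracy to
expect on any particular organism.

# Optimization and numerical choices

Both networks train with Adam (learning rate 1e-3, β = 0.9/0.999), batch
size 128, binary/categorical cross-entropy, a 10% validation split,
early stopping with patience 5 and best-weight restore, and a cap of 100
(MLP) or 15 (CNN) epochs. One integer seed drives balancing, shuffling,
weight initialization and dropout. Hidden/conv weights use He
initialization; the dense stack of the CNN uses Xavier scaling and the
softmax head starts at zero (uniform posterior) because the ReLU +
max-pool blocks accumulate positive activation means that would otherwise
inflate the initial logits and stall early training. Max-pool ties break
toward the first position.

The first convolutional layer is additionally seeded with k-mer detectors
by default (`filter_init = "kmer"`): each filter starts as a one-hot
template of one of the hexamers whose frequencies differ most between the
two orientation classes of the training set, with a bias that fires on a
near-exact match, and backprop selects and refines them from there. This
is the standard remedy, familiar from motif-discovery networks, for a
well-known failure mode: with fully random filters the probability that
any of 32 projections correlates usefully with a short sparse motif is
small, and at desk-scale training sizes (thousands of sequences rather
than the tens of thousands a full annotation provides) the optimization
sits on a long plateau — or, given enough capacity, memorizes the training
windows instead of discovering the signal. The seeding uses training
sequences only, is part of the fitting procedure, and can be disabled
with `filter_init = "random"`. Convolution patch gather/scatter is the only
compiled code (Rcpp); everything else is base-R matrix algebra. Training
is exactly reproducible given the seed on a fixed BLAS; across BLAS
implementations reproducibility is statistical (accuracy), not bitwise.

Degenerate inputs are handled explicitly: reads that cannot be featurized
(shorter than `k_max`, or containing non-ACGT symbols at prediction time)
receive an `NA` score, are written unchanged, and are excluded from
metrics with a separate count — silently counting them as correct would
inflate accuracy. Undefined precision/recall ratios (empty confusion
cells) are reported as 0 with a `degenerate` flag. In
`orientation_metrics()` the positive class is `REVERSE` (the event the
score measures); macro-averages over both classes are reported alongside,
since published per-class averages can follow either convention.

# Design decisions taken where the design was open

* Sequences shorter than 250 nt get the same single right-padded window
  as 250–500 nt ones, rather than being dropped; combined with the
  `min_len` filter this keeps the window contract uniform.
* The final partial window of a long sequence is right-padded like a
  short transcript's — the one padding rule is applied everywhere.
* Exact architectural table sizes for the two networks are not pinned by
  the constraints we follow (5 hidden layers; 3 conv + 3 pool + 3 dense;
  32 first-layer filters; sigmoid/softmax heads), so layer sizes are
  package defaults, all configurable.
* The MAPQ filter is `>= min_mapq` with default 60 rather than `== 60`,
  keeping the parameter meaningful for mappers whose scale differs.
* k-mers are stranded, never canonicalized — collapsing a k-mer with its
  reverse complement would erase exactly the signal being learned.

# Problem sizes used in tests and the acceptance script

The shipped benchmarks train the MLP on 3,000 synthetic sequences
(lengths 500–2,000 nt, default motif set at density 0.01, k_max = 4) and
test on 1,000 held-out reads, with variants adding a 10% per-base error
channel, 100-nt end-trimming, and a no-signal null (density 0, uniform
composition). The CNN uses the same benchmark, and motif recovery is
checked on sequences carrying a single planted hexamer. These sizes are
an order of magnitude below a real annotation (the CLI defaults to
subsampling 50,000 training transcripts), chosen so the full suite runs
on a laptop CPU in minutes while leaving the planted signal clearly
recoverable.

# Known limitations

* Accuracies on synthetic data say nothing quantitative about real
  transcriptomes; cross-species transfer, DRS error structure and
  antisense transcripts are all untested here.
* The CNN trains from scratch in R on CPU; it is minutes-slow at desk
  scale, and large corpora call for the MLP (or patience).
* Ties in the majority vote flip the whole cluster to reverse by the
  strict reading of the rule; on even-sized clusters with weak models
  this is mildly pessimistic.
* The MEME writer emits the minimal format only (no strands line, E
  placeholder 0), which TOMTOM accepts.
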