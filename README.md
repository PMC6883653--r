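# readorient

Reference-free prediction of the 5'-to-3' orientation of long cDNA
sequencing reads.

## The problem

Long-read cDNA sequencing (Oxford Nanopore, PacBio) reads each molecule in
an arbitrary strand: a read is either the native 5'-to-3' sequence of its
source RNA or the reverse complement. Downstream work — ORF detection,
motif analysis, de novo transcriptome interrogation — needs the native
orientation, but recovering it usually requires mapping to a reference
genome/transcriptome or detecting error-prone strand-specific adapters.
Neither is available for non-model organisms.

RNA sequence is not strand-symmetric: transcripts carry biases and motifs
tied to their metabolism (polyadenylation signals, protein-binding sites).
`readorient` exploits this by training small neural classifiers on
sequences of known orientation — a transcriptome annotation, direct-RNA
(DRS) reads, or reads labeled by an independent mapping — and then scoring
unlabeled cDNA reads with no reference at prediction time.

## Models

Two classifiers are implemented, both trained on a balanced set in which a
random half of the input sequences is reverse-complemented (label 1 = "not
5'-to-3'"):

* **MLP** — a multilayer perceptron with 5 ReLU hidden layers and a
  sigmoid output, fed a normalized k-mer frequency vector: for each k =
  1..k_max (default 5) and each of the 4^k k-mers,
  `frequency(kmer) = count(kmer) / (L - k + 1)`
  for a read of length L, so each k-block sums to 1 and the input size is
  independent of read length (1364 features at k_max = 5).
* **CNN** — a LeNet-style network (3 convolutions, 3 max-pooling steps, 3
  dense layers, 2-class softmax) on one-hot encoded 500-nt windows taken
  every 250 nt (right-padded with N). A read's posterior is the mean of
  its window posteriors for each orientation; the larger mean wins.

The model score approximates the probability that a read is **not** in
5'-to-3' orientation; a read with score strictly greater than 0.5 is
reverse-complemented on output. Per-read calls can be corrected by a
cluster-level majority vote: if more than 50% of a cluster's reads are
predicted forward, all its reads are set to forward, otherwise all are
reverse-complemented. First-layer convolutional filters can be converted
to position weight matrices (from the input subsequences aligned with
strictly positive activations) and written in MEME minimal format for
comparison against known RNA-binding motifs.

## Worked example

```r
library(readorient)

# synthetic benchmark: transcripts with planted strand-specific hexamers
tx    <- simulate_transcripts(600, length_range = c(500, 2000),
                              motif_density = 0.01, seed = 1)
reads <- simulate_reads(simulate_transcripts(200, length_range = c(500, 2000),
                                             motif_density = 0.01, seed = 2),
                        revcomp_prob = 0.5, seed = 3)

fit <- orient_fit(tx, model = "mlp", k_max = 4, seed = 1)
fit
#> Read-orientation model (multilayer perceptron)
#>   features: k-mer frequencies, k = 1..4 (340 features)
#>   hidden layers: 512, 256, 128, 64, 32
#>   trained on 600 sequences
#>   score = P(read not in 5'-to-3' orientation); flip iff score > 0.5

evaluate_orientation(fit, reads)
#> Orientation metrics on 200 reads (positive class: REVERSE)
#>   precision 0.9167  recall 0.8889  F1 0.9026  accuracy 0.9050
#>   macro: precision 0.9054  recall 0.9048  F1 0.9049
#>          truth
#> predicted REVERSE FORWARD
#>   REVERSE      88       8
#>   FORWARD      11      93
```

`precision` is the proportion of `REVERSE` calls that are correct,
`recall` the proportion of truly reverse reads recovered, and the
confusion matrix counts reads. Oriented FASTA/FASTQ output and a
predictions table come from `predict_orientations()`; cluster correction
from `parse_clusters()` + `majority_vote()`.

The same workflow is available from a shell via the bundled CLI
(`inst/scripts/readorient`): `simulate`, `train`, `test`, `predict`,
`vote`, and `motifs` subcommands.

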