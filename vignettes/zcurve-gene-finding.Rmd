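---
title: "Z-curve gene finding: model, training and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Z-curve gene finding: model, training and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zgene)
```

## The problem

Ab initio gene finding in bacteria and archaea asks: given nothing but the
genome sequence, which open reading frames (ORFs) are protein-coding genes?
Prokaryotic genes are intronless, so the combinatorial substrate is simple —
every stretch that begins at a start codon (ATG/GTG/TTG under genetic code
11) and runs to the first in-frame stop codon (TAA/TAG/TGA) is a candidate —
but the substrate is large: a 200 kb genome typically contains a few
thousand candidate ORFs of ≥ 90 nt, of which only a few hundred are genes.
The discriminative signal is compositional: coding sequence is a stream of
codons drawn from a species-specific biased usage table, which imprints
*phase-specific* statistics (the distribution of a base depends on its
position within the codon), while non-coding ORFs — random open stretches in
intergenic DNA, and "shadow" ORFs opposite real genes — lack this phase
structure or carry its mirror image.

## The Z-curve encoding

For an ORF we count k-mers stratified by the codon position (phase 1, 2, 3)
of the k-mer's leading base, for k = 1–4. For k = 2 the three phases
correspond to dinucleotides at codon positions 1–2, 2–3 and 3–1, the last
spanning the codon boundary and therefore sensitive to codon-order
correlations that single-codon statistics cannot see.

Each group of four frequencies — the distribution of the final base given
the phase and the preceding k−1 bases — is mapped by the Z transformation
onto three axes with direct chemical meaning:

* x = (A+G) − (C+T): purine vs pyrimidine,
* y = (A+C) − (G+T): amino vs keto,
* z = (A+T) − (G+C): weak vs strong hydrogen bonding.

The map is linear and loses only the constraint that the four frequencies
sum to one, which is why every group of 4 frequencies becomes 3 variables
(a 3/4 reduction). The block sizes follow: mono 4×3×3/4 = 9, di
4²×3×3/4 = 36, tri 4³×3×3/4 = 144, tetra 4⁴×3×3/4 = 576, for 765 variables
in total. The legacy 33-variable encoding (mono plus dinucleotides at
positions 1–2 and 2–3 only: 9 + 24) is retained via `encode_orf_legacy()`
for comparison; its mono block is identical to the full encoding's.

Two numerical choices matter here:

* **Stop-codon exclusion.** The terminal stop codon is constant across all
  ORFs and is excluded from counting.
* **Pseudocount smoothing (default 0.5).** Conditional frequencies are
  estimated per (phase, prefix) group; the tetranucleotide block has 192
  such groups, so a 40-codon ORF contributes on average ~0.2 observations
  per group, and the raw maximum-likelihood frequencies of short ORFs are
  dominated by sampling noise saturating at ±1. We therefore add 0.5
  pseudo-observations per group, spread uniformly over the four bases,
  shrinking rarely-seen groups toward (0, 0, 0) — the uninformative point of
  the Z space, and the value assigned to never-seen groups. This is a
  bias–variance trade: it slightly attenuates genuine signal in short genes
  while strongly suppressing the short-ORF false positives that otherwise
  dominate the error budget. `pseudocount = 0` recovers the raw estimator.

## Self-training: no external labels

The classifier is trained per genome, from the anonymous sequence itself:

* **Positives**: canonical ORFs of ≥ 480 nt (`seed_min_len`) that do not
  overlap a longer candidate by more than the overlap cap. Under a null
  model, ORFs of this length are rare by chance, so the seed set is almost
  pure coding sequence. Fewer than 50 such seeds is an error (the genome is
  too small or too fragmented for per-genome self-training).
* **Negatives**: for each seed, (i) a nucleotide-order shuffle of its body
  (identical base composition, all codon-phase structure destroyed) and
  (ii) its opposite-strand shadow (the reverse complement — the mirrored
  phase signature a shadow ORF would show). Both negative families are
  derived from the positives, so they are available in arbitrarily
  gene-dense genomes and composition-controlled by construction.

A linear max-margin classifier (soft-margin SVM, linear kernel, C = 1, the
solver's default) is fitted on standardized features; centring and scaling
are folded back into the stored weights so that the model is a plain affine
score f(v) = w·v + b. The linear kernel is the appropriate choice at 765
dimensions with a few hundred training samples.

One **self-training refinement pass** is performed by default: all
candidate ORFs are scored, confident calls (|f| > 1) become the new
training sets, and the model is refitted. The first-round model is trained
only on long seeds, so its behaviour on short ORFs is an extrapolation; the
refinement pass injects confidently-labelled short ORFs of both classes and
markedly sharpens the decision boundary in the short regime. If either
confident class is empty the previous model is kept with a warning.

## The calling pipeline

`zgene()` orchestrates: ORF enumeration (all six frames; for circular
contigs a doubled-sequence scan finds origin-crossing ORFs, reported with
`start > end` and `wrap = TRUE`) → encoding → scoring → thresholding
(default 0, the margin boundary) → greedy overlap resolution (descending
score, a candidate is dropped if it overlaps a retained gene by more than
30 nt on either strand; ties break toward the longer, then leftmost
candidate) → start relocation.

**Start relocation.** For each retained gene the in-frame candidate starts
compete on `coding_score(truncated ORF) + sd_weight × SD`, where SD is the
best ungapped identity count of the Shine–Dalgarno motif AGGAGG against a
window 5–13 nt upstream of the candidate start. The 3′ terminus never
changes, and relocation never moves onto a start whose truncated ORF fails
the coding threshold. `sd_weight` defaults to `sd(coding scores)/6` so that
a perfect 6/6 motif match is worth roughly one standard deviation of the
coding score — the two terms are put on comparable scales rather than one
dominating. This relocator is a deliberately simple stand-in for a full
start-site model: it uses only motif identity and spacer range, not a
position-weight matrix or spacer-length energetics.

## Evaluation conventions

A prediction is **correct iff it shares the annotated gene's stop-codon
terminus** (contig, strand and 3′ coordinate); the start is ignored,
because start annotation is itself unreliable. On this rule:
Sn = correct/annotated, PPV = correct/predicted, Accuracy = (Sn + PPV)/2
(true negatives are uncountable in this setting, so the midpoint replaces a
specificity-based accuracy), and APR = additional predictions/annotated.
For essentiality: Sn over annotated essential genes, Sp over annotated
nonessential genes, OA over all — and a gene only counts as correct if it
was both *found* by the caller and assigned the right class, so caller
misses are penalized.

## Consensus of two gene finders

`combine_predictions()` implements the joint-application rule: predictions
agreeing by 3′ terminus are retained outright; program-specific predictions
pass through a pluggable homology oracle (in production a protein-database
search excluding the query's own taxon; in tests a truth-aware predicate or
a whitelist) and are kept only on a hit. With any sound oracle this can
only add true genes and only remove program-specific false positives, so
sensitivity is bounded below by the better input and the additional
positive rate above by the better input.

## Essentiality post-scoring

Each predicted protein is looked up in every reference organism by a
pluggable matcher (exact-id lookup for fixtures; a reciprocal-best-hit
matcher over pairwise alignments is provided). The essentiality score is
the distance-weighted fraction of references in which the best hit is a
known essential gene: score = Σ wᵢeᵢ / Σ wᵢ with wᵢ = exp(−dᵢ) by default,
eᵢ ∈ {0, 1}. The score is a convex combination of the evidence, hence in
[0, 1]; calls use a neutral 0.5 cutoff by default. The evolutionary
distances are inputs here — no composition-vector phylogeny is computed —
and the weighting function and cutoff are both configurable.

## What the synthetic generator emulates — and what it does not

`synth_genome()` plants non-overlapping genes on both strands of an iid
intergenic background (GC fraction configurable, default 0.5). Gene
interiors are iid draws from a codon table sampled by exponentially
tilting the uniform table with Gaussian log-weights of scale `codon_bias`
(default 0.5, a moderate bias; 0 gives exactly uniform). Gene lengths are
`150 + 3·Geometric` nt with mean 900, matching typical bacterial gene-length
scales; 10% of genes are labelled essential, echoing the strong class
imbalance of real essentiality screens; an AGGAGG box is planted 7 nt
upstream of each gene. Defaults: 200 kb, 150 genes.

This emulates exactly the structure the encoder is built to detect —
phase-specific composition against a phase-free background — and planted
truth makes Sn/PPV measurable without downloads. It does **not** emulate:
operon structure and overlapping genes, GC-skew and replication-strand
asymmetries, horizontally transferred composition mosaics, RBS variability,
pseudogenes, or annotation error. Passing the synthetic benchmarks
therefore demonstrates that the machinery (enumeration, encoding, training,
arbitration) is correct and self-consistent, not that real-genome accuracy
equals the synthetic numbers.

A subtlety worth recording: a "no signal" negative control cannot use
shuffled negatives. Base-shuffling a gene reintroduces in-frame stop
codons, and candidate ORFs are stop-free by definition, so any ORF-trained
classifier separates genes from shuffles even with a uniform codon table —
that is real structure, not leakage. The package's null control
(`null_orf_set()`) therefore compares held-out planted genes of a second
genome against length-matched stop-free null ORFs; at `codon_bias = 0` this
AUC is ≈ 0.5, and at 0.5 it is ≈ 1.

## Problem sizes and degenerate inputs

The shipped tests and the acceptance script run the full pipeline on ten
200 kb genomes with 150 planted genes each (the benchmark condition), an
80 kb genome for module-level checks, and thousands of sub-kilobase
sequences against brute-force oracles. Degenerate inputs are defined
behaviours: a genome with no qualifying ORF yields an empty prediction set;
codons containing N are never start/stop candidates and translate to X;
too few long-ORF seeds is an error advising a smaller `seed_min_len`;
duplicate 3′ termini are de-duplicated with a warning wherever they would
break one-to-one matching.

## Known limitations

* One model per genome; no pooling across GC classes and no pretrained
  fallback for very small or highly fragmented assemblies.
* The linear score is partly length-sensitive through the smoothing
  shrinkage; very short genes (< ~120 nt) are the main source of misses.
* The start relocator is motif-based only; a full start-site model
  (PWM + spacer energetics + leaderless transcripts) is out of scope.
* The essentiality module treats reference distances as given and the
  matcher as pluggable; it does not reproduce any particular published
  distance estimator.
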