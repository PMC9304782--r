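---
title: "Codon-switch representations of coding variants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-switch representations of coding variants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcs)
```

## The representation

A coding single-nucleotide variant changes one base of one codon. `crcs`
represents it as a **codon switch**: a directional pair (reference codon →
alternative codon) differing in at most one base. Each of the 64 codons has
nine single-base neighbours, giving 9 × 64 = 576 substitution switches;
together with the 64 identity switches (codon unchanged) the vocabulary has
**640 entries**, enough to write any coding sequence, altered or not. A
variant on a transcript becomes a **codon switch sequence**: the spliced CDS
rendered codon-by-codon as identity switches, except the single codon
carrying the variant. Codons are defined in spliced transcript space, so
variants in codons spanning exon junctions are handled naturally;
minus-strand models are reverse-complemented and the alternate base is
complemented into transcript orientation.

The dictionary ordering is canonical — reference codons lexicographic
(AAA..TTT), identity switch first, then substitutions by position and
alternative base — and a hash of this ordering travels with every embedding
matrix, so a model can refuse index sequences produced under a different
ordering.

## Learning switch embeddings

Switch semantics are learned with skip-gram-with-negative-sampling recast as
a binary classification. Within each sequence, center positions are
subsampled with keep probability

$$p(f) = \min\!\left(1, \sqrt{1 + f/\varepsilon}\,\frac{\varepsilon}{f}\right),
\qquad \varepsilon = 0.001,$$

where $f$ is the switch's relative frequency over the embedding corpus.
Identity switches dominate every sequence (a sequence of $m$ codons has at
most one non-identity switch), so without subsampling the training signal
would be swamped by identity-identity pairs; the formula squeezes frequent
switches and keeps rare ones with probability one ($f = 0$ maps to 1 as the
limit). $f$ is a *relative* frequency: the floor $\varepsilon = 0.001$ is
only meaningful on that scale.

Each selected center contributes one positive tuple per context switch
within a window of `ws = 3` positions on either side (truncated at the
ends) and $\lceil (2\,ws + 1)\,nsr \rceil = 2$ negative tuples at
`nsr = 0.2`, whose partners are drawn uniformly from all 640 switches. Two
printed-form readings of the negative count (floor = 1, ceiling = 2) are
possible; the ceiling is used because it matches the stated per-center count
of two. Negatives may collide with true context switches; no resampling is
attempted. The classifier is deliberately minimal: one **shared** 640 × L
embedding matrix serves both the center and partner roles, the head applies
a single dense unit (weight and bias) to the dot product of the two
embeddings, and a sigmoid feeds binary cross-entropy. At the default
L = 300 this network has exactly 640 × 300 + 2 = **192,002** trainable
parameters, optimized with ADAM (step 1e-3, β₁ = 0.9, β₂ = 0.999 — standard
choices, none are dictated by the method) over shuffled mini-batches for
200 epochs. The analytic gradient is verified against finite differences in
the test suite.

```{r}
n_trainable(init_embedding_model(L = 300))
keep_probability(c(0.001, 0.01, 0.1))
```

## The BLAC classifier

Variant scoring uses a recurrent attention network over the frozen
embeddings, in this exact layer order: embedding lookup (non-trainable) →
bidirectional LSTM → batch normalization → bidirectional LSTM → batch
normalization → time-distributed dense (tanh) → batch normalization →
additive attention → dense sigmoid scalar. The attention layer scores each
time step with $v^\top \tanh(W_a x_t + b_a)$, softmaxes over time and
returns the weighted sum; the sigmoid output is the probability that the
variant is cancer-like. Hidden sizes default to (64, 64, 32, 32) and are
configuration, not method: the reference description leaves the widths to a
supplementary schematic whose totals cannot be reconstructed from the text,
so no attempt is made to match a specific total parameter count.

Three numerical choices matter. Variable-length sequences are bucketed by
length and padded; padded steps are masked out of the recurrences (state
carries through unchanged), the batch-norm statistics, the attention
softmax and the loss, and the suite asserts that padded and unpadded
forward passes agree to 1e-5. Batch normalization keeps running statistics
(momentum 0.99) that are used at inference. The forget-gate bias starts at
1 so early gradients pass through the recurrences. The full network's
analytic gradients are checked against finite differences; every
nonlinearity is smooth (tanh/sigmoid), which keeps that check sharp.

Evaluation is gene-disjoint: genes are partitioned into near-equal folds
and every sequence is scored by the one model whose training split excluded
its gene, so the classifier can never succeed by memorizing a gene's
background sequence. Average precision is computed step-wise over distinct
score thresholds (a single tie group therefore collapses to the positive
prevalence), and the fake-split control — random pseudo-classes cut from a
single-source pool, full training cycle, AP ≈ 0.5 — guards against
pipeline leakage.

## Downstream statistics

*Driver scan.* Scores are grouped by (cancer type, gene) with a minimum
group size of 5; each gene is tested with a one-sided Mann–Whitney U test
(cancer scores stochastically larger than control scores for the same
gene). The exact null is enumerated when the pooled sample size is ≤ 12
(ties handled by permutation); otherwise the normal approximation with tie
and continuity correction is used. Within each cancer type the p-values are
Holm–Šidák-adjusted, $\mathrm{adj}_{(i)} = \max_{j \le i}\,[1 - (1 -
p_{(j)})^{m - j + 1}]$, and flagged at α = 0.05 (the α is this package's
choice). Genes significant in ≥ 10 cancer types are retained, then cancer
types left with ≤ 5 such genes are dropped; both thresholds are parameters
(a figure-caption variant of the recurrence rule uses ≥ 5 cancer types, so
neither value is privileged). Enrichment of a known-driver list is tested
with a one-sided two-sample Kolmogorov–Smirnov test on −log₁₀ adjusted
p-values, with exact zeros floored at the smallest positive double.

*Survival.* A patient's cumulative score is
$\mathrm{BLACs} = \tfrac{1}{N}\sum_{i=1}^{N} (2^{k\,s_i} - 1)$ with k = 4,
which lives in [0, 2ᵏ − 1] and weights high-scoring mutations
exponentially. Cohorts are filtered to patients with ≥ 5 scored mutations
and cancer types with ≥ 100 patients. Each type is dichotomized at the
cutpoint maximizing the log-rank chi-square over midpoints of consecutive
distinct scores, constrained so each side keeps ≥ 10% of patients and ≥ 5
patients (the search needs a degenerate-split guard; both constraints are
configurable), ties breaking to the lowest threshold. The log-rank
statistic accumulates observed-minus-expected events over distinct event
times with the hypergeometric variance, events counted before censorings at
tied times; it is cross-checked against `survival::survdiff` and a
permutation reference in the tests. Kaplan–Meier curves come from
`survival::survfit`. Only overall survival is modeled, and no
multiple-testing correction is applied across cancer types (the reference
analysis reports raw log-rank p at the 0.1 level).

```{r}
blacs_score(c(0.5, 1.0), k = 4)
```

## What the synthetic data emulates

`simulate_genome()` builds multi-exon, two-strand gene models on short
chromosomes and plants **context sites** in each CDS: windows whose `ws`
flanking codons on both sides come from one of two disjoint 8-codon sets
(GC-rich vs AT-rich) while the center codon stays background.
`simulate_variants()` places class-1 variants at GC-context sites with
probability β (uniformly otherwise) and class-0 variants at AT-context
sites analogously. The signal therefore lives **only in the flanking codon
composition** — the substituted base is always drawn uniformly at the
chosen codon — mirroring the premise that cancer-like variants sit in
differential nucleotide contexts; β = 0 makes the class-conditional context
distributions coincide. `simulate_survival()` draws exponential survival
times with hazard $\text{base} \cdot e^{\gamma\,\mathrm{BLACs}}$ and
independent exponential censoring calibrated to a target censored fraction.
All generators are pure functions of (config, seed).

What passing tests on these data do *not* show: real mutational signatures
(APOBEC/UV etc.), allele-frequency structure, inter-gene correlation, or
corpus-scale class overlap — the synthetic classes are far cleaner than
ExAC-vs-COSMIC-style data, so absolute APs here say nothing about
achievable AP on real cohorts. The studies are controls and
parameter-recovery checks, not benchmarks.

## Study scales and defaults

The reduced study conditions used by the control experiments (and the
acceptance script) are the package's choices, made once: toy genomes of 12
genes with CDS lengths of 30–60 codons; a 600-sequence homogeneous pool for
the fake-split control and 500 variants per class for the planted-signal
study (β = 0.9); embeddings of length 16 trained for 30 epochs; a reduced
BLAC of widths (8, 8, 8, 8) trained for 15 (control) or 30 (signal) epochs
per fold with ADAM at 3e-3, batch 32, 4 gene-disjoint folds. At corpus
scale the defaults revert to the method's published values (L = 300, 200
epochs, widths 64/64/32/32, length cap 1500, ≥ 200 variants per gene).

## Known limitations

- **Cutpoint-selection inflation.** Maximizing the log-rank chi-square over
  cutpoints and then reading the raw log-rank p overstates significance
  under the null: with γ = 0 cohorts of 150 patients, about half of
  replicates fall below p = 0.1 despite no signal. This is inherent to the
  optimal-threshold design the method prescribes, and the package
  reproduces it faithfully; `survival_null_calibration()` demonstrates that
  the log-rank test itself calibrates at a *prespecified* (median) split.
  Interpret optimized-threshold p-values as descriptive, not inferential.
- The embedding split unit is the variant; the reference text does not
  state whether its 40% embedding hold-out was drawn over variants or
  transcripts, and transcript-level splitting would differ slightly.
- Deduplication uses the (transcript, CDS position, ref, alt) key after
  splice inflation, which is equivalent to the genomic key per source; a
  corpus deduplicated genome-wide across sources would be smaller.
- Indels, multi-nucleotide and complex alterations are out of scope by
  design, as are UTR and non-coding variants.
- Training is plain R linear algebra: fine at the reduced study scale
  (minutes on one CPU), not meant for corpus-scale embedding runs.
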