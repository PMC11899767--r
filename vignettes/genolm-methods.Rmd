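---
title: "Whole-genome language-model features for trait prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome language-model features for trait prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Genomic selection predicts a plant's phenotype from its genome-wide
genotype. Classical approaches feed SNP dosage matrices to a regression or
classification model, which ignores the sequence context around each
variant and covers only the assayed loci. `genolm` implements the
alternative this package is built around: learn a small DNA language model
over whole chromosome sequences, pool its per-window hidden states into one
fixed-length feature vector per sample, and hand those vectors to ordinary
supervised predictors under cross-validation.

The package covers the full path: FASTA/VCF ingestion, single-nucleotide
tokenization, windowing, language-model training, chromosome-level fusion,
a trait-prediction harness, and a seeded synthetic-data generator used by
every test.

## Tokenization and windowing

DNA is tokenized one nucleotide per token over a 7-symbol vocabulary —
`A/T/C/G` plus `PAD`, `SEP` and `UNK` — with the fixed id assignment
`A=0, T=1, C=2, G=3, PAD=4, SEP=5, UNK=6`. Fixing ids (rather than deriving
them from input order) keeps serialized models and window files valid
across runs. Soft-masked lowercase bases are uppercased, not mapped to
`UNK`; any non-ACGT letter (N, IUPAC ambiguity codes) becomes `UNK`. `SEP`
is reserved and never emitted inside a window.

Two input modes mirror the two ways a genome can be presented to the model:

* **All-sequence mode** tiles each chromosome into consecutive,
  non-overlapping windows of `L_in` nucleotides; the final short window is
  right-padded. Concatenating the unpadded parts of the windows
  reconstructs the chromosome exactly, a property the tests check for every
  length from 1 to `3 L_in`.
* **SNP mode** extracts one window per variant site spanning
  `[i - L_in/2, i + L_in/2)` around the 0-based site index `i`, so the
  variant base always sits at offset `L_in/2`. A window clipped by a
  chromosome end is padded on the clipped side rather than shifted, which
  keeps the anchor offset constant — downstream pooling masks the padding
  anyway. The stated rule "`L_in/2` on either side" cannot hold exactly for
  an even-length window that also contains the variant; we keep window
  length exactly `L_in` (variant + `L_in/2` left flank + `L_in/2 - 1`
  right flank) so both modes produce interchangeable shapes.

Internally all coordinates are 0-based half-open; VCF positions are
converted on ingest. Only biallelic SNPs are accepted from VCF — the SNP
window mode is defined per point variant — and skipped records are counted
and reported. Windows never substitute alleles themselves: callers supply
per-sample sequences that already carry them.

## The language model

The model is a decoder-only stack of **Hyena operators**. Each operator
projects its input into three streams `x1`, `x2`, `v` (dense layer followed
by a causal depthwise convolution of width 3), then combines them with one
long causal convolution and two element-wise gates:

y = x2 ⊙ ( h * (x1 ⊙ v) )

where `*` is causal convolution with a filter `h` of the same length as the
input — equivalently, multiplication by the lower-triangular Toeplitz
matrix built from `h`. The filter is *implicit*: a two-layer MLP with sine
activation maps positional features of index `t` to the filter value
`h[t]`, so the parameter count is independent of the window length. The
positional features are the normalized index plus sine/cosine pairs at
geometrically spaced periods; the normalization constant is the model's
maximum context `L_in` (not the current window length), so a filter
materialized at length 8 agrees with the first 8 rows of the same filter at
length 16 and windows of different lengths see consistent filters.

Two further choices are ours where the architecture leaves room:

* **Decay envelope.** Filters are modulated by `exp(-alpha_c t)` with one
  learnable rate per channel, initialized so effective decay lengths spread
  geometrically from 5% to 150% of `L_in`. This is the standard
  stabilization for long implicit filters; it can be disabled
  (`use_decay = FALSE`) for ablation.
* **Block layout.** Pre-layer-normalization, the Hyena operator, an output
  projection, then a position-wise feed-forward sublayer (GELU, width
  `2 d_model`), each wrapped in a residual connection — the minimal layout
  that trains stably at depth 2 and beyond.

The convolution is evaluated with FFTs zero-padded to the next power of two
at or above `2L - 1`, so no circular wrap-around occurs; the test suite
verifies exact agreement (relative error below 1e-8, in practice near
machine precision) with a brute-force Toeplitz multiplication on random
instances, and verifies end-to-end causality by perturbing window suffixes
and checking that prefix logits are bit-stable.

Training minimizes the average cross-entropy of predicting each position's
*next nucleotide*. Positions whose target is a special token (`PAD`,
`UNK`, `SEP`) are excluded — the objective is defined over nucleotides
only. Optimization is Adam with gradient clipping at global norm 1, batch
size 16, learning rate 6e-4, and up to 6 epochs by default; all shuffling
derives from the configuration seed, so runs are bit-reproducible on one
device. Models are trained from scratch: no external pretrained checkpoint
is loaded, which keeps the mechanics of the method intact while removing
any dependency on outside artifacts.

The forward and backward passes run in compiled C++ (RcppArmadillo); a
pure-R implementation of the identical computation is kept in the package
and the test suite asserts agreement between the two to 1e-10, plus
agreement of analytic gradients with central finite differences.

### What training can and cannot achieve at desk scale

Three synthetic corpora with known entropy pin down the training loop:

* a periodic `ACGT...` sequence is fully predictable, so held-out
  cross-entropy must fall below 0.1 nats within 6 epochs;
* an i.i.d. uniform sequence cannot be predicted below its source entropy
  `ln 4`;
* an order-1 Markov sequence has an analytic entropy rate
  `-sum_i pi_i sum_j P_ij ln P_ij`, and the trained model must land within
  0.1 nats of it.

These checks run at `L_in = 256`, `d_model = 64`, two layers, with corpora
of 400 training windows (120 for the uniform corpus, where no learning
beyond the unigram floor is possible) — sizes chosen so the fixed 6-epoch
budget contains enough optimizer steps to converge on the learnable
corpora while the whole block stays within a few minutes of CPU time.

## From windows to per-sample features

A trained model embeds a window as the mean of its final-layer hidden
states over unpadded positions. Masked mean pooling makes padding inert: a
window and its PAD-extended copy embed identically. Pooling by mean rather
than max or last-token is our choice where the method description is
silent; the mean is the only one of the three that makes the later
window-to-chromosome average commute with window boundaries, and it is
trivially ablatable.

Windows are then aggregated in two stages:

1. **Chromosome vectors** — arithmetic mean of the window embeddings of one
   chromosome, so chromosomes of different lengths produce comparable
   vectors.
2. **Sample vectors** — either the element-wise mean of the chromosome
   vectors (**averaging fusion**, width `D_vec`, invariant to chromosome
   permutation) or their concatenation in a fixed, recorded chromosome
   order (**concatenation fusion**, width `n_chrom * D_vec`, block `k`
   recoverable as chromosome `k`'s vector). For the 20 chromosomes of a
   soybean-sized genome at `D_vec = 512`, concatenation gives the expected
   10,240-dimensional vector.

When `D_vec` is smaller than the model width, chromosome vectors are
reduced by principal components. The reducer is deterministic, serialized
next to the model, and — inside cross-validation — fitted on training folds
only, so no test-sample information leaks into the features. We reduce
per-chromosome *before* concatenation; reducing the concatenated vector
instead would entangle chromosomes and is left as an ablation.

## The trait-prediction harness

Traits are either quantitative (continuous) or qualitative (categorical).
The harness follows the evaluation protocol of genomic-selection studies:

* records with missing values are dropped; for qualitative traits, every
  category with fewer than `min_count` samples (default 50) is removed and
  logged. The default separates kept from removed categories in the
  published soybean tables, where kept categories have hundreds to
  thousands of samples and removed ones at most a few dozen;
* quantitative targets are min-max scaled to [0, 1], fitted on the
  training fold only and applied affinely to the test fold without
  clipping. MSE and MAE are reported on this normalized scale; the Pearson
  correlation is computed after mapping predictions back to the original
  trait scale (for an affine map the correlation is identical on either
  scale, so one training run per fold suffices);
* 10-fold cross-validation with fold sizes differing by at most one, every
  sample tested exactly once, and — for classification — folds stratified
  by label so small categories do not vanish from individual folds
  (a deliberate refinement of plain random folding);
* the reported metrics are per-fold values and their arithmetic mean.

Predictors are pluggable through a registry: gradient-boosted trees
(xgboost), random forest and extremely randomized trees (ranger),
k-nearest neighbours, penalized linear models (glmnet ridge), a
single-hidden-layer feed-forward network (nnet), and a small 1-D
convolutional network over the feature axis implemented in the package.
All run single-threaded with fixed seeds so repeated calls are identical.
Classification accuracy generalizes the binary confusion-matrix form
`(TP + TN) / (TP + TN + FP + FN)` to the multi-class fraction correct.

## The synthetic-data generator

The generator defines the study conditions for every test: it emulates the
statistical structure the pipeline assumes — one genome sequence per
accession, a panel of biallelic point variants, additive genetics — at a
scale a single CPU handles in minutes.

* **Reference genomes**: i.i.d. bases from a stated composition or an
  order-1 Markov chain; an optional planted oligomer at a stated insertion
  rate (positions logged).
* **Population**: `n_sites` polymorphic sites placed uniformly across
  chromosomes, alternate-allele frequencies drawn from [0.1, 0.5], haploid
  0/1 dosages per sample, and per-sample sequences equal to the reference
  with carried alleles substituted. Samples are haploid by design — each
  accession is one genome sequence; diploidy is out of scope.
* **Traits**: `n_qtl` causal sites with Gaussian effects; the quantitative
  trait is the genetic value plus Gaussian noise scaled so the realized
  heritability matches `h2`; a qualitative trait cuts the genetic value at
  rank quantiles into balanced classes. The architecture is additive only —
  sufficient for signal-recovery checks; epistasis is deliberately absent.

The default conditions for the end-to-end recovery check are 300 samples,
2 chromosomes of 10 kb, 100 polymorphic sites of which 20 are causal, and
h² = 0.8 — a marker density and architecture dense enough that a 64-dim
feature vector can carry the signal, while keeping the full pipeline run
(train, embed 12,000 windows, 21 cross-validated fits) inside a few
minutes. With those features the gradient-boosted predictor's mean
held-out correlation must exceed the 95th percentile of a 20-permutation
label-shuffled null computed on the same features.

What passing these tests shows — and what it does not: the synthetic
genomes have no linkage disequilibrium, no recombination map, no population
structure, and additive-only genetics, so success here demonstrates that
the pipeline's machinery (windowing, embedding, fusion, evaluation) is
correct and leak-free, not that the method attains any particular accuracy
on real crop data.

## Numerical and degenerate-input choices

* FFT length: next power of two at or above `2L - 1`; exactness is tested
  against the O(L²) oracle.
* Layer-norm epsilon 1e-5; GELU in tanh approximation.
* Constant training targets skip min-max scaling (identity transform), and
  a constant test fold records `NA` correlation rather than erroring.
* All-PAD windows are rejected by the embedder (nothing to pool) but
  accepted by the forward pass (finite logits).
* Ties in simulated genetic values are broken by rank so class counts stay
  balanced.
* Feature tables and chromosome-vector tables are written with 17
  significant digits, making disk round trips bit-identical.

## Problem sizes used by the test suite

Unit tests run at toy sizes (windows of 16–48 tokens, widths 8–16). The
verification suite uses the sizes stated above: 200 convolution instances,
20 causality probes, 400-window training corpora at `L_in = 256`, and one
full 300-sample pipeline at `L_in = 512` — chosen as the smallest sizes at
which each property is meaningfully exercised.

## Known limitations

* Contexts up to 32,768 tokens are accepted, but desk-scale training has
  only been exercised up to `L_in = 512`; nothing prevents longer runs
  beyond time.
* Single device, single thread: no distributed or multi-GPU training.
* The published pretrained genome checkpoints are not loadable; models
  train from scratch.
* Haploid genotypes only; no phasing, no per-genotype allele substitution
  inside the windowing layer.
* The harness evaluates one trait at a time; multi-trait joint models are
  out of scope.
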