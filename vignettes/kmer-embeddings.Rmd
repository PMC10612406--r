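---
title: "What a masked language model learns from overlapping k-mer tokens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{What a masked language model learns from overlapping k-mer tokens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kmerlm)
```

## The question

Genomic language models tokenize a DNA sequence of length $L$ into its
$L - k + 1$ overlapping k-mers and pre-train a BERT-style transformer with a
masked-language-model (MLM) objective. Because consecutive tokens share
$k - 1$ characters, masking a *single* token is trivial: its neighbours
reveal all of it. The standard remedy is **contiguous-k masking** — masking
runs of exactly $k$ consecutive tokens — after which, for an isolated
interior run, exactly **one** nucleotide of the underlying sequence cannot
be deduced from the flanking unmasked tokens. The nominal label space per
masked token is $4^k + 5$ (all k-mers plus the five special tokens
`[PAD] [UNK] [CLS] [SEP] [MASK]`), but the *non-trivially inferable* part of
the problem is only $4 + 5$: one free nucleotide plus the specials.

The MLM objective therefore decomposes into (i) a **data-independent**
subtask — emit predictions that are consistent with the overlap constraints
— and (ii) a **data-dependent** subtask — guess the one free nucleotide from
sequence statistics. This package reproduces, at desk scale, the analysis of
what each module of the model learns: pre-training on *random* sequences
isolates subtask (i), module-level re-initialization ("knockout") isolates
the contribution of the embedding vs the encoding module, and frozen-embedding
classifiers test whether the learned token representation alone is useful
downstream.

## The model

`build_model()` constructs a post-norm transformer encoder (learned absolute
position embeddings, GELU activations, multi-head attention) with an
explicit, total and disjoint parameter partition:

* **embedding module** — token ($V \times H$), position ($P \times H$) and
  token-type ($T \times H$) tables plus their layer-norm;
* **encoding module** — per layer: four $H \times H$ attention projections
  with biases, the two feed-forward matrices ($H \times F$, $F \times H$)
  with biases, and two layer-norms;
* **MLM head** — an untied $H \times V$ output projection with bias.

For the standard 5-mer architecture ($H = 768$, 12 layers, $F = 3072$,
$P = 512$, $T = 2$) the closed-form count gives 85,054,464 encoding
parameters, 98.6% of the embedding+encoding total. The head is counted
separately; including it in the denominator would not reproduce the
published share, which is why the partition excludes it (the corresponding
open question is noted in `count_parameters()`).

Weight tying between the token embedding and the MLM output projection is
available (`tie_embeddings = TRUE`, the arrangement HuggingFace-style BERT
models actually use) but **off by default** so that the embedding/encoding
partition stays clean; all reported analyses use the untied default.
Everything — initialization (truncated normal, sd 0.02), window sampling,
masking, dropout — is driven by explicit integer seeds, and forward/backward
passes are implemented in base R with hand-derived gradients (verified
against central finite differences in the test suite; no deep-learning
framework exists in the target environment).

## Masking, inferability, and the two consistency scores

`mask_contiguous()` samples non-overlapping run starts uniformly by
rejection; runs always have length exactly $k$ in sampled plans (truncated
boundary runs can be built with `manual_plan()` and then legitimately free
more than one nucleotide). Replacement actions follow the standard BERT
80/10/10 mask/random/keep mix, configurable because the original
overlapping-k-mer recipe does not state its mix; development-set evaluation
uses pure `[MASK]` corruption so the dev loss has a clean information-
theoretic floor ($\ln 4$ per fully flanked run token on i.i.d. uniform
data).

`analyze_inferability()` classifies each source nucleotide as *observed*
(covered by at least one unmasked token), *deducible* (masked-only but
forced by constraint propagation) or *free*. A subtle point the
implementation makes explicit: for whole-token masking the overlap
constraints only ever equate a source position with itself, so the
*deducible* class is structurally empty — a masked-only position is either
covered (observed) or free. The brute-force oracle in the tests (full
enumeration of all $4^9$ completions of a masked span, filtered against the
flanking tokens) confirms this.

Two different pairwise k-mer scores matter and must not be conflated:

* `overlap_score(a, b)` — **chainability**: the longest $m$ with
  suffix$_m$(a) = prefix$_m$(b) (either direction). This is the right score
  for *prediction* consistency: a predicted masked token is consistent when
  its nucleotides agree with the values forced by flanking unmasked tokens
  (`prediction_overlap_consistency()`), and a random predictor achieves
  $\approx 4/4^k$ on fully constrained run tokens.
* `affix_score(a, b)` — **shared affix**: the longest $m$ with equal
  $m$-prefixes or equal $m$-suffixes. This is the similarity that trained
  *embeddings* exhibit: the candidate set of a masked run token is a family
  of four k-mers sharing $k-1$ characters (same prefix for the first run
  position, same suffix for the last, same outer characters in between), and
  co-predicted tokens acquire similar representations.

`neighbor_overlap_statistic()` scores each k-mer's nearest embedding
neighbours (cosine by default, ties broken lexicographically) with one of
these scores and compares against a label-permutation null
($p = (1 + \#\{\text{null} \ge \text{obs}\})/(M+1)$, $M = 999$). The
default is the affix score: on a mini model pre-trained to full overlap
consistency the statistic sits ~30 null standard deviations above the null
($p = 10^{-3}$) while an untrained control is indistinguishable from it;
under the chainability score the same (correctly) clustered table scores
significantly *below* the null, because substitution families are
anti-chainable on average. We verified this both by direct enumeration and
on trained models: nearest neighbours of `ACG` in a trained table are
`ACC, ACA, ACT` (shared prefix) and `TCG, CCG` (shared suffix) — the
shared-affix families — which is the published phenomenon.

`central_nucleotide_separation()` quantifies the four central-base classes
(odd $k$) with a mean silhouette width on the full-dimensional rows; at desk
scale the effect is directional (trained > untrained) but small, consistent
with central-base clustering being a large-scale, many-epoch feature.
`project_2d()` (t-SNE via Rtsne, fixed seed) renders the qualitative
picture.

## The phase transition, and the training recipe

Overlap consistency is not learned gradually. With the mini configuration
(k = 3, $H = 64$, 2 layers, 4 heads, 32-token windows, batch 16, Adam with
10% linear warmup then linear decay from $3\times10^{-3}$), the dev loss
stays near the unigram entropy ($\approx \ln 64$, minus the specials) for
~2,500 steps and then drops sharply to the $\ln 4$ constraint floor by
~5,000 steps, at which point prediction consistency is 1.0. The pre-training
fixtures therefore run 5,000 steps. Higher learning rates
($10^{-2}$) destabilize the post-norm stack and never transition; shorter
runs stop in the pre-transition regime (loss $\approx$ 3.8–3.9, consistency
near baseline). The 1-mer control model has no overlap structure to exploit
and plateaus at the $\ln 4$ floor with masked accuracy 0.25 on uniform
random text — any predictor's expected accuracy under i.i.d. uniform bases.

## The synthetic world

All inputs are generated:

* **Random corpus** — i.i.d. uniform A/C/G/T (`background_model(0)`), the
  stand-in for the ~3-billion-base random pre-training corpus, scaled to
  ~200 kb (400 sequences of 500 bp) for the fixtures.
* **Structured corpus** — an order-1 Markov chain
  (`default_markov_model()`) with repeat-like self-transitions and CpG
  depletion, standing in for genomic text. It provides learnable context for
  the data-dependent subtask; it does not model repeats, isochores, coding
  bias or any real-genome feature beyond first-order structure.
* **Motif discovery sets** — 101 bp backgrounds with one PWM instance
  implanted uniformly at random; negatives are Altschul–Erikson
  dinucleotide-preserving shuffles of their paired positives (exact
  dinucleotide multiset, same endpoints), so composition is uninformative
  and only the intact motif separates the classes.
* **Motif occupancy sets** — positives with a centered instance; negatives
  are fresh backgrounds rejection-matched in GC (±2%) carrying a centered
  instance matched in PWM log-likelihood (±1 nat). By construction the
  *stated* covariates cannot classify; at desk scale this task carries
  essentially no residual signal, mirroring its "harder than discovery"
  role.
* **TATA promoter sets** — 300 bp windows emulating −249..+50 around a TSS;
  positives implant a TATA-box PWM at the canonical −30 offset, negatives
  implant the same PWM at a uniformly random non-canonical position, so
  motif *presence* cannot classify — only its position can (this mirrors the
  motif-containing negatives of the real resource). Non-TATA positives are
  GC-biased backgrounds; negatives replace 12 of 20 equal segments with
  fresh uniform background, the published baseline convention for that
  dataset family, which the source text describes with the positive/negative
  roles apparently transposed — we follow the baseline convention.

A green test on this world establishes that the *mechanisms* behave as
described (implants present, pairs matched, splits exact, statistics
calibrated); it does not establish performance on real EPDnew/ENCODE data.

## Downstream evaluation

`cnn_config()`/`train_classifier()` implement the simplified frozen-
embedding classifier: embedding lookup (frozen by default) → parallel valid
convolutions of widths 7/14/27 tokens → ReLU → global max pooling → dense →
sigmoid, Adam on binary cross-entropy, ten epochs, model selection by
development-set MCC — deliberately one auditable architecture rather than
the multi-branch original, since the claims under test concern the embedding
layer. `evaluate()` reports accuracy/F1/MCC at a 0.5 threshold plus AUROC
(midrank formula, equal to brute-force pair counting) and AUPRC (step
integration over distinct score thresholds). Full-model fine-tuning for the
knockout ablation (`finetune_classifier()`) attaches a sigmoid head to the
`[CLS]` state and updates all modules.

## Numerical choices

* Layer-norm epsilon $10^{-6}$; softmax computed with row-max subtraction.
* Adam $\beta = (0.9, 0.999)$, $\epsilon = 10^{-8}$; gradient flows are
  exact (no clipping); the learning-rate floor after decay is 5% of peak so
  late-run evaluation points remain informative.
* Dev loss smoothing $\alpha = 0.1$; convergence = first eval point with
  smoothed loss at or below threshold (optional patience).
* Dinucleotide shuffle: random last-exit edges retried until they form an
  arborescence into the terminal vertex, then per-vertex edge permutation —
  the classical Euler-path construction, giving exact dinucleotide-count
  preservation.
* GC matching by rejection with 1,000 attempts; occupancy strength matching
  within ±1 nat of PWM log-likelihood.
* Nearest-neighbour distance ties break lexicographically for determinism.
  On an all-equidistant table (one-hot) the neighbour sets are then *purely*
  the tie-break, which mechanically inflates the affix score (lexicographic
  neighbours share prefixes); calibration checks on such degenerate tables
  therefore use the chain score, and trained tables — which have no ties —
  are unaffected.
* All derived seeds are mixed into [0, 2^31) with a fixed multiplicative
  scheme; no global RNG state leaks (`local_seed()` restores
  `.Random.seed`).

## Known limitations

* Desk scale only: two layers, $H = 64$, ~200 kb corpora. Absolute numbers
  (losses, step counts, AUROCs) are not comparable to GPU-scale published
  values; only directions and mechanisms are.
* The warm-start contrast at reduced step budgets shows the warm arm
  starting essentially converged on the data-independent subtask while the
  cold arm has not transitioned yet; the paired step difference is therefore
  extreme rather than the published ~1500 vs ~5500.
* The central-base silhouette is near zero (though ordered) at this scale.
* `N` bases are rejected, not handled; no reverse-complement awareness; no
  sliding windows beyond `max_positions`.
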