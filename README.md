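# kmerlm

Masked language models over overlapping k-mer nucleotide tokens — a
desk-scale laboratory for studying *what* BERT-style genomic language models
learn during pre-training, and whether their token embeddings are useful on
their own.

## The scientific problem

Genomic BERT models tokenize DNA into overlapping k-mers (a sequence of
length $L$ becomes $L-k+1$ tokens, consecutive tokens sharing $k-1$
characters) and pre-train by masking runs of $k$ contiguous tokens. For an
isolated masked run, all but **one** nucleotide is deducible from the
flanking unmasked tokens, so the effective label space collapses from
$4^k + 5$ (k-mers + 5 special tokens) to $4 + 5$. Masked-token prediction
therefore splits into a *data-independent* subtask — produce predictions
consistent with the overlap constraints — and a *data-dependent* subtask —
infer the one free nucleotide. This package implements, entirely from
synthetic data and in pure R:

* the overlapping k-mer vocabulary, contiguous-k masking, and a
  nucleotide-level inferability analysis (`build_vocabulary`, `tokenize`,
  `mask_contiguous`, `analyze_inferability`);
* a reproducible transformer encoder with an explicit embedding / encoding /
  head parameter partition, module "knockout" re-initialization, checkpoint
  IO, and embedding extraction (`build_model`, `count_parameters`,
  `reinitialize_module`, `extract_token_embeddings`);
* an MLM pre-training loop with smoothed dev-loss tracking, convergence
  detection, warm starts, masked accuracy and prediction overlap-consistency
  (`pretrain`, `warm_start_pretrain`, `convergence_step`,
  `prediction_overlap_consistency`);
* synthetic corpora and benchmark datasets: random and Markov backgrounds,
  PWM motif implants, Altschul–Erikson dinucleotide-preserving shuffles,
  GC/strength-matched occupancy negatives, TATA / non-TATA promoter sets
  (`generate_background`, `dinucleotide_shuffle`,
  `make_motif_discovery_dataset`, `make_promoter_dataset`, ...);
* embedding-geometry statistics with permutation nulls, central-base
  silhouettes and t-SNE projections (`neighbor_overlap_statistic`,
  `central_nucleotide_separation`, `project_2d`);
* a frozen-embedding CNN classifier with a full metric suite
  (`cnn_config`, `train_classifier`, `evaluate`: accuracy, F1, MCC, AUROC,
  AUPRC), full-model fine-tuning (`finetune_classifier`), and experiment
  drivers for the four comparative studies (`run_experiment`).

## Worked example

```r
library(kmerlm)

v <- build_vocabulary(5)
v
#> <kmer_vocab> k=5, 1029 tokens (4^5 + 5)

count_parameters(model_config(k = 5))
#> <parameter_count> embedding=1,186,560 encoding=85,054,464 head=791,301
#>                   encoding share=98.6%

# an isolated run of 5 contiguous masked 5-mers leaves ONE free nucleotide
s  <- generate_background(background_model(0), 40, seed = 8)
ts <- tokenize(s, v)
analyze_inferability(ts, manual_plan(ts, 10, 5))
#> <inferability_report> observed=39 deducible=0 free=1
non_trivial_label_space(v)
#> [1] 9

# motif discovery with dinucleotide-shuffled negatives, frozen one-hot CNN
motif <- consensus_pwm("GATTACAG", noise = 0)
ds  <- make_motif_discovery_dataset(motif, background_model(0),
                                    n = 600, L = 101, seed = 1)
clf <- build_classifier(cnn_config(one_hot_table(3), n_kernels = 16L,
                                   epochs = 8L, seed = 1),
                        input_length_tokens = 99L)
tr  <- train_classifier(clf, ds)
tr$dev_mcc
#> [1] 0.905            # best dev-epoch MCC (epoch 7)
evaluate(tr$classifier, ds)
#> <metrics> n=60 acc=0.9667 F1=0.9655 MCC=0.9354 AUROC=0.9911 AUPRC=0.9921
```

The parameter accounting shows the encoding module holding ~98.6% of the
embedding+encoding parameters (~85 M for the standard 5-mer architecture);
the inferability report verifies the contiguous-masking arithmetic; and the
frozen-embedding CNN separates implanted motifs from
composition-matched shuffles almost perfectly — the baseline against which
model-extracted k-mer embeddings are compared (see the vignette and
`run_embedding_comparison()`).

## Command line

An installed script exposes the main stages:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/kmerlm.R", package="kmerlm"))')" \
    gen-data --task motif_discovery --n 2000 --seed 1 --outdir out/
# subcommands: gen-data, pretrain, count-params, extract-embeddings,
#              analyze-embeddings, train-downstream, run-experiment
```

## Further reading

The methods vignette (`vignettes/kmer-embeddings.Rmd`) documents the model
and its assumptions, the synthetic-data world and what green tests do and do
not establish, the two k-mer similarity scores (chainability vs shared
affix) and why the embedding statistic uses the latter, the pre-training
phase transition that motivates the 5,000-step fixtures, and known
limitations.
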