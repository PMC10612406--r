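#' Desk-scale comparative experiments
#'
#' Drivers for the four comparative analyses: the pre-training contrast
#' (random vs structured corpora vs untrained, scored by embedding-geometry
#' statistics), the module-knockout downstream ablation, the frozen-embedding
#' comparison, and the warm-start contrast. Every run is reproducible from
#' (spec, seeds); per-arm failures are recorded without aborting sibling
#' arms.
#'
#' @name experiments
NULL

#' Default structured (order-1 Markov) background: a stand-in for genomic
#' text with repeat-like self-transitions and CpG depletion.
#' @return A [background_model()] of order 1.
#' @export
default_markov_model <- function() {
  P <- matrix(c(0.45, 0.15, 0.25, 0.15,
                0.25, 0.35, 0.05, 0.35,
                0.30, 0.20, 0.35, 0.15,
                0.15, 0.20, 0.30, 0.35),
              4, 4, byrow = TRUE,
              dimnames = list(DNA_BASES, DNA_BASES))
  background_model(1, P)
}

#' Experiment specification
#'
#' @param experiment One of `pretrain_contrast`, `embedding_comparison`,
#'   `downstream_ablation`, `warm_start`.
#' @param seeds Integer vector of run seeds (>= 1 seed).
#' @param scale Named list of scale knobs; missing entries take desk-scale
#'   defaults (corpus ~2e6 bases via 4000 x 500 bp sequences, mini k=3
#'   model, 2000 steps, n = 2000 per labeled dataset).
#' @param outdir Output directory (created on demand) or `NULL`.
#' @return An object of class `experiment_spec`.
#' @export
experiment_spec <- function(experiment = c("pretrain_contrast",
                                           "embedding_comparison",
                                           "downstream_ablation",
                                           "warm_start"),
                            seeds = c(1L, 2L, 3L), scale = list(),
                            outdir = NULL) {
  experiment <- match.arg(experiment)
  if (length(seeds) < 1L) stop_param("need at least one seed")
  defaults <- list(
    n_corpus_seqs = 4000L, corpus_seq_len = 500L,
    k = 3L, hidden = 64L, layers = 2L, heads = 4L, ffn = 256L,
    max_positions = 128L,
    steps = 2000L, eval_every = 100L, batch = 8L, window_tokens = 48L,
    lr = 3e-3, mask_rate = 0.15,
    n_dataset = 2000L, dataset_L = 101L,
    n_eval_windows = 150L,
    threshold = 1.6, finetune_epochs = 3L, finetune_lr = 3e-4,
    cnn_epochs = 10L, onehot_ks = 1:5,
    external_table = NULL
  )
  scale <- utils::modifyList(defaults, scale)
  structure(list(experiment = experiment, seeds = as.integer(seeds),
                 scale = scale, outdir = outdir),
            class = "experiment_spec")
}

experiment_report <- function(experiment, rows, spec, metric_cols) {
  rows <- as.data.frame(rows)
  aggregates <- NULL
  if (nrow(rows) > 0) {
    aggregates <- do.call(rbind, lapply(split(rows, rows$arm), function(g) {
      out <- data.frame(arm = g$arm[1], n_runs = nrow(g))
      for (mc in metric_cols) {
        out[[paste0(mc, "_mean")]] <- mean(g[[mc]], na.rm = TRUE)
        out[[paste0(mc, "_sd")]] <- stats::sd(g[[mc]])
      }
      out
    }))
    rownames(aggregates) <- NULL
  }
  structure(list(experiment = experiment, rows = rows,
                 aggregates = aggregates,
                 provenance = list(seeds = spec$seeds,
                                   config_hash = config_hash(spec$scale))),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %s: %d rows\n", x$experiment,
              nrow(x$rows)))
  if (!is.null(x$aggregates)) print(x$aggregates, digits = 4)
  invisible(x)
}

#' Write an experiment report (rows as TSV, full report as JSON)
#' @param report An `experiment_report`.
#' @param dir Output directory.
#' @export
write_experiment_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(report$rows, file.path(dir, "rows.tsv"), sep = "\t")
  jsonlite::write_json(
    list(experiment = report$experiment,
         aggregates = report$aggregates,
         provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}

#' Pre-train one arm model for an experiment
#' @noRd
pretrain_arm <- function(spec, corpus, seed, init_state = NULL) {
  sc <- spec$scale
  cfg <- mini_model_config(k = sc$k, hidden = sc$hidden, layers = sc$layers,
                           heads = sc$heads, ffn = sc$ffn,
                           max_positions = sc$max_positions, seed = seed)
  state <- if (is.null(init_state)) build_model(cfg) else init_state
  pretrain(state, corpus,
           mask_cfg = list(rate = sc$mask_rate),
           opt_cfg = list(steps = sc$steps, eval_every = sc$eval_every,
                          batch = sc$batch, window_tokens = sc$window_tokens,
                          lr = sc$lr),
           seed = seed)
}

#' Pre-training contrast: random vs structured corpora vs untrained
#'
#' For every seed, trains one model on an i.i.d. uniform corpus and one on
#' an order-1 Markov corpus, keeps an untrained control, and scores each
#' arm's extracted token embeddings with [neighbor_overlap_statistic()] and
#' [central_nucleotide_separation()].
#'
#' @param spec An [experiment_spec()].
#' @return An `experiment_report` with one row per (arm, seed).
#' @export
run_pretrain_contrast <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  sc <- spec$scale
  rows <- list()
  for (seed in spec$seeds) {
    rnd_corpus <- generate_corpus(background_model(0), sc$n_corpus_seqs,
                                  sc$corpus_seq_len, seed = mix_seed(seed, 1L))
    mkv_corpus <- generate_corpus(default_markov_model(), sc$n_corpus_seqs,
                                  sc$corpus_seq_len, seed = mix_seed(seed, 2L))
    arms <- list()
    arms$untrained <- build_model(mini_model_config(
      k = sc$k, hidden = sc$hidden, layers = sc$layers, heads = sc$heads,
      ffn = sc$ffn, max_positions = sc$max_positions, seed = seed))
    arms$trained_random <- tryCatch(
      pretrain_arm(spec, rnd_corpus, seed)$state, error = identity)
    arms$trained_markov <- tryCatch(
      pretrain_arm(spec, mkv_corpus, seed)$state, error = identity)
    for (arm in names(arms)) {
      st <- arms[[arm]]
      if (inherits(st, "error")) {
        warning(sprintf("arm %s seed %d failed: %s", arm, seed,
                        conditionMessage(st)))
        next
      }
      tab <- extract_token_embeddings(st)
      nos <- neighbor_overlap_statistic(tab, seed = mix_seed(seed, 5L))
      sep <- central_nucleotide_separation(tab)
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, seed = seed,
        observed_mean_overlap = nos$observed_mean_overlap,
        null_mean = nos$null_mean, null_sd = nos$null_sd,
        z = nos$z, empirical_p = nos$empirical_p,
        silhouette = sep$silhouette)
    }
  }
  experiment_report("pretrain_contrast", do.call(rbind, rows), spec,
                    c("observed_mean_overlap", "z", "empirical_p",
                      "silhouette"))
}

#' Module-knockout downstream ablation
#'
#' Four arms mirroring the standard / data-randomized / encoder-knockout /
#' fully-random contrast: a model pre-trained on structured (Markov) text,
#' one pre-trained on random text, the structured model with its encoding
#' module re-initialized (embeddings retained), and an entirely untrained
#' model. Each arm is fine-tuned end-to-end on a synthetic TATA promoter
#' dataset and evaluated on its test split.
#'
#' @param spec An [experiment_spec()]; `scale$max_positions` must cover the
#'   promoter length (use >= 304 for L = 300).
#' @return An `experiment_report` with accuracy/F1/MCC/AUROC/AUPRC per
#'   (arm, seed).
#' @export
run_downstream_ablation <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  sc <- spec$scale
  rows <- list()
  for (seed in spec$seeds) {
    rnd_corpus <- generate_corpus(background_model(0), sc$n_corpus_seqs,
                                  sc$corpus_seq_len, seed = mix_seed(seed, 1L))
    mkv_corpus <- generate_corpus(default_markov_model(), sc$n_corpus_seqs,
                                  sc$corpus_seq_len, seed = mix_seed(seed, 2L))
    structured <- pretrain_arm(spec, mkv_corpus, seed)$state
    data_rand <- pretrain_arm(spec, rnd_corpus, seed)$state
    enc_rand <- reinitialize_module(structured, "encoding",
                                    seed = mix_seed(seed, 3L))
    all_rand <- build_model(mini_model_config(
      k = sc$k, hidden = sc$hidden, layers = sc$layers, heads = sc$heads,
      ffn = sc$ffn, max_positions = sc$max_positions,
      seed = mix_seed(seed, 4L)))
    ds <- make_promoter_dataset(tata_pwm(), background_model(0),
                                n = sc$n_dataset, L = 300L,
                                variant = "tata", seed = mix_seed(seed, 6L))
    arms <- list(structured = structured, data_rand = data_rand,
                 enc_rand = enc_rand, all_rand = all_rand)
    for (arm in names(arms)) {
      res <- tryCatch({
        ft <- finetune_classifier(arms[[arm]], ds, lr = sc$finetune_lr,
                                  epochs = sc$finetune_epochs,
                                  batch = sc$batch, seed = seed)
        evaluate_finetuned(ft, ds)
      }, error = identity)
      if (inherits(res, "error")) {
        warning(sprintf("arm %s seed %d failed: %s", arm, seed,
                        conditionMessage(res)))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, seed = seed, accuracy = res$accuracy, F1 = res$F1,
        MCC = res$MCC, AUROC = res$AUROC, AUPRC = res$AUPRC)
    }
  }
  experiment_report("downstream_ablation", do.call(rbind, rows), spec,
                    c("accuracy", "F1", "MCC", "AUROC", "AUPRC"))
}

#' Frozen-embedding comparison
#'
#' Trains the frozen-embedding CNN on identical motif-discovery datasets
#' (paired splits across arms) with: one-hot tables for the configured k
#' values, an optional external word2vec-format table, and token embeddings
#' extracted from mini models pre-trained on random and on Markov text.
#'
#' @param spec An [experiment_spec()].
#' @return An `experiment_report` with one row per (arm, seed).
#' @export
run_embedding_comparison <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  sc <- spec$scale
  motif <- consensus_pwm("GATTACAG", noise = 0.02, name = "bench")
  first_seed <- spec$seeds[1]
  rnd_corpus <- generate_corpus(background_model(0), sc$n_corpus_seqs,
                                sc$corpus_seq_len,
                                seed = mix_seed(first_seed, 1L))
  mkv_corpus <- generate_corpus(default_markov_model(), sc$n_corpus_seqs,
                                sc$corpus_seq_len,
                                seed = mix_seed(first_seed, 2L))
  model_tables <- list(
    model_random = extract_token_embeddings(
      pretrain_arm(spec, rnd_corpus, first_seed)$state),
    model_markov = extract_token_embeddings(
      pretrain_arm(spec, mkv_corpus, first_seed)$state)
  )
  arms <- c(stats::setNames(
    lapply(sc$onehot_ks, one_hot_table),
    sprintf("one_hot_k%d", sc$onehot_ks)), model_tables)
  if (!is.null(sc$external_table)) {
    ext <- tryCatch(load_embedding_table(sc$external_table),
                    error = identity)
    if (inherits(ext, "error")) {
      warning(sprintf("external table skipped: %s", conditionMessage(ext)))
    } else {
      arms$external <- ext
    }
  }
  rows <- list()
  for (seed in spec$seeds) {
    ds <- make_motif_discovery_dataset(motif, background_model(0),
                                       n = sc$n_dataset, L = sc$dataset_L,
                                       seed = mix_seed(seed, 11L))
    for (arm in names(arms)) {
      res <- tryCatch({
        tab <- arms[[arm]]
        k_arm <- nchar(drop_specials(tab)$labels[1])
        clf <- build_classifier(
          cnn_config(tab, seed = seed, epochs = sc$cnn_epochs),
          input_length_tokens = sc$dataset_L - k_arm + 1L)
        tr <- train_classifier(clf, ds)
        list(m = evaluate(tr$classifier, ds), dim = ncol(drop_specials(tab)$matrix))
      }, error = identity)
      if (inherits(res, "error")) {
        warning(sprintf("arm %s seed %d failed: %s", arm, seed,
                        conditionMessage(res)))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, seed = seed, input_dim = res$dim,
        accuracy = res$m$accuracy, F1 = res$m$F1, MCC = res$m$MCC,
        AUROC = res$m$AUROC, AUPRC = res$m$AUPRC)
    }
  }
  experiment_report("embedding_comparison", do.call(rbind, rows), spec,
                    c("accuracy", "F1", "MCC", "AUROC", "AUPRC"))
}

#' Warm-start contrast
#'
#' For every seed, pre-trains on a structured Markov corpus twice: cold
#' (fresh initialization) and warm (initialized from a checkpoint
#' pre-trained on random text with the same architecture), and records the
#' first step at which the smoothed dev loss crosses `scale$threshold`.
#'
#' @param spec An [experiment_spec()].
#' @return An `experiment_report` with convergence steps and paired
#'   differences (warm minus cold; non-crossing runs count as `Inf`).
#' @export
run_warm_start <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  sc <- spec$scale
  rows <- list()
  for (seed in spec$seeds) {
    rnd_corpus <- generate_corpus(background_model(0), sc$n_corpus_seqs,
                                  sc$corpus_seq_len, seed = mix_seed(seed, 1L))
    mkv_corpus <- generate_corpus(default_markov_model(), sc$n_corpus_seqs,
                                  sc$corpus_seq_len, seed = mix_seed(seed, 2L))
    init_state <- pretrain_arm(spec, rnd_corpus, seed)$state
    cold <- pretrain_arm(spec, mkv_corpus, seed)
    warm <- warm_start_pretrain(init_state, mkv_corpus,
                                mask_cfg = list(rate = sc$mask_rate),
                                opt_cfg = list(steps = sc$steps,
                                               eval_every = sc$eval_every,
                                               batch = sc$batch,
                                               window_tokens = sc$window_tokens,
                                               lr = sc$lr),
                                seed = seed)
    for (arm in c("cold", "warm")) {
      log <- if (arm == "cold") cold$log else warm$log
      cv <- convergence_step(log, sc$threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm, seed = seed,
        step_reached = ifelse(is.na(cv$step_reached), Inf, cv$step_reached),
        initial_dev_loss = log$evals$dev_loss[1],
        final_smoothed = utils::tail(log$evals$smoothed_loss, 1))
    }
  }
  rows <- do.call(rbind, rows)
  rep <- experiment_report("warm_start", rows, spec,
                           c("step_reached", "initial_dev_loss",
                             "final_smoothed"))
  wide <- merge(rows[rows$arm == "warm", c("seed", "step_reached")],
                rows[rows$arm == "cold", c("seed", "step_reached")],
                by = "seed", suffixes = c("_warm", "_cold"))
  rep$paired_differences <- wide$step_reached_warm - wide$step_reached_cold
  rep
}

#' Run the experiment named in a spec
#' @param spec An [experiment_spec()].
#' @return An `experiment_report` (also written to `spec$outdir` if set).
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  rep <- switch(spec$experiment,
                pretrain_contrast = run_pretrain_contrast(spec),
                embedding_comparison = run_embedding_comparison(spec),
                downstream_ablation = run_downstream_ablation(spec),
                warm_start = run_warm_start(spec))
  if (!is.null(spec$outdir)) write_experiment_report(rep, spec$outdir)
  rep
}
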