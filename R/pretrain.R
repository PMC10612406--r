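#' Masked-language-model pre-training
#'
#' Minimal but complete MLM pre-training loop: fixed-length windows are
#' sampled uniformly from the corpus, tokenized into overlapping k-mers,
#' masked with contiguous-k runs, and the model is trained with Adam (linear
#' warmup then linear decay). Development loss is evaluated on a fixed set
#' of held-out batches every `eval_every` steps and smoothed with an
#' exponential moving average.
#'
#' @name pretraining
NULL

default_opt_cfg <- function() {
  list(lr = 1e-3, batch = 8L, steps = 500L, eval_every = 25L,
       warmup_frac = 0.1, window_tokens = 64L, n_dev_batches = 4L)
}

default_mask_cfg <- function() {
  # dev evaluation uses pure-[MASK] corruption so the dev loss has a clean
  # entropy-floor interpretation (ln 4 per fully-flanked run token)
  list(rate = 0.15, action_probs = c(mask = 0.8, random = 0.1, keep = 0.1),
       dev_action_probs = c(mask = 1, random = 0, keep = 0))
}

#' Sample one training batch of masked windows
#' @noRd
sample_batch <- function(corpus, vocab, window_tokens, batch, rate,
                         action_probs, seed) {
  k <- vocab$k
  wlen <- window_tokens + k - 1L
  lens <- nchar(corpus)
  eligible <- which(lens >= wlen)
  if (length(eligible) == 0L) {
    stop_param("no corpus sequence is long enough for %d-token windows",
               window_tokens)
  }
  Tt <- window_tokens + 2L
  ids <- matrix(0L, batch, Tt)
  predict_pos <- integer(0)
  target_ids <- integer(0)
  for (b in seq_len(batch)) {
    sb <- mix_seed(seed, b)
    pick <- local_seed(sb, {
      i <- eligible[sample.int(length(eligible), 1L)]
      s <- sample.int(lens[i] - wlen + 1L, 1L)
      c(i, s)
    })
    win <- substr(corpus[pick[1]], pick[2], pick[2] + wlen - 1L)
    ts <- tokenize(win, vocab, add_specials = TRUE)
    plan <- mask_contiguous(ts, rate, rng_seed = mix_seed(sb, 7L),
                            action_probs = action_probs)
    ap <- local_seed(mix_seed(sb, 11L), apply_plan(ts, plan))
    ids[b, ] <- ap$input_ids
    predict_pos <- c(predict_pos, (b - 1L) * Tt + ap$predict_pos)
    target_ids <- c(target_ids, ap$target_ids)
  }
  list(ids = ids, predict_pos = predict_pos, target_ids = target_ids)
}

#' One forward/backward pass, returning loss and full gradient list
#' @noRd
mlm_step_grads <- function(state, batch, drop_seed = NULL) {
  fw <- forward_transformer(state, batch$ids, train = TRUE,
                            drop_seed = drop_seed)
  hb <- mlm_head_fwd_bwd(state, fw$X, batch$predict_pos, batch$target_ids)
  dX <- matrix(0, nrow(fw$X), ncol(fw$X))
  dX[batch$predict_pos, ] <- hb$dXm
  grads <- backward_transformer(state, fw$cache, dX)
  grads$head.W <- hb$g_headW
  grads$head.b <- hb$g_headb
  if (!is.null(hb$g_emb_tok)) grads$emb.tok <- grads$emb.tok + hb$g_emb_tok
  list(loss = hb$loss, grads = grads)
}

#' Batch MLM loss without gradients
#' @noRd
mlm_batch_loss <- function(state, batch) {
  fw <- forward_transformer(state, batch$ids, train = FALSE)
  hb <- mlm_head_fwd_bwd(state, fw$X, batch$predict_pos, batch$target_ids,
                         want_grad = FALSE)
  list(loss = hb$loss, n = length(batch$predict_pos), preds = hb$preds)
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0L)
}

adam_update <- function(params, grads, opt, lr, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - b1^opt$t
  c2 <- 1 - b2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / c1) / (sqrt(opt$v[[nm]] / c2) + eps)
  }
  list(params = params, opt = opt)
}

lr_schedule <- function(step, steps, lr, warmup_frac) {
  warmup <- max(1, floor(steps * warmup_frac))
  if (step <= warmup) return(lr * step / warmup)
  lr * max(0.05, (steps - step) / max(1, steps - warmup))
}

#' Pre-train a masked language model
#'
#' @param state A [build_model()] state (or a warm-start copy).
#' @param corpus Character vector of nucleotide strings.
#' @param mask_cfg list(rate, action_probs); default 15% with the 80/10/10
#'   mask/random/keep replacement mix.
#' @param opt_cfg list(lr, batch, steps, eval_every, warmup_frac,
#'   window_tokens, n_dev_batches).
#' @param dev_corpus Held-out sequences for dev loss; if `NULL`, 20% of
#'   `corpus` is held out (and removed from the training stream).
#' @param seed Integer seed governing window sampling, masking and dropout;
#'   runs are deterministic given (state, corpus, configs, seed).
#' @param alpha Exponential smoothing factor for the dev-loss curve
#'   (default 0.1).
#' @return list(state, log) where `log` is a `pretrain_log` with an `evals`
#'   data.frame (step, dev_loss, smoothed_loss).
#' @export
pretrain <- function(state, corpus, mask_cfg = list(), opt_cfg = list(),
                     dev_corpus = NULL, seed = 1L, alpha = 0.1) {
  stopifnot(inherits(state, "model_state"))
  if (length(corpus) == 0L || all(nchar(corpus) == 0L)) {
    stop_param("empty corpus")
  }
  mask_cfg <- utils::modifyList(default_mask_cfg(), mask_cfg)
  opt_cfg <- utils::modifyList(default_opt_cfg(), opt_cfg)
  vocab <- state$vocab
  if (is.null(dev_corpus)) {
    n_dev <- max(1L, floor(0.2 * length(corpus)))
    dev_idx <- local_seed(mix_seed(seed, 424243L),
                          sample.int(length(corpus), n_dev))
    dev_corpus <- corpus[dev_idx]
    if (length(corpus) > n_dev) corpus <- corpus[-dev_idx]
  }
  dev_batches <- lapply(seq_len(opt_cfg$n_dev_batches), function(i) {
    sample_batch(dev_corpus, vocab, opt_cfg$window_tokens, opt_cfg$batch,
                 mask_cfg$rate, mask_cfg$dev_action_probs,
                 seed = mix_seed(seed, 777000L + i))
  })
  eval_dev <- function(st) {
    tot <- 0; n <- 0
    for (b in dev_batches) {
      r <- mlm_batch_loss(st, b)
      tot <- tot + r$loss * r$n
      n <- n + r$n
    }
    tot / n
  }

  opt <- adam_init(state$params)
  evals <- data.frame(step = 0L, dev_loss = eval_dev(state),
                      smoothed_loss = NA_real_)
  evals$smoothed_loss[1] <- evals$dev_loss[1]
  smoothed <- evals$dev_loss[1]

  for (step in seq_len(opt_cfg$steps)) {
    batch <- sample_batch(corpus, vocab, opt_cfg$window_tokens, opt_cfg$batch,
                          mask_cfg$rate, mask_cfg$action_probs,
                          seed = mix_seed(seed, step))
    sg <- mlm_step_grads(state, batch, drop_seed = mix_seed(seed, step + 500000L))
    if (!is.finite(sg$loss)) {
      stop_param("non-finite training loss at step %d (lr too high?)", step)
    }
    lr_t <- lr_schedule(step, opt_cfg$steps, opt_cfg$lr, opt_cfg$warmup_frac)
    upd <- adam_update(state$params, sg$grads, opt, lr_t)
    state$params <- upd$params
    opt <- upd$opt
    if (step %% opt_cfg$eval_every == 0L || step == opt_cfg$steps) {
      dl <- eval_dev(state)
      if (!is.finite(dl)) stop_param("non-finite dev loss at step %d", step)
      smoothed <- alpha * dl + (1 - alpha) * smoothed
      evals <- rbind(evals, data.frame(step = step, dev_loss = dl,
                                       smoothed_loss = smoothed))
    }
  }
  state$provenance <- c(state$provenance,
                        list(pretrain = list(seed = seed,
                                             steps = opt_cfg$steps,
                                             config_hash = config_hash(
                                               list(mask_cfg, opt_cfg)))))
  log <- structure(
    list(evals = evals, alpha = alpha, mask_cfg = mask_cfg,
         opt_cfg = opt_cfg, seed = seed),
    class = "pretrain_log"
  )
  list(state = state, log = log)
}

#' @export
print.pretrain_log <- function(x, ...) {
  n <- nrow(x$evals)
  cat(sprintf("<pretrain_log> %d evals; dev loss %.4f -> %.4f (smoothed %.4f)\n",
              n, x$evals$dev_loss[1], x$evals$dev_loss[n],
              x$evals$smoothed_loss[n]))
  invisible(x)
}

#' Warm-start pre-training from an existing checkpoint
#'
#' Identical contract to [pretrain()], but initial weights are copied from
#' `init_from`, whose configuration must match `state`-building
#' expectations (vocabulary and all architectural dimensions).
#'
#' @param init_from A `model_state` to copy weights from.
#' @inheritParams pretrain
#' @return list(state, log); the log echoes the init provenance.
#' @export
warm_start_pretrain <- function(init_from, corpus, mask_cfg = list(),
                                opt_cfg = list(), dev_corpus = NULL,
                                seed = 1L, alpha = 0.1) {
  stopifnot(inherits(init_from, "model_state"))
  res <- pretrain(init_from, corpus, mask_cfg, opt_cfg, dev_corpus, seed,
                  alpha)
  res$log$warm_start <- list(init_provenance = init_from$provenance)
  res$state$provenance <- c(res$state$provenance, list(warm_started = TRUE))
  res
}

#' Check two model states are architecture-compatible
#' @noRd
check_config_compatible <- function(a, b) {
  fields <- c("k", "vocab_size", "hidden", "layers", "heads", "ffn",
              "max_positions", "type_vocab")
  for (f in fields) {
    if (!identical(a$config[[f]], b$config[[f]])) {
      stop_param("config mismatch on '%s': %s vs %s", f,
                 a$config[[f]], b$config[[f]])
    }
  }
  invisible(TRUE)
}

#' First crossing of a smoothed-loss threshold
#'
#' @param log A `pretrain_log`.
#' @param threshold Threshold in nats on the smoothed dev loss.
#' @param patience Number of consecutive eval points required at or below
#'   the threshold (default 1).
#' @return list(threshold, step_reached (NA if never), patience).
#' @export
convergence_step <- function(log, threshold, patience = 1L) {
  stopifnot(inherits(log, "pretrain_log"))
  ev <- log$evals
  ok <- ev$smoothed_loss <= threshold
  step_reached <- NA_integer_
  run <- 0L
  for (i in seq_along(ok)) {
    run <- if (ok[i]) run + 1L else 0L
    if (run >= patience) {
      step_reached <- ev$step[i - patience + 1L]
      break
    }
  }
  structure(list(threshold = threshold, step_reached = step_reached,
                 patience = as.integer(patience)),
            class = "convergence_result")
}

#' Build a fixed evaluation set of masked windows
#'
#' @param corpus Character vector of sequences.
#' @param vocab A [build_vocabulary()] object.
#' @param n_windows Number of windows.
#' @param window_tokens Interior tokens per window.
#' @param rate Masking rate.
#' @param seed Integer seed.
#' @param action_probs Replacement mix (default pure `[MASK]`, the cleanest
#'   setting for accuracy/consistency evaluation).
#' @return List of `list(ts, plan)` pairs.
#' @export
make_mlm_eval_set <- function(corpus, vocab, n_windows, window_tokens, rate,
                              seed = 1L,
                              action_probs = c(mask = 1, random = 0, keep = 0)) {
  k <- vocab$k
  wlen <- window_tokens + k - 1L
  lens <- nchar(corpus)
  eligible <- which(lens >= wlen)
  if (length(eligible) == 0L) stop_param("no sequence long enough")
  lapply(seq_len(n_windows), function(i) {
    sb <- mix_seed(seed, i)
    pick <- local_seed(sb, {
      j <- eligible[sample.int(length(eligible), 1L)]
      s <- sample.int(lens[j] - wlen + 1L, 1L)
      c(j, s)
    })
    win <- substr(corpus[pick[1]], pick[2], pick[2] + wlen - 1L)
    ts <- tokenize(win, vocab, add_specials = TRUE)
    plan <- mask_contiguous(ts, rate, rng_seed = mix_seed(sb, 7L),
                            action_probs = action_probs)
    list(ts = ts, plan = plan)
  })
}

eval_set_batches <- function(state, eval_set, seed = 1L) {
  vocab <- state$vocab
  lapply(seq_along(eval_set), function(i) {
    e <- eval_set[[i]]
    ap <- local_seed(mix_seed(seed, i), apply_plan(e$ts, e$plan))
    list(ts = e$ts, plan = e$plan, ap = ap)
  })
}

#' Masked-token prediction accuracy over an evaluation set
#'
#' Fraction of masked positions where the argmax prediction equals the true
#' token.
#' @param state A `model_state`.
#' @param eval_set A [make_mlm_eval_set()] result.
#' @param seed Seed for any random-replacement corruption.
#' @return Fraction in [0, 1].
#' @export
masked_token_accuracy <- function(state, eval_set, seed = 1L) {
  prep <- eval_set_batches(state, eval_set, seed)
  correct <- 0L; total <- 0L
  for (e in prep) {
    ids <- matrix(e$ap$input_ids, nrow = 1)
    fw <- forward_transformer(state, ids, train = FALSE)
    hb <- mlm_head_fwd_bwd(state, fw$X, e$ap$predict_pos, e$ap$target_ids,
                           want_grad = FALSE)
    correct <- correct + sum(hb$preds == e$ap$target_ids)
    total <- total + length(e$ap$target_ids)
  }
  if (total == 0L) stop_param("evaluation set has no masked positions")
  correct / total
}

#' Overlap consistency of masked-token predictions
#'
#' For every masked token with at least one nucleotide forced by flanking
#' unmasked tokens (per [analyze_inferability()]), checks whether the
#' predicted k-mer agrees with all forced nucleotides. An untrained model
#' predicts an essentially random token, giving a combinatorial baseline of
#' about `4 / 4^k` for fully-constrained run tokens.
#'
#' @inheritParams masked_token_accuracy
#' @return Fraction of constrained masked predictions that are
#'   overlap-consistent.
#' @export
prediction_overlap_consistency <- function(state, eval_set, seed = 1L) {
  vocab <- state$vocab
  k <- vocab$k
  prep <- eval_set_batches(state, eval_set, seed)
  consistent <- 0L; total <- 0L
  for (e in prep) {
    rep_inf <- analyze_inferability(e$ts, e$plan)
    known <- rep_inf$status != "free"
    src_chars <- strsplit(e$ts$source, "", fixed = TRUE)[[1]]
    ids <- matrix(e$ap$input_ids, nrow = 1)
    fw <- forward_transformer(state, ids, train = FALSE)
    hb <- mlm_head_fwd_bwd(state, fw$X, e$ap$predict_pos, e$ap$target_ids,
                           want_grad = FALSE)
    pred_tokens <- vocab$tokens[hb$preds + 1L]
    for (j in seq_along(e$plan$masked_pos)) {
      i <- e$plan$masked_pos[j]          # interior token index
      span <- i:(i + k - 1L)             # source positions of token i
      forced <- span[known[span]]
      if (length(forced) == 0L) next
      total <- total + 1L
      tok <- pred_tokens[j]
      if (tok %in% vocab$special_tokens) next
      tok_chars <- strsplit(tok, "", fixed = TRUE)[[1]]
      if (all(tok_chars[forced - i + 1L] == src_chars[forced])) {
        consistent <- consistent + 1L
      }
    }
  }
  if (total == 0L) stop_param("no constrained masked positions in eval set")
  consistent / total
}

#' Combinatorial overlap-consistency baseline for a random predictor
#'
#' A token with `m` forced nucleotides is matched by `4^(k-m)` of the `4^k`
#' k-mers; for fully-constrained run tokens (`m = k - 1`) this is `4 / 4^k`.
#' @param k k-mer length.
#' @param include_specials Divide by the full label space `4^k + 5` instead
#'   of `4^k`.
#' @return Baseline fraction.
#' @export
overlap_consistency_baseline <- function(k, include_specials = FALSE) {
  denom <- if (include_specials) 4^k + 5 else 4^k
  4 / denom
}

#' Write a pre-training log as TSV (+ JSON metadata sidecar)
#' @param log A `pretrain_log`.
#' @param path TSV path; metadata goes to `paste0(path, ".json")`.
#' @export
write_pretrain_log <- function(log, path) {
  stopifnot(inherits(log, "pretrain_log"))
  data.table::fwrite(log$evals, path, sep = "\t")
  meta <- list(alpha = log$alpha, seed = log$seed, mask_cfg = log$mask_cfg,
               opt_cfg = log$opt_cfg)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
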