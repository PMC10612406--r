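#' Fine-tune a pre-trained masked language model for classification
#'
#' Standard BERT-style fine-tuning: sequences are tokenized with `[CLS]` /
#' `[SEP]`, the final hidden state at the `[CLS]` position feeds a sigmoid
#' classification head, and all parameters (embedding module, encoding
#' module and head) are updated with Adam on binary cross-entropy. The model
#' with the highest development-set MCC across epochs is retained.
#'
#' @param state A `model_state` (pre-trained, knocked out, or fresh).
#' @param ds A `labeled_seqset`; sequence length `L` must satisfy
#'   `L - k + 3 <= max_positions`.
#' @param lr,epochs,batch Optimization settings.
#' @param seed Integer seed (shuffling, head init).
#' @return list(state, head, best_epoch, dev_mcc, history); pass to
#'   [evaluate_finetuned()].
#' @export
finetune_classifier <- function(state, ds, lr = 3e-4, epochs = 3L,
                                batch = 8L, seed = 1L) {
  stopifnot(inherits(state, "model_state"), inherits(ds, "labeled_seqset"))
  cfg <- state$config
  k <- cfg$k
  Tt <- ds$length - k + 3L
  if (Tt > cfg$max_positions) {
    stop_param("need max_positions >= %d for L = %d", Tt, ds$length)
  }
  ids_for <- function(split) {
    rec <- ds$records[ds$records$split == split, ]
    if (nrow(rec) == 0L) return(NULL)
    ids <- matrix(0L, nrow(rec), Tt)
    for (i in seq_len(nrow(rec))) {
      ids[i, ] <- tokenize(rec$sequence[i], state$vocab)$ids
    }
    list(ids = ids, labels = rec$label)
  }
  tr <- ids_for("train"); dv <- ids_for("dev")
  if (is.null(tr) || is.null(dv)) stop_param("train and dev splits required")
  if (length(unique(tr$labels)) < 2) stop_param("single-class training split")
  H <- cfg$hidden
  head <- local_seed(mix_seed(seed, 17L),
                     list(W = matrix(stats::rnorm(H, 0, 0.02), H, 1), b = 0))
  opt <- adam_init(state$params)
  opt_head <- adam_init(head)
  score_split <- function(part) {
    probs <- numeric(nrow(part$ids))
    for (s in seq(1L, nrow(part$ids), by = batch)) {
      sel <- s:min(s + batch - 1L, nrow(part$ids))
      fw <- forward_transformer(state, part$ids[sel, , drop = FALSE])
      cls_rows <- (seq_along(sel) - 1L) * Tt + 1L
      logit <- drop(fw$X[cls_rows, , drop = FALSE] %*% head$W) + head$b
      probs[sel] <- 1 / (1 + exp(-logit))
    }
    probs
  }
  n <- nrow(tr$ids)
  best <- list(mcc = -Inf, params = state$params, head = head, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        dev_mcc = numeric(0))
  for (ep in seq_len(epochs)) {
    perm <- local_seed(mix_seed(seed, ep), sample.int(n))
    losses <- numeric(0)
    for (s in seq(1L, n, by = batch)) {
      sel <- perm[s:min(s + batch - 1L, n)]
      y <- tr$labels[sel]
      fw <- forward_transformer(state, tr$ids[sel, , drop = FALSE],
                                train = TRUE,
                                drop_seed = mix_seed(seed, ep * 1e5 + s))
      cls_rows <- (seq_along(sel) - 1L) * Tt + 1L
      Xcls <- fw$X[cls_rows, , drop = FALSE]
      logit <- drop(Xcls %*% head$W) + head$b
      prob <- 1 / (1 + exp(-logit))
      pr <- pmin(pmax(prob, 1e-9), 1 - 1e-9)
      losses <- c(losses, -mean(y * log(pr) + (1 - y) * log(1 - pr)))
      dlogit <- (prob - y) / length(y)
      dX <- matrix(0, nrow(fw$X), H)
      dX[cls_rows, ] <- outer(dlogit, drop(head$W))
      grads <- backward_transformer(state, fw$cache, dX)
      gh <- list(W = crossprod(Xcls, matrix(dlogit, ncol = 1)),
                 b = sum(dlogit))
      upd <- adam_update(state$params, grads, opt, lr)
      state$params <- upd$params; opt <- upd$opt
      updh <- adam_update(head, gh, opt_head, lr)
      head <- updh$params; opt_head <- updh$opt
    }
    dev_mcc <- metrics_report(score_split(dv), dv$labels)$MCC
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = mean(losses),
                                         dev_mcc = dev_mcc))
    if (dev_mcc > best$mcc) {
      best <- list(mcc = dev_mcc, params = state$params, head = head,
                   epoch = ep)
    }
  }
  state$params <- best$params
  list(state = state, head = best$head, best_epoch = best$epoch,
       dev_mcc = best$mcc, history = history, Tt = Tt, batch = batch)
}

#' Evaluate a fine-tuned model on the test split
#' @param ft A [finetune_classifier()] result.
#' @param ds The `labeled_seqset` it was trained on.
#' @param threshold Score threshold (default 0.5).
#' @return A [metrics_report()].
#' @export
evaluate_finetuned <- function(ft, ds, threshold = 0.5) {
  state <- ft$state
  rec <- ds$records[ds$records$split == "test", ]
  if (nrow(rec) == 0L) stop_param("empty test split")
  Tt <- ft$Tt
  probs <- numeric(nrow(rec))
  for (s in seq(1L, nrow(rec), by = ft$batch)) {
    sel <- s:min(s + ft$batch - 1L, nrow(rec))
    ids <- matrix(0L, length(sel), Tt)
    for (i in seq_along(sel)) {
      ids[i, ] <- tokenize(rec$sequence[sel[i]], state$vocab)$ids
    }
    fw <- forward_transformer(state, ids)
    cls_rows <- (seq_along(sel) - 1L) * Tt + 1L
    logit <- drop(fw$X[cls_rows, , drop = FALSE] %*% ft$head$W) + ft$head$b
    probs[sel] <- 1 / (1 + exp(-logit))
  }
  metrics_report(probs, rec$label, threshold)
}
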