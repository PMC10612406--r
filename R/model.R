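#' BERT-style masked language model over k-mer tokens
#'
#' A post-norm transformer encoder implemented in base R with hand-derived
#' backpropagation. Parameters live in a flat named list partitioned into
#' three disjoint groups by name prefix: `emb.*` (token/position/type
#' embeddings plus their layer-norm), `enc.L<j>.*` (per-layer attention and
#' feed-forward weights with their layer-norms), and `head.*` (the MLM output
#' projection). The partition is the unit of module-level "knockout"
#' re-initialization.
#'
#' @name model_core
NULL

#' Truncated-normal initializer (BERT scheme: sd 0.02, clipped at 2 sd)
#' @noRd
trunc_normal <- function(n, sd = 0.02) {
  lo <- stats::pnorm(-2); hi <- stats::pnorm(2)
  stats::qnorm(stats::runif(n, lo, hi)) * sd
}

init_params <- function(cfg, seed) {
  H <- cfg$hidden; V <- cfg$vocab_size; P <- cfg$max_positions
  Tt <- cfg$type_vocab; Fw <- cfg$ffn
  local_seed(seed, {
    p <- list(
      emb.tok = matrix(trunc_normal(V * H), V, H),
      emb.pos = matrix(trunc_normal(P * H), P, H),
      emb.typ = matrix(trunc_normal(Tt * H), Tt, H),
      emb.ln.g = rep(1, H), emb.ln.b = rep(0, H)
    )
    for (l in seq_len(cfg$layers)) {
      pre <- sprintf("enc.L%d.", l)
      lay <- list(
        matrix(trunc_normal(H * H), H, H), rep(0, H),   # Wq bq
        matrix(trunc_normal(H * H), H, H), rep(0, H),   # Wk bk
        matrix(trunc_normal(H * H), H, H), rep(0, H),   # Wv bv
        matrix(trunc_normal(H * H), H, H), rep(0, H),   # Wo bo
        rep(1, H), rep(0, H),                           # ln1
        matrix(trunc_normal(H * Fw), H, Fw), rep(0, Fw),  # W1 b1
        matrix(trunc_normal(Fw * H), Fw, H), rep(0, H),   # W2 b2
        rep(1, H), rep(0, H)                            # ln2
      )
      names(lay) <- paste0(pre, c("Wq", "bq", "Wk", "bk", "Wv", "bv",
                                  "Wo", "bo", "ln1.g", "ln1.b",
                                  "W1", "b1", "W2", "b2", "ln2.g", "ln2.b"))
      p <- c(p, lay)
    }
    p$head.W <- matrix(trunc_normal(H * V), H, V)
    p$head.b <- rep(0, V)
    p
  })
}

#' Build a masked-language-model state
#'
#' Weights are initialized from a truncated normal (sd 0.02, clipped at two
#' standard deviations); layer-norm scales start at 1 and all biases at 0.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [model_config()].
#' @return An object of class `model_state` with fields `config`, `params`
#'   (flat named list), `vocab`, and `provenance`.
#' @export
build_model <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  structure(
    list(config = cfg, params = init_params(cfg, cfg$seed),
         vocab = build_vocabulary(cfg$k),
         provenance = list(built = "fresh", seed = cfg$seed)),
    class = "model_state"
  )
}

#' @export
print.model_state <- function(x, ...) {
  pc <- count_parameters_walk(x)
  cat(sprintf("<model_state> k=%d H=%d layers=%d; %s params (%.1f%% encoding)\n",
              x$config$k, x$config$hidden, x$config$layers,
              format(pc$embedding_params + pc$encoding_params + pc$head_params,
                     big.mark = ","),
              100 * pc$fraction_encoding))
  invisible(x)
}

#' Re-initialize a parameter module ("knockout")
#'
#' Freshly initializes the parameters of the chosen module while leaving all
#' other parameters bit-identical; `scope = "all"` reproduces
#' [build_model()] with the given seed.
#'
#' @param state A `model_state`.
#' @param scope One of `"encoding"`, `"embedding"`, `"all"`.
#' @param seed Integer seed for the fresh initialization.
#' @return A `model_state`.
#' @export
reinitialize_module <- function(state, scope = c("encoding", "embedding", "all"),
                                seed = 1L) {
  stopifnot(inherits(state, "model_state"))
  scope <- match.arg(scope)
  cfg <- state$config
  cfg$seed <- as.integer(seed)
  fresh <- init_params(cfg, seed)
  if (scope == "all") {
    state$params <- fresh
  } else {
    groups <- param_group(names(state$params))
    take <- groups == scope
    state$params[take] <- fresh[take]
  }
  state$provenance <- c(state$provenance,
                        list(reinit = list(scope = scope, seed = seed)))
  state
}

#' Extract the k-mer token embedding table
#'
#' Returns only the token embedding rows (position and type embeddings are
#' part of the embedding module but are not token representations).
#'
#' @param state A `model_state`.
#' @param include_specials Keep the five special-token rows (default FALSE).
#' @return An [embedding_table()] with source `"model"`.
#' @export
extract_token_embeddings <- function(state, include_specials = FALSE) {
  stopifnot(inherits(state, "model_state"))
  labels <- state$vocab$tokens
  mat <- state$params$emb.tok
  if (!include_specials) {
    keep <- !(labels %in% state$vocab$special_tokens)
    labels <- labels[keep]
    mat <- mat[keep, , drop = FALSE]
  }
  embedding_table(labels, mat, source = "model",
                  includes_specials = include_specials)
}

# ---------------------------------------------------------------------------
# forward / backward
# ---------------------------------------------------------------------------

layer_norm_fwd <- function(X, g, b, eps = 1e-6) {
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc * Xc)
  sd <- sqrt(v + eps)
  xhat <- Xc / sd
  Y <- sweep(xhat, 2, g, "*")
  Y <- sweep(Y, 2, b, "+")
  list(Y = Y, xhat = xhat, sd = sd)
}

layer_norm_bwd <- function(dY, cache, g) {
  dxhat <- sweep(dY, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- (dxhat - m1 - cache$xhat * m2) / cache$sd
  list(dX = dX,
       dg = colSums(dY * cache$xhat),
       db = colSums(dY))
}

GELU_C <- sqrt(2 / pi)
gelu_fwd <- function(x) {
  x2 <- x * x
  th <- tanh(GELU_C * (x + 0.044715 * x * x2))
  list(y = 0.5 * x * (1 + th), th = th)
}
gelu_bwd <- function(x, th) {
  0.5 * (1 + th) + 0.5 * x * (1 - th * th) * GELU_C *
    (1 + 0.134145 * x * x)
}

#' Transformer forward pass
#'
#' @param state Model state.
#' @param ids B x T integer matrix of 0-based token ids.
#' @param train Keep caches for backprop and apply dropout.
#' @param drop_seed Seed for dropout masks when training.
#' @return list(X = final hidden (B*T x H, sequence-major rows), cache).
#' @noRd
forward_transformer <- function(state, ids, train = FALSE, drop_seed = NULL) {
  cfg <- state$config
  p <- state$params
  B <- nrow(ids); Tt <- ncol(ids); H <- cfg$hidden
  A <- cfg$heads; dh <- H / A
  if (Tt > cfg$max_positions) {
    stop_param("sequence length %d exceeds max_positions %d", Tt,
               cfg$max_positions)
  }
  rows_t <- rep(seq_len(Tt), times = B)  # position index per row
  flat_ids <- as.integer(t(ids))         # sequence-major
  X <- p$emb.tok[flat_ids + 1L, , drop = FALSE] +
    p$emb.pos[rows_t, , drop = FALSE]
  X <- sweep(X, 2, p$emb.typ[1L, ], "+")
  ln0 <- layer_norm_fwd(X, p$emb.ln.g, p$emb.ln.b)
  X <- ln0$Y

  use_drop <- train && cfg$dropout > 0
  if (use_drop && !is.null(drop_seed)) set.seed(drop_seed)
  drop_mask <- function(n, m) {
    matrix(stats::rbinom(n * m, 1, 1 - cfg$dropout), n, m) / (1 - cfg$dropout)
  }
  d0 <- NULL
  if (use_drop) { d0 <- drop_mask(nrow(X), H); X <- X * d0 }

  seq_rows <- lapply(seq_len(B), function(b) ((b - 1L) * Tt + 1L):(b * Tt))
  hcols <- lapply(seq_len(A), function(h) ((h - 1L) * dh + 1L):(h * dh))

  caches <- vector("list", cfg$layers)
  for (l in seq_len(cfg$layers)) {
    pre <- sprintf("enc.L%d.", l)
    Xin <- X
    QKV <- X %*% cbind(p[[paste0(pre, "Wq")]], p[[paste0(pre, "Wk")]],
                       p[[paste0(pre, "Wv")]])
    QKV <- QKV + rep(c(p[[paste0(pre, "bq")]], p[[paste0(pre, "bk")]],
                       p[[paste0(pre, "bv")]]), each = nrow(QKV))
    Q <- QKV[, 1:H, drop = FALSE]
    K <- QKV[, (H + 1):(2 * H), drop = FALSE]
    V <- QKV[, (2 * H + 1):(3 * H), drop = FALSE]
    Ctx <- matrix(0, nrow(X), H)
    Ps <- vector("list", B * A)
    inv_sq <- 1 / sqrt(dh)
    for (b in seq_len(B)) {
      rr <- seq_rows[[b]]
      for (h in seq_len(A)) {
        cc <- hcols[[h]]
        S <- tcrossprod(Q[rr, cc, drop = FALSE], K[rr, cc, drop = FALSE]) *
          inv_sq
        E <- exp(S - matrixStats::rowMaxs(S))
        P <- E / rowSums(E)
        Ps[[(b - 1L) * A + h]] <- P
        Ctx[rr, cc] <- P %*% V[rr, cc, drop = FALSE]
      }
    }
    AO <- Ctx %*% p[[paste0(pre, "Wo")]]
    AO <- AO + rep(p[[paste0(pre, "bo")]], each = nrow(AO))
    d1 <- NULL
    if (use_drop) { d1 <- drop_mask(nrow(AO), H); AO <- AO * d1 }
    R1 <- Xin + AO
    ln1 <- layer_norm_fwd(R1, p[[paste0(pre, "ln1.g")]],
                          p[[paste0(pre, "ln1.b")]])
    X1 <- ln1$Y
    F1 <- X1 %*% p[[paste0(pre, "W1")]]
    F1 <- F1 + rep(p[[paste0(pre, "b1")]], each = nrow(F1))
    ge <- gelu_fwd(F1)
    FO <- ge$y %*% p[[paste0(pre, "W2")]]
    FO <- FO + rep(p[[paste0(pre, "b2")]], each = nrow(FO))
    d2 <- NULL
    if (use_drop) { d2 <- drop_mask(nrow(FO), H); FO <- FO * d2 }
    R2 <- X1 + FO
    ln2 <- layer_norm_fwd(R2, p[[paste0(pre, "ln2.g")]],
                          p[[paste0(pre, "ln2.b")]])
    X <- ln2$Y
    if (train) {
      caches[[l]] <- list(Xin = Xin, Q = Q, K = K, V = V, Ps = Ps, Ctx = Ctx,
                          ln1 = ln1, X1 = X1, F1 = F1, G = ge$y, th = ge$th,
                          ln2 = ln2, d1 = d1, d2 = d2)
    }
  }
  cache <- if (train) {
    list(caches = caches, ln0 = ln0, flat_ids = flat_ids, rows_t = rows_t,
         B = B, Tt = Tt, seq_rows = seq_rows, hcols = hcols, dh = dh, d0 = d0)
  } else NULL
  list(X = X, cache = cache)
}

#' Transformer backward pass
#'
#' @param state Model state.
#' @param cache Forward cache (train = TRUE).
#' @param dX Gradient w.r.t. final hidden states (B*T x H).
#' @return Named list of gradients over `state$params` (head excluded).
#' @noRd
backward_transformer <- function(state, cache, dX) {
  cfg <- state$config
  p <- state$params
  H <- cfg$hidden; A <- cfg$heads; dh <- cache$dh
  B <- cache$B; Tt <- cache$Tt
  seq_rows <- cache$seq_rows; hcols <- cache$hcols
  grads <- list()
  for (l in rev(seq_len(cfg$layers))) {
    pre <- sprintf("enc.L%d.", l)
    cc_l <- cache$caches[[l]]
    lb2 <- layer_norm_bwd(dX, cc_l$ln2, p[[paste0(pre, "ln2.g")]])
    grads[[paste0(pre, "ln2.g")]] <- lb2$dg
    grads[[paste0(pre, "ln2.b")]] <- lb2$db
    dR2 <- lb2$dX
    dFO <- dR2
    if (!is.null(cc_l$d2)) dFO <- dFO * cc_l$d2
    dG <- dFO %*% t(p[[paste0(pre, "W2")]])
    grads[[paste0(pre, "W2")]] <- crossprod(cc_l$G, dFO)
    grads[[paste0(pre, "b2")]] <- colSums(dFO)
    dF1 <- dG * gelu_bwd(cc_l$F1, cc_l$th)
    grads[[paste0(pre, "W1")]] <- crossprod(cc_l$X1, dF1)
    grads[[paste0(pre, "b1")]] <- colSums(dF1)
    dX1 <- dR2 + dF1 %*% t(p[[paste0(pre, "W1")]])
    lb1 <- layer_norm_bwd(dX1, cc_l$ln1, p[[paste0(pre, "ln1.g")]])
    grads[[paste0(pre, "ln1.g")]] <- lb1$dg
    grads[[paste0(pre, "ln1.b")]] <- lb1$db
    dR1 <- lb1$dX
    dAO <- dR1
    if (!is.null(cc_l$d1)) dAO <- dAO * cc_l$d1
    dCtx <- dAO %*% t(p[[paste0(pre, "Wo")]])
    grads[[paste0(pre, "Wo")]] <- crossprod(cc_l$Ctx, dAO)
    grads[[paste0(pre, "bo")]] <- colSums(dAO)
    dQ <- matrix(0, nrow(dX), H)
    dK <- matrix(0, nrow(dX), H)
    dV <- matrix(0, nrow(dX), H)
    for (b in seq_len(B)) {
      rr <- seq_rows[[b]]
      for (h in seq_len(A)) {
        ch <- hcols[[h]]
        P <- cc_l$Ps[[(b - 1L) * A + h]]
        dCh <- dCtx[rr, ch, drop = FALSE]
        Vh <- cc_l$V[rr, ch, drop = FALSE]
        dP <- tcrossprod(dCh, Vh)
        dV[rr, ch] <- crossprod(P, dCh)
        dS <- (dP - rowSums(dP * P)) * P / sqrt(dh)
        dQ[rr, ch] <- dS %*% cc_l$K[rr, ch, drop = FALSE]
        dK[rr, ch] <- crossprod(dS, cc_l$Q[rr, ch, drop = FALSE])
      }
    }
    Xin <- cc_l$Xin
    grads[[paste0(pre, "Wq")]] <- crossprod(Xin, dQ)
    grads[[paste0(pre, "bq")]] <- colSums(dQ)
    grads[[paste0(pre, "Wk")]] <- crossprod(Xin, dK)
    grads[[paste0(pre, "bk")]] <- colSums(dK)
    grads[[paste0(pre, "Wv")]] <- crossprod(Xin, dV)
    grads[[paste0(pre, "bv")]] <- colSums(dV)
    dX <- dR1 +
      dQ %*% t(p[[paste0(pre, "Wq")]]) +
      dK %*% t(p[[paste0(pre, "Wk")]]) +
      dV %*% t(p[[paste0(pre, "Wv")]])
  }
  if (!is.null(cache$d0)) dX <- dX * cache$d0
  lb0 <- layer_norm_bwd(dX, cache$ln0, p$emb.ln.g)
  grads$emb.ln.g <- lb0$dg
  grads$emb.ln.b <- lb0$db
  dE <- lb0$dX
  dtok_part <- rowsum(dE, cache$flat_ids)
  dtok <- matrix(0, cfg$vocab_size, H)
  dtok[as.integer(rownames(dtok_part)) + 1L, ] <- dtok_part
  grads$emb.tok <- dtok
  dpos_part <- rowsum(dE, cache$rows_t)
  dpos <- matrix(0, cfg$max_positions, H)
  dpos[as.integer(rownames(dpos_part)), ] <- dpos_part
  grads$emb.pos <- dpos
  dtyp <- matrix(0, cfg$type_vocab, H)
  dtyp[1L, ] <- colSums(dE)
  grads$emb.typ <- dtyp
  grads
}

#' MLM head + cross-entropy at selected rows
#'
#' @return list(loss, probs, preds (0-based), dX rows for the masked rows,
#'   head gradients).
#' @noRd
mlm_head_fwd_bwd <- function(state, X, rows, targets, want_grad = TRUE) {
  p <- state$params
  tied <- isTRUE(state$config$tie_embeddings)
  W <- if (tied) t(p$emb.tok) else p$head.W
  Xm <- X[rows, , drop = FALSE]
  logits <- Xm %*% W
  logits <- sweep(logits, 2, p$head.b, "+")
  logits <- logits - apply(logits, 1, max)
  E <- exp(logits)
  probs <- E / rowSums(E)
  M <- length(rows)
  idx <- cbind(seq_len(M), targets + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  preds <- max.col(probs, ties.method = "first") - 1L
  out <- list(loss = loss, preds = preds)
  if (want_grad) {
    dlogits <- probs
    dlogits[idx] <- dlogits[idx] - 1
    dlogits <- dlogits / M
    out$dXm <- dlogits %*% if (tied) p$emb.tok else t(p$head.W)
    if (tied) {
      out$g_emb_tok <- crossprod(dlogits, Xm)  # V x H contribution
      out$g_headW <- p$head.W * 0              # unused when tied
    } else {
      out$g_headW <- crossprod(Xm, dlogits)
    }
    out$g_headb <- colSums(dlogits)
  }
  out
}

#' Masked-language-model loss for one sequence
#'
#' Mean cross-entropy (nats) over the masked positions only, together with
#' the argmax predictions at those positions. Unmasked positions contribute
#' nothing to the loss.
#'
#' @param state A `model_state`.
#' @param ts A [tokenize()] result.
#' @param plan A [mask_contiguous()] plan for `ts`.
#' @param apply_seed Seed controlling the random-replacement tokens when the
#'   plan contains `random` actions.
#' @return list(loss, predictions) with `predictions` the 0-based predicted
#'   token ids at the masked positions (in plan order).
#' @export
mlm_loss <- function(state, ts, plan, apply_seed = 1L) {
  stopifnot(inherits(state, "model_state"), inherits(ts, "token_seq"),
            inherits(plan, "masking_plan"))
  if (length(plan$masked_pos) == 0L) stop_param("plan masks no positions")
  ap <- local_seed(apply_seed, apply_plan(ts, plan))
  ids <- matrix(ap$input_ids, nrow = 1)
  fw <- forward_transformer(state, ids, train = FALSE)
  hb <- mlm_head_fwd_bwd(state, fw$X, ap$predict_pos, ap$target_ids,
                         want_grad = FALSE)
  list(loss = hb$loss, predictions = hb$preds)
}

# ---------------------------------------------------------------------------
# checkpoint IO
# ---------------------------------------------------------------------------

#' Save / load model checkpoints
#'
#' Single-file container (RDS) embedding a format version, the full
#' configuration echo and all parameter groups; `load_model(save_model(m))`
#' is bit-identical. Loading validates every parameter shape against the
#' embedded configuration.
#'
#' @param state A `model_state`.
#' @param path Checkpoint path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `model_state`.
#' @export
save_model <- function(state, path) {
  stopifnot(inherits(state, "model_state"))
  obj <- list(format = "kmerlm-checkpoint-1",
              config = unclass(state$config),
              params = state$params,
              provenance = state$provenance)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "kmerlm-checkpoint-1")) {
    stop_param("unrecognized checkpoint format")
  }
  cfg <- do.call(model_config, obj$config[c("k", "hidden", "layers", "heads",
                                            "ffn", "max_positions",
                                            "type_vocab", "dropout", "seed")])
  ref <- init_params(cfg, cfg$seed)
  if (!identical(names(ref), names(obj$params))) {
    stop_param("checkpoint parameter names do not match its configuration")
  }
  for (nm in names(ref)) {
    if (!identical(dim(ref[[nm]]), dim(obj$params[[nm]])) ||
        length(ref[[nm]]) != length(obj$params[[nm]])) {
      stop_param("shape mismatch for parameter '%s'", nm)
    }
  }
  structure(list(config = cfg, params = obj$params,
                 vocab = build_vocabulary(cfg$k),
                 provenance = obj$provenance),
            class = "model_state")
}
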