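#' Frozen-embedding CNN sequence classifier
#'
#' A multi-width 1-D convolutional network over k-mer token sequences with a
#' pluggable, optionally frozen embedding layer: embedding lookup ->
#' parallel valid convolutions (one set per kernel width) -> ReLU -> global
#' max pooling -> concatenation -> dense ReLU layer -> dropout -> sigmoid
#' output. Inputs are tokenized with the same k as the embedding table; no
#' CLS/SEP or position embeddings are used.
#'
#' @param embedding An [embedding_table()] covering all `4^k` k-mers.
#' @param kernel_widths Convolution widths in token units (default
#'   `c(7, 14, 27)`).
#' @param n_kernels Kernels per width (default 32).
#' @param dense_units Hidden dense units (default 32).
#' @param dropout Dropout probability on the dense layer (default 0).
#' @param freeze_embeddings Keep the embedding rows fixed (default `TRUE`).
#' @param lr,epochs,batch Adam learning rate, training epochs, batch size.
#' @param seed Integer seed for initialization and batch shuffling.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(embedding, kernel_widths = c(7L, 14L, 27L),
                       n_kernels = 32L, dense_units = 32L, dropout = 0,
                       freeze_embeddings = TRUE, lr = 1e-3, epochs = 10L,
                       batch = 32L, seed = 1L) {
  stopifnot(inherits(embedding, "embedding_table"))
  emb <- drop_specials(embedding)
  k <- nchar(emb$labels[1])
  if (!setequal(emb$labels, all_kmers(k))) {
    stop_param("embedding table must cover all %d-mers", k)
  }
  structure(
    list(embedding = emb, k = k, kernel_widths = as.integer(kernel_widths),
         n_kernels = as.integer(n_kernels),
         dense_units = as.integer(dense_units), dropout = dropout,
         freeze_embeddings = freeze_embeddings, lr = lr,
         epochs = as.integer(epochs), batch = as.integer(batch),
         seed = as.integer(seed)),
    class = "cnn_config"
  )
}

#' Build a CNN classifier
#'
#' @param cfg A [cnn_config()].
#' @param input_length_tokens Tokenized input length `L - k + 1`.
#' @return An object of class `cnn_classifier` (config, parameter list,
#'   embedding matrix in lexicographic k-mer order).
#' @export
build_classifier <- function(cfg, input_length_tokens) {
  stopifnot(inherits(cfg, "cnn_config"))
  Tt <- as.integer(input_length_tokens)
  if (any(cfg$kernel_widths >= Tt)) {
    stop_param("kernel width %d must be smaller than the %d-token input",
               max(cfg$kernel_widths), Tt)
  }
  d <- ncol(cfg$embedding$matrix)
  E <- cfg$embedding$matrix[match(all_kmers(cfg$k), cfg$embedding$labels), ,
                            drop = FALSE]
  nw <- length(cfg$kernel_widths)
  nk <- cfg$n_kernels
  params <- local_seed(cfg$seed, {
    p <- list()
    for (i in seq_len(nw)) {
      w <- cfg$kernel_widths[i]
      sdw <- sqrt(2 / (w * d))
      p[[sprintf("conv%d.W", i)]] <- matrix(stats::rnorm(w * d * nk, 0, sdw),
                                            w * d, nk)
      p[[sprintf("conv%d.b", i)]] <- rep(0, nk)
    }
    p$dense.W <- matrix(stats::rnorm(nw * nk * cfg$dense_units, 0,
                                     sqrt(2 / (nw * nk))),
                        nw * nk, cfg$dense_units)
    p$dense.b <- rep(0, cfg$dense_units)
    p$out.W <- matrix(stats::rnorm(cfg$dense_units, 0,
                                   sqrt(1 / cfg$dense_units)),
                      cfg$dense_units, 1)
    p$out.b <- 0
    p
  })
  structure(
    list(config = cfg, params = params, E = E, input_tokens = Tt),
    class = "cnn_classifier"
  )
}

#' Number of trainable parameters (frozen embedding excluded)
#' @param clf A `cnn_classifier`.
#' @return Integer count.
#' @export
n_trainable <- function(clf) {
  stopifnot(inherits(clf, "cnn_classifier"))
  n <- sum(vapply(clf$params, length, numeric(1)))
  if (!clf$config$freeze_embeddings) n <- n + length(clf$E)
  as.integer(n)
}

#' Tokenize a dataset split into a 1-based k-mer id matrix
#' @noRd
tokenize_split <- function(ds, split, k) {
  rec <- ds$records[ds$records$split == split, ]
  if (nrow(rec) == 0L) return(NULL)
  Tt <- ds$length - k + 1L
  ids <- matrix(0L, nrow(rec), Tt)
  kmer_index <- stats::setNames(seq_len(4^k), all_kmers(k))
  for (i in seq_len(nrow(rec))) {
    s <- rec$sequence[i]
    ids[i, ] <- kmer_index[substring(s, seq_len(Tt), seq_len(Tt) + k - 1L)]
  }
  list(ids = ids, labels = rec$label, id = rec$id)
}

cnn_forward <- function(clf, ids, train = FALSE, drop_seed = NULL) {
  cfg <- clf$config
  p <- clf$params
  B <- nrow(ids); Tt <- ncol(ids)
  d <- ncol(clf$E)
  X <- clf$E[as.integer(t(ids)), , drop = FALSE]  # (B*T) x d, seq-major
  nw <- length(cfg$kernel_widths); nk <- cfg$n_kernels
  pooled <- matrix(0, B, nw * nk)
  caches <- vector("list", nw)
  for (i in seq_len(nw)) {
    w <- cfg$kernel_widths[i]
    Tc <- Tt - w + 1L
    base_rows <- as.vector(vapply(seq_len(B), function(b) {
      (b - 1L) * Tt + seq_len(Tc)
    }, integer(Tc)))
    Z <- matrix(0, B * Tc, nk)
    W <- p[[sprintf("conv%d.W", i)]]
    for (j in seq_len(w)) {
      Wj <- W[((j - 1L) * d + 1L):(j * d), , drop = FALSE]
      Z <- Z + X[base_rows + (j - 1L), , drop = FALSE] %*% Wj
    }
    Z <- Z + rep(p[[sprintf("conv%d.b", i)]], each = nrow(Z))
    A <- pmax(Z, 0)
    # rows are b-major blocks of Tc: reshape to Tc x (B*nk) and pool over Tc
    Am <- matrix(A, nrow = Tc)
    j_star <- max.col(t(Am), ties.method = "first")   # length B*nk
    pool <- matrix(Am[cbind(j_star, seq_along(j_star))], B, nk)
    am <- matrix(j_star, B, nk)
    pooled[, ((i - 1L) * nk + 1L):(i * nk)] <- pool
    caches[[i]] <- list(Z = Z, am = am, base_rows = base_rows, Tc = Tc)
  }
  H1 <- pooled %*% p$dense.W
  H1 <- sweep(H1, 2, p$dense.b, "+")
  A1 <- pmax(H1, 0)
  dmask <- NULL
  if (train && cfg$dropout > 0) {
    if (!is.null(drop_seed)) set.seed(drop_seed)
    dmask <- matrix(stats::rbinom(length(A1), 1, 1 - cfg$dropout),
                    nrow(A1)) / (1 - cfg$dropout)
    A1 <- A1 * dmask
  }
  logit <- drop(A1 %*% p$out.W) + p$out.b
  prob <- 1 / (1 + exp(-logit))
  list(prob = prob, cache = if (train) {
    list(X = X, pooled = pooled, H1 = H1, A1 = A1, dmask = dmask,
         caches = caches, ids = ids)
  } else NULL)
}

cnn_backward <- function(clf, cache, dlogit) {
  cfg <- clf$config
  p <- clf$params
  B <- nrow(cache$ids); Tt <- ncol(cache$ids)
  d <- ncol(clf$E)
  nw <- length(cfg$kernel_widths); nk <- cfg$n_kernels
  grads <- list()
  dA1 <- dlogit %*% t(p$out.W)
  grads$out.W <- crossprod(cache$A1, dlogit)
  grads$out.b <- sum(dlogit)
  if (!is.null(cache$dmask)) dA1 <- dA1 * cache$dmask
  dH1 <- dA1 * (cache$H1 > 0)
  grads$dense.W <- crossprod(cache$pooled, dH1)
  grads$dense.b <- colSums(dH1)
  dpooled <- dH1 %*% t(p$dense.W)
  dX <- matrix(0, B * Tt, d)
  for (i in seq_len(nw)) {
    cc <- cache$caches[[i]]
    w <- cfg$kernel_widths[i]
    Tc <- cc$Tc
    dpool <- dpooled[, ((i - 1L) * nk + 1L):(i * nk), drop = FALSE]
    dA <- matrix(0, B * Tc, nk)
    rows <- as.vector(cc$am) + rep((seq_len(B) - 1L) * Tc, times = nk) -
      0L  # am is B x nk of within-block argmax
    cols <- rep(seq_len(nk), each = B)
    dA[cbind(rows, cols)] <- as.vector(dpool)
    dZ <- dA * (cc$Z > 0)
    W <- p[[sprintf("conv%d.W", i)]]
    dW <- matrix(0, w * d, nk)
    for (j in seq_len(w)) {
      rows_j <- cc$base_rows + (j - 1L)
      Xj <- cache$X[rows_j, , drop = FALSE]
      dW[((j - 1L) * d + 1L):(j * d), ] <- crossprod(Xj, dZ)
      if (!cfg$freeze_embeddings) {
        Wj <- W[((j - 1L) * d + 1L):(j * d), , drop = FALSE]
        dX[rows_j, ] <- dX[rows_j, , drop = FALSE] + dZ %*% t(Wj)
      }
    }
    grads[[sprintf("conv%d.W", i)]] <- dW
    grads[[sprintf("conv%d.b", i)]] <- colSums(dZ)
  }
  dE <- NULL
  if (!cfg$freeze_embeddings) {
    part <- rowsum(dX, as.integer(t(cache$ids)))
    dE <- matrix(0, nrow(clf$E), d)
    dE[as.integer(rownames(part)), ] <- part
  }
  list(grads = grads, dE = dE)
}

#' Train a CNN classifier with dev-MCC model selection
#'
#' Trains with Adam on binary cross-entropy for `epochs` epochs; after each
#' epoch the development split is scored and the parameters with the highest
#' dev MCC are retained.
#'
#' @param clf A [build_classifier()] result.
#' @param ds A `labeled_seqset` with non-empty train and dev splits.
#' @return list(classifier, best_epoch, dev_mcc, history).
#' @export
train_classifier <- function(clf, ds) {
  stopifnot(inherits(clf, "cnn_classifier"), inherits(ds, "labeled_seqset"))
  cfg <- clf$config
  tr <- tokenize_split(ds, "train", cfg$k)
  dv <- tokenize_split(ds, "dev", cfg$k)
  if (is.null(tr) || is.null(dv)) stop_param("train and dev splits required")
  if (length(unique(tr$labels)) < 2) stop_param("single-class training split")
  if (ncol(tr$ids) != clf$input_tokens) {
    stop_param("dataset token length %d != classifier input length %d",
               ncol(tr$ids), clf$input_tokens)
  }
  n <- nrow(tr$ids)
  opt <- adam_init(clf$params)
  optE <- if (!cfg$freeze_embeddings) {
    list(m = clf$E * 0, v = clf$E * 0, t = 0L)
  } else NULL
  best <- list(mcc = -Inf, params = clf$params, E = clf$E, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        dev_mcc = numeric(0))
  for (ep in seq_len(cfg$epochs)) {
    perm <- local_seed(mix_seed(cfg$seed, ep), sample.int(n))
    losses <- numeric(0)
    for (start in seq(1L, n, by = cfg$batch)) {
      sel <- perm[start:min(start + cfg$batch - 1L, n)]
      ids <- tr$ids[sel, , drop = FALSE]
      y <- tr$labels[sel]
      fw <- cnn_forward(clf, ids, train = TRUE,
                        drop_seed = mix_seed(cfg$seed, ep * 100000L + start))
      pr <- pmin(pmax(fw$prob, 1e-9), 1 - 1e-9)
      losses <- c(losses, -mean(y * log(pr) + (1 - y) * log(1 - pr)))
      dlogit <- matrix((fw$prob - y) / length(y), ncol = 1)
      bk <- cnn_backward(clf, fw$cache, dlogit)
      upd <- adam_update(clf$params, bk$grads, opt, cfg$lr)
      clf$params <- upd$params
      opt <- upd$opt
      if (!cfg$freeze_embeddings && !is.null(bk$dE)) {
        optE$t <- optE$t + 1L
        optE$m <- 0.9 * optE$m + 0.1 * bk$dE
        optE$v <- 0.999 * optE$v + 0.001 * bk$dE^2
        clf$E <- clf$E - cfg$lr * (optE$m / (1 - 0.9^optE$t)) /
          (sqrt(optE$v / (1 - 0.999^optE$t)) + 1e-8)
      }
    }
    dev_prob <- cnn_forward(clf, dv$ids)$prob
    dev_mcc <- metrics_report(dev_prob, dv$labels)$MCC
    history <- rbind(history, data.frame(epoch = ep,
                                         train_loss = mean(losses),
                                         dev_mcc = dev_mcc))
    if (dev_mcc > best$mcc) {
      best <- list(mcc = dev_mcc, params = clf$params, E = clf$E, epoch = ep)
    }
  }
  clf$params <- best$params
  clf$E <- best$E
  list(classifier = clf, best_epoch = best$epoch, dev_mcc = best$mcc,
       history = history)
}

#' Score sequences with a trained classifier
#' @param clf A trained `cnn_classifier`.
#' @param ds A `labeled_seqset`.
#' @param split Which split to score (default `"test"`).
#' @return list(scores, labels, id).
#' @export
predict_classifier <- function(clf, ds, split = "test") {
  part <- tokenize_split(ds, split, clf$config$k)
  if (is.null(part)) stop_param("empty %s split", split)
  list(scores = cnn_forward(clf, part$ids)$prob, labels = part$labels,
       id = part$id)
}

#' Evaluate a trained classifier on the test split
#'
#' @param clf A trained `cnn_classifier`.
#' @param ds A `labeled_seqset` with a non-empty test split.
#' @param threshold Score threshold (default 0.5).
#' @return A [metrics_report()].
#' @export
evaluate <- function(clf, ds, threshold = 0.5) {
  pr <- predict_classifier(clf, ds, "test")
  metrics_report(pr$scores, pr$labels, threshold)
}
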