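#' Model configuration
#'
#' Configuration of the BERT-style masked language model. The default values
#' mirror the standard 5-mer architecture (12 layers, hidden 768, 12 heads,
#' feed-forward 3072, 512 positions, 2 token types); use
#' [mini_model_config()] for desk-scale work.
#'
#' @param k k-mer length.
#' @param hidden Hidden width H (must be divisible by `heads`).
#' @param layers Number of transformer layers.
#' @param heads Attention heads.
#' @param ffn Feed-forward inner width.
#' @param max_positions Maximum sequence length (tokens incl. specials).
#' @param type_vocab Number of token-type (segment) embeddings; all inputs
#'   use segment 0.
#' @param dropout Dropout probability (applied after the embedding layer-norm
#'   and after each sublayer output when training).
#' @param tie_embeddings Share the token embedding matrix with the MLM
#'   output projection (the standard BERT arrangement). Default
#'   `FALSE`, which keeps the embedding/encoding partition clean; when
#'   `TRUE` the `head.W` parameter is retained but unused.
#' @param seed Integer seed controlling weight initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(k = 5L, hidden = 768L, layers = 12L, heads = 12L,
                         ffn = 3072L, max_positions = 512L, type_vocab = 2L,
                         dropout = 0.1, tie_embeddings = FALSE, seed = 1L) {
  cfg <- list(k = as.integer(k), vocab_size = as.integer(4^k + 5),
              hidden = as.integer(hidden), layers = as.integer(layers),
              heads = as.integer(heads), ffn = as.integer(ffn),
              max_positions = as.integer(max_positions),
              type_vocab = as.integer(type_vocab),
              dropout = as.numeric(dropout),
              tie_embeddings = isTRUE(tie_embeddings),
              seed = as.integer(seed))
  problems <- character(0)
  if (cfg$k < 1 || cfg$k > 8) problems <- c(problems, "k must be in [1, 8]")
  if (cfg$hidden %% cfg$heads != 0) {
    problems <- c(problems,
                  sprintf("hidden (%d) must be divisible by heads (%d)",
                          cfg$hidden, cfg$heads))
  }
  if (cfg$layers < 1) problems <- c(problems, "layers must be >= 1")
  if (cfg$ffn < 1) problems <- c(problems, "ffn must be >= 1")
  if (cfg$max_positions < cfg$k + 2) {
    problems <- c(problems, "max_positions too small")
  }
  if (cfg$dropout < 0 || cfg$dropout >= 1) {
    problems <- c(problems, "dropout must be in [0, 1)")
  }
  if (length(problems) > 0) {
    stop_param("invalid model config: %s", paste(problems, collapse = "; "))
  }
  structure(cfg, class = "model_config")
}

#' Desk-scale mini configuration
#' @param k k-mer length (default 3).
#' @param ... Overrides passed to [model_config()].
#' @return A `model_config`.
#' @export
mini_model_config <- function(k = 3L, ...) {
  args <- utils::modifyList(
    list(k = k, hidden = 64L, layers = 2L, heads = 4L, ffn = 256L,
         max_positions = 128L, type_vocab = 2L, dropout = 0, seed = 1L),
    list(...)
  )
  do.call(model_config, args)
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> k=%d V=%d H=%d layers=%d heads=%d ffn=%d P=%d\n",
              x$k, x$vocab_size, x$hidden, x$layers, x$heads, x$ffn,
              x$max_positions))
  invisible(x)
}

#' Parameter accounting for the embedding/encoding partition
#'
#' Closed-form counts: the embedding module holds the token, position and
#' type tables plus its layer-norm (`V*H + P*H + T*H + 2H`); the encoding
#' module holds, per layer, four H x H projections with biases, the two
#' feed-forward matrices with biases, and two layer-norms
#' (`4(H^2+H) + (H*F+F) + (F*H+H) + 4H`). The MLM head (`H*V + V`) is
#' counted separately and excluded from `fraction_encoding`, which matches
#' the printed ~98.6% share for the standard 5-mer architecture.
#'
#' @param cfg A [model_config()].
#' @return An object of class `parameter_count` with fields
#'   `embedding_params`, `encoding_params`, `head_params`,
#'   `fraction_encoding`.
#' @examples
#' count_parameters(model_config(k = 5))$fraction_encoding  # ~0.986
#' @export
count_parameters <- function(cfg) {
  stopifnot(inherits(cfg, "model_config"))
  H <- cfg$hidden; V <- cfg$vocab_size; P <- cfg$max_positions
  Tt <- cfg$type_vocab; Fw <- cfg$ffn; Lyr <- cfg$layers
  emb <- as.numeric(V) * H + as.numeric(P) * H + as.numeric(Tt) * H + 2 * H
  enc <- Lyr * (4 * (as.numeric(H)^2 + H) + (as.numeric(H) * Fw + Fw) +
                  (as.numeric(Fw) * H + H) + 2 * 2 * H)
  head <- as.numeric(H) * V + V
  structure(
    list(embedding_params = emb, encoding_params = enc, head_params = head,
         fraction_encoding = enc / (emb + enc)),
    class = "parameter_count"
  )
}

#' @export
print.parameter_count <- function(x, ...) {
  cat(sprintf(
    "<parameter_count> embedding=%s encoding=%s head=%s encoding share=%.1f%%\n",
    format(x$embedding_params, big.mark = ","),
    format(x$encoding_params, big.mark = ","),
    format(x$head_params, big.mark = ","),
    100 * x$fraction_encoding))
  invisible(x)
}

#' Count parameters by walking a built model's actual shapes
#'
#' Independent cross-check of [count_parameters()].
#' @param state A [build_model()] state.
#' @return A `parameter_count`.
#' @export
count_parameters_walk <- function(state) {
  stopifnot(inherits(state, "model_state"))
  sizes <- vapply(state$params, length, numeric(1))
  groups <- param_group(names(state$params))
  structure(
    list(embedding_params = sum(sizes[groups == "embedding"]),
         encoding_params = sum(sizes[groups == "encoding"]),
         head_params = sum(sizes[groups == "head"]),
         fraction_encoding = sum(sizes[groups == "encoding"]) /
           sum(sizes[groups %in% c("embedding", "encoding")])),
    class = "parameter_count"
  )
}

#' Map parameter names to module groups (total, disjoint partition)
#' @noRd
param_group <- function(names) {
  ifelse(startsWith(names, "emb."), "embedding",
         ifelse(startsWith(names, "enc."), "encoding", "head"))
}
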