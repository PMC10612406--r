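#' Overlapping k-mer vocabularies
#'
#' A k-mer vocabulary holds the five BERT special tokens (`[PAD]`, `[UNK]`,
#' `[CLS]`, `[SEP]`, `[MASK]`, ids 0--4) followed by all `4^k` k-mers over
#' `{A,C,G,T}` in lexicographic order (ids `5 .. 4^k+4`). The label search
#' space of a k-mer masked language model is therefore `4^k + 5`.
#'
#' @param k k-mer length, an integer in `[1, 8]`.
#' @return An object of class `kmer_vocab` with fields `k`, `tokens`
#'   (character vector in id order), `special_tokens`, and `index` (a named
#'   integer vector mapping token string to 0-based id).
#' @examples
#' v <- build_vocabulary(2)
#' length(v$tokens)  # 4^2 + 5 = 21
#' @export
build_vocabulary <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k != as.integer(k)) {
    stop_param("k must be a single integer")
  }
  k <- as.integer(k)
  if (k < 1L || k > 8L) {
    stop_param("k must satisfy 1 <= k <= 8 (got %d)", k)
  }
  specials <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")
  kmers <- all_kmers(k)
  tokens <- c(specials, kmers)
  index <- seq_along(tokens) - 1L
  names(index) <- tokens
  structure(
    list(k = k, tokens = tokens, special_tokens = specials, index = index),
    class = "kmer_vocab"
  )
}

#' All k-mers over ACGT in lexicographic order
#' @param k k-mer length.
#' @return Character vector of length `4^k`.
#' @export
all_kmers <- function(k) {
  k <- as.integer(k)
  grids <- rev(rep(list(DNA_BASES), k))
  do.call(paste0, rev(expand.grid(grids, stringsAsFactors = FALSE)))
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat(sprintf("<kmer_vocab> k=%d, %d tokens (4^%d + 5)\n",
              x$k, length(x$tokens), x$k))
  invisible(x)
}

#' Size of the non-trivially inferable label space
#'
#' Under contiguous-k masking every masked k-mer has all but one nucleotide
#' forced by its unmasked overlapping neighbours, so the effective label
#' search space collapses from `4^k + 5` to `4 + 5`, independent of k.
#'
#' @param vocab A [build_vocabulary()] object.
#' @return Integer, `4 + length(special tokens)` (i.e. 9).
#' @export
non_trivial_label_space <- function(vocab) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  4L + length(vocab$special_tokens)
}

vocab_special_ids <- function(vocab) {
  unname(vocab$index[vocab$special_tokens])
}

vocab_id <- function(vocab, token) {
  id <- vocab$index[token]
  if (anyNA(id)) stop_param("unknown token '%s'", token[which(is.na(id))[1]])
  unname(id)
}

#' Tokenize a nucleotide sequence into overlapping k-mers
#'
#' A sequence of length `L` becomes its `L - k + 1` overlapping k-mers in
#' order; consecutive tokens share `k - 1` characters. Optionally a leading
#' `[CLS]` and trailing `[SEP]` are added.
#'
#' @param seq Nucleotide string over `{A,C,G,T}` of length at least `k`.
#' @param vocab A [build_vocabulary()] object.
#' @param add_specials Add `[CLS]`/`[SEP]` boundary tokens (default `TRUE`).
#' @return An object of class `token_seq` with fields `vocab`, `ids`
#'   (0-based token ids, including any boundary tokens), `has_cls`,
#'   `has_sep`, and `source` (the input string).
#' @examples
#' v <- build_vocabulary(5)
#' tokenize("GATCTG", v, add_specials = FALSE)$ids  # the 5-mers GATCT, ATCTG
#' @export
tokenize <- function(seq, vocab, add_specials = TRUE) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  chars <- check_dna(seq)
  k <- vocab$k
  if (length(chars) < k) {
    stop_param("sequence length %d is shorter than k = %d", length(chars), k)
  }
  n <- length(chars) - k + 1L
  kmers <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  ids <- vocab_id(vocab, kmers)
  if (add_specials) {
    ids <- c(vocab_id(vocab, "[CLS]"), ids, vocab_id(vocab, "[SEP]"))
  }
  structure(
    list(vocab = vocab, ids = as.integer(ids),
         has_cls = add_specials, has_sep = add_specials, source = seq),
    class = "token_seq"
  )
}

#' Interior (non-special) token ids of a token sequence
#' @noRd
interior_ids <- function(ts) {
  ids <- ts$ids
  if (ts$has_cls) ids <- ids[-1]
  if (ts$has_sep) ids <- ids[-length(ids)]
  ids
}

#' Number of interior tokens
#' @noRd
n_interior <- function(ts) length(interior_ids(ts))

#' Offset of the first interior token within `ts$ids`
#' @noRd
interior_offset <- function(ts) if (ts$has_cls) 1L else 0L

#' @export
print.token_seq <- function(x, ...) {
  cat(sprintf("<token_seq> k=%d, %d tokens (%d interior)%s\n",
              x$vocab$k, length(x$ids), n_interior(x),
              if (x$has_cls) " +[CLS]/[SEP]" else ""))
  invisible(x)
}

#' Reconstruct the nucleotide string from overlapping k-mer tokens
#'
#' Inverse of [tokenize()]: adjacent interior tokens must agree on their
#' `k - 1`-character overlap, otherwise a consistency error names the first
#' offending pair.
#'
#' @param ts A [tokenize()] result (special tokens are ignored).
#' @return The unique nucleotide string whose overlapping k-mers equal the
#'   interior tokens.
#' @export
detokenize <- function(ts) {
  stopifnot(inherits(ts, "token_seq"))
  vocab <- ts$vocab
  k <- vocab$k
  toks <- vocab$tokens[interior_ids(ts) + 1L]
  if (length(toks) == 0L) stop_param("no interior tokens to decode")
  if (length(toks) > 1L) {
    left <- substring(toks[-length(toks)], 2L, k)
    right <- substring(toks[-1L], 1L, k - 1L)
    bad <- which(left != right)
    if (length(bad) > 0L) {
      i <- bad[1]
      stop_param("overlap-inconsistent adjacent tokens at positions %d/%d: %s vs %s",
                 i, i + 1L, toks[i], toks[i + 1L])
    }
  }
  paste0(toks[1], paste(substring(toks[-1L], k, k), collapse = ""))
}

#' Write / read a vocabulary as two-column TSV (token, id)
#' @param vocab A [build_vocabulary()] object.
#' @param path File path.
#' @return `write_vocabulary` returns `path` invisibly; `read_vocabulary`
#'   returns a `kmer_vocab`.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  utils::write.table(
    data.frame(token = vocab$tokens, id = unname(vocab$index)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer"))
  nk <- sum(!grepl("^\\[", df$token))
  k <- as.integer(round(log(nk, 4)))
  if (4^k != nk) stop_param("token count %d is not 4^k for any k", nk)
  v <- build_vocabulary(k)
  if (!identical(v$tokens, df$token[order(df$id)])) {
    stop_param("vocabulary file does not match canonical token order")
  }
  v
}

#' Write / read token sequences as whitespace-separated token lines
#'
#' One sequence per line, mirroring common k-merized corpus files.
#' @param ts_list List of `token_seq` objects.
#' @param path File path.
#' @param vocab Vocabulary used to decode when reading.
#' @export
write_token_lines <- function(ts_list, path) {
  lines <- vapply(ts_list, function(ts) {
    paste(ts$vocab$tokens[ts$ids + 1L], collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_token_lines
#' @export
read_token_lines <- function(path, vocab) {
  stopifnot(inherits(vocab, "kmer_vocab"))
  lapply(readLines(path), function(line) {
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    has_cls <- length(toks) > 0 && toks[1] == "[CLS]"
    has_sep <- length(toks) > 0 && toks[length(toks)] == "[SEP]"
    interior <- toks[!(toks %in% vocab$special_tokens)]
    src <- if (length(interior) > 0) {
      ts_tmp <- structure(list(vocab = vocab,
                               ids = vocab_id(vocab, interior),
                               has_cls = FALSE, has_sep = FALSE),
                          class = "token_seq")
      tryCatch(detokenize(ts_tmp), error = function(e) NULL)
    } else NULL
    structure(
      list(vocab = vocab, ids = vocab_id(vocab, toks),
           has_cls = has_cls, has_sep = has_sep, source = src),
      class = "token_seq"
    )
  })
}
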