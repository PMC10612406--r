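#' Labeled k-mer embedding tables
#'
#' A matrix of k-mer vectors with row labels, from any source: extracted
#' from a model, one-hot, or loaded from a word2vec-format text file.
#'
#' @param labels Character vector of unique token labels.
#' @param matrix Numeric matrix, one row per label, all entries finite.
#' @param source One of `"model"`, `"one_hot"`, `"external"`.
#' @param includes_specials Whether special-token rows are present.
#' @return An object of class `embedding_table`.
#' @export
embedding_table <- function(labels, matrix,
                            source = c("model", "one_hot", "external"),
                            includes_specials = FALSE) {
  source <- match.arg(source)
  matrix <- as.matrix(matrix)
  if (length(labels) != nrow(matrix)) {
    stop_param("got %d labels for %d rows", length(labels), nrow(matrix))
  }
  if (anyDuplicated(labels)) {
    stop_param("duplicate token label '%s'", labels[anyDuplicated(labels)])
  }
  if (ncol(matrix) < 1) stop_param("embedding dimension must be >= 1")
  if (!all(is.finite(matrix))) stop_param("embedding matrix has non-finite entries")
  rownames(matrix) <- labels
  structure(list(labels = labels, matrix = matrix, source = source,
                 includes_specials = includes_specials),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d x %d, source=%s%s\n",
              nrow(x$matrix), ncol(x$matrix), x$source,
              if (x$includes_specials) " (incl. specials)" else ""))
  invisible(x)
}

#' One-hot k-mer embedding table
#'
#' Identity matrix over the `4^k` k-mers in lexicographic order; dimension
#' `4^k` (256 for 4-mers, 1024 for 5-mers). No special-token rows.
#'
#' @param k k-mer length in `[1, 8]`.
#' @return An `embedding_table` with source `"one_hot"`.
#' @export
one_hot_table <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k != as.integer(k) || k < 1 || k > 8) {
    stop_param("k must be a single integer with 1 <= k <= 8")
  }
  kmers <- all_kmers(k)
  embedding_table(kmers, diag(length(kmers)), source = "one_hot")
}

#' Drop special-token rows from an embedding table
#' @param t An `embedding_table`.
#' @return The table restricted to k-mer rows.
#' @export
drop_specials <- function(t) {
  stopifnot(inherits(t, "embedding_table"))
  keep <- !grepl("^\\[", t$labels)
  embedding_table(t$labels[keep], t$matrix[keep, , drop = FALSE],
                  source = t$source, includes_specials = FALSE)
}

#' Read / write word2vec text format
#'
#' Header line "V d" followed by V rows "token v1 ... vd" (the dna2vec
#' interchange format).
#'
#' @param path File path.
#' @param expected_k If given, validate every label as a k-mer of this
#'   length.
#' @return `load_embedding_table` returns an `embedding_table` with source
#'   `"external"`.
#' @export
load_embedding_table <- function(path, expected_k = NULL) {
  lines <- readLines(path)
  if (length(lines) < 1) stop_param("empty embedding file")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 2 || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop_param("malformed word2vec header at line 1: expected 'V d'")
  }
  V <- as.integer(hdr[1]); d <- as.integer(hdr[2])
  if (length(lines) - 1L != V) {
    stop_param("header declares %d rows but file has %d", V, length(lines) - 1L)
  }
  labels <- character(V)
  mat <- matrix(NA_real_, V, d)
  for (i in seq_len(V)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(parts) != d + 1L) {
      stop_param("parse error at line %d: expected %d values, got %d",
                 i + 1L, d, length(parts) - 1L)
    }
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals)) stop_param("parse error at line %d: non-numeric value", i + 1L)
    labels[i] <- parts[1]
    mat[i, ] <- vals
  }
  if (!is.null(expected_k)) {
    bad <- which(nchar(labels) != expected_k |
                   grepl(sprintf("[^ACGT]"), labels))
    if (length(bad) > 0) {
      stop_param("label '%s' (line %d) is not a %d-mer",
                 labels[bad[1]], bad[1] + 1L, expected_k)
    }
  }
  embedding_table(labels, mat, source = "external")
}

#' @rdname load_embedding_table
#' @param t An `embedding_table` to write.
#' @export
write_embedding_table <- function(t, path) {
  stopifnot(inherits(t, "embedding_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(t$matrix), ncol(t$matrix)), con)
  rows <- apply(t$matrix, 1, function(v) {
    paste(format(v, digits = 8, trim = TRUE, scientific = FALSE),
          collapse = " ")
  })
  writeLines(paste(t$labels, rows), con)
  invisible(path)
}
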