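#' Background sequence models
#'
#' Order-0 (i.i.d.) or order-1 (first-order Markov) nucleotide background.
#' The order-0 uniform model is the "random corpus" used for pre-training
#' contrasts; the order-1 model is a structured stand-in for real genomic
#' text.
#'
#' @param order 0 or 1.
#' @param composition For order 0, a length-4 probability vector over
#'   A,C,G,T; for order 1, a 4x4 row-stochastic transition matrix
#'   (rows/cols in A,C,G,T order).
#' @param initial Length-4 initial distribution (order 1 only; defaults to
#'   the stationary distribution of `composition`).
#' @return An object of class `background_model`.
#' @examples
#' bg <- background_model(0)                    # uniform random
#' s <- generate_background(bg, 1000, seed = 1)
#' @export
background_model <- function(order = 0, composition = NULL, initial = NULL) {
  if (!order %in% c(0, 1)) stop_param("order must be 0 or 1")
  if (order == 0) {
    if (is.null(composition)) composition <- rep(0.25, 4)
    composition <- as.numeric(composition)
    if (length(composition) != 4 || any(composition < 0) ||
        abs(sum(composition) - 1) > 1e-9) {
      stop_param("composition must be a length-4 probability vector summing to 1")
    }
    initial <- composition
  } else {
    if (is.null(composition)) stop_param("order-1 model needs a transition matrix")
    composition <- as.matrix(composition)
    if (!all(dim(composition) == c(4, 4)) || any(composition < 0) ||
        any(abs(rowSums(composition) - 1) > 1e-9)) {
      stop_param("transition matrix must be 4x4 row-stochastic")
    }
    if (is.null(initial)) initial <- stationary_distribution(composition)
    initial <- as.numeric(initial)
    if (length(initial) != 4 || any(initial < 0) ||
        abs(sum(initial) - 1) > 1e-9) {
      stop_param("initial must be a length-4 probability vector summing to 1")
    }
  }
  structure(list(order = order, composition = composition, initial = initial),
            class = "background_model")
}

#' Stationary distribution of a 4x4 transition matrix
#' @noRd
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Generate a background nucleotide string
#'
#' @param model A [background_model()].
#' @param length Number of bases (>= 1).
#' @param seed Integer seed; output is bit-reproducible given (model, seed).
#' @return A single nucleotide string.
#' @export
generate_background <- function(model, length, seed = NULL) {
  stopifnot(inherits(model, "background_model"))
  length <- as.integer(length)
  if (length < 1L) stop_param("length must be >= 1")
  local_seed(seed, {
    if (model$order == 0) {
      paste(sample(DNA_BASES, length, replace = TRUE, prob = model$composition),
            collapse = "")
    } else {
      P <- model$composition
      cum <- t(apply(P, 1, cumsum))
      us <- stats::runif(length)
      states <- integer(length)
      s <- findInterval(us[1], cumsum(model$initial)) + 1L
      states[1] <- s
      if (length > 1L) {
        for (i in 2:length) {
          u <- us[i]
          s <- 1L + (u > cum[s, 1]) + (u > cum[s, 2]) + (u > cum[s, 3])
          states[i] <- s
        }
      }
      paste(DNA_BASES[states], collapse = "")
    }
  })
}

#' Generate a corpus of background sequences
#'
#' @param model A [background_model()].
#' @param n_sequences Number of sequences.
#' @param length Length of each sequence.
#' @param seed Integer seed.
#' @return Character vector of nucleotide strings.
#' @export
generate_corpus <- function(model, n_sequences, length, seed = NULL) {
  vapply(seq_len(n_sequences), function(i) {
    generate_background(model, length,
                        seed = if (is.null(seed)) NULL else mix_seed(seed, i))
  }, character(1))
}

#' Empirical transition matrix of a nucleotide string
#' @param seq Nucleotide string.
#' @return 4x4 row-stochastic matrix (A,C,G,T order).
#' @export
empirical_transitions <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  a <- factor(chars[-length(chars)], levels = DNA_BASES)
  b <- factor(chars[-1], levels = DNA_BASES)
  tb <- table(a, b)
  m <- unclass(tb / pmax(rowSums(tb), 1))
  dimnames(m) <- list(DNA_BASES, DNA_BASES)
  m
}

#' Read / write FASTA corpora
#'
#' Thin wrappers over Biostrings when available, with a plain-text fallback.
#' @param path FASTA file path.
#' @param seqs Named or unnamed character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    stats::setNames(as.character(x), names(x))
  } else {
    lines <- readLines(path)
    idx <- grepl("^>", lines)
    headers <- sub("^>\\s*", "", lines[idx])
    grp <- cumsum(idx)
    seqs <- vapply(split(lines[!idx], grp[!idx]), paste, character(1),
                   collapse = "")
    stats::setNames(toupper(seqs), headers)
  }
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  } else {
    writeLines(paste0(">", names(seqs), "\n", seqs), path)
  }
  invisible(path)
}
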