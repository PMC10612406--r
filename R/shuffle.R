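#' Dinucleotide-preserving sequence shuffle
#'
#' Random shuffle of a nucleotide sequence that preserves the exact multiset
#' of overlapping dinucleotides (and hence the first and last characters),
#' via the Euler-path construction of Altschul & Erikson: the sequence is a
#' walk on the 4-vertex de Bruijn multigraph whose edges are its adjacent
#' base pairs; a uniform-ish random Eulerian walk with the same edge multiset
#' is produced by (i) choosing, for every vertex except the terminal one, a
#' random "last exit" edge such that the chosen edges form an arborescence
#' into the terminal vertex, (ii) permuting each vertex's remaining out-edges
#' uniformly, then (iii) walking the graph from the original first character.
#'
#' @param seq Nucleotide string, length >= 2.
#' @param seed Optional integer seed (deterministic output when given).
#' @return A shuffled string with identical dinucleotide counts.
#' @examples
#' s <- dinucleotide_shuffle("ACGCGATTAC", seed = 1)
#' identical(dinucleotide_counts(s), dinucleotide_counts("ACGCGATTAC"))
#' @export
dinucleotide_shuffle <- function(seq, seed = NULL) {
  chars <- check_dna(seq)
  n <- length(chars)
  if (n < 2L) stop_param("sequence must have length >= 2")
  local_seed(seed, dinucleotide_shuffle_impl(chars))
}

dinucleotide_shuffle_impl <- function(chars) {
  n <- length(chars)
  from <- match(chars[-n], DNA_BASES)
  to <- match(chars[-1], DNA_BASES)
  last <- match(chars[n], DNA_BASES)
  first <- match(chars[1], DNA_BASES)
  # out-edge target lists per vertex
  out <- lapply(1:4, function(v) to[from == v])
  present <- which(vapply(out, length, integer(1)) > 0L | 1:4 == last)

  repeat {
    # pick a candidate last-exit edge for every non-terminal vertex with
    # out-edges; accept if they form an arborescence into the terminal vertex
    last_exit <- rep(NA_integer_, 4)
    for (v in present) {
      if (v != last && length(out[[v]]) > 0L) {
        last_exit[v] <- out[[v]][sample.int(length(out[[v]]), 1L)]
      }
    }
    ok <- TRUE
    for (v in present) {
      if (v == last || is.na(last_exit[v])) next
      cur <- v
      steps <- 0L
      while (cur != last && steps <= 4L) {
        if (is.na(last_exit[cur])) break
        cur <- last_exit[cur]
        steps <- steps + 1L
      }
      if (cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }

  # permute remaining edges, append the reserved last exit
  ordered <- lapply(1:4, function(v) {
    edges <- out[[v]]
    if (!is.na(last_exit[v])) {
      i <- match(last_exit[v], edges)
      edges <- edges[-i]
    }
    if (length(edges) > 1L) edges <- edges[sample.int(length(edges))]
    c(edges, if (!is.na(last_exit[v])) last_exit[v])
  })

  # walk
  res <- integer(n)
  res[1] <- first
  ptr <- rep(1L, 4)
  cur <- first
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(DNA_BASES[res], collapse = "")
}

#' Overlapping dinucleotide counts of a sequence
#' @param seq Nucleotide string.
#' @return Named integer vector over the 16 dinucleotides.
#' @export
dinucleotide_counts <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) return(stats::setNames(integer(16), all_kmers(2)))
  di <- paste0(chars[-n], chars[-1])
  tb <- table(factor(di, levels = all_kmers(2)))
  stats::setNames(as.integer(tb), names(tb))
}
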