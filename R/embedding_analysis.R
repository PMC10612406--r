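#' Geometry of k-mer embedding tables
#'
#' Statistics quantifying "overlapping-consistent" embedding geometry:
#' whether k-mers that share prefixes or suffixes (i.e. could be adjacent in
#' an overlapping tokenization) lie close together, and whether the four
#' central-nucleotide classes separate.
#'
#' @name embedding_analysis
NULL

#' Prefix/suffix overlap between two k-mers
#'
#' The largest `m` in `[0, k-1]` such that the length-`m` suffix of one
#' string equals the length-`m` prefix of the other (checked in both
#' directions). Consecutive tokens of an overlapping tokenization score
#' `k - 1`.
#'
#' @param a,b k-mer strings of equal length.
#' @return Integer overlap in `[0, k-1]`.
#' @examples
#' overlap_score("GATCT", "ATCTG")  # 4
#' @export
overlap_score <- function(a, b) {
  k <- nchar(a)
  if (nchar(b) != k) stop_param("k-mer lengths differ (%d vs %d)", k, nchar(b))
  for (m in (k - 1L):0L) {
    if (m == 0L) return(0L)
    if (substr(a, k - m + 1L, k) == substr(b, 1L, m) ||
        substr(b, k - m + 1L, k) == substr(a, 1L, m)) {
      return(m)
    }
  }
  0L
}

#' Shared-affix score between two k-mers
#'
#' The largest `m` in `[0, k-1]` such that the two k-mers share their
#' length-`m` prefix or their length-`m` suffix. This is the similarity that
#' clustered embedding families exhibit: families like `CTCCN` (shared
#' 4-prefix) or `NGCTT` (shared 4-suffix) score `k - 1` with each other.
#' Contrast with [overlap_score()], which measures chainability (suffix of
#' one equals prefix of the other) and underlies prediction consistency.
#'
#' @param a,b k-mer strings of equal length.
#' @return Integer in `[0, k-1]`.
#' @examples
#' affix_score("CTCCA", "CTCCG")  # 4: shared prefix CTCC
#' @export
affix_score <- function(a, b) {
  k <- nchar(a)
  if (nchar(b) != k) stop_param("k-mer lengths differ (%d vs %d)", k, nchar(b))
  for (m in (k - 1L):0L) {
    if (m == 0L) return(0L)
    if (substr(a, 1L, m) == substr(b, 1L, m) ||
        substr(a, k - m + 1L, k) == substr(b, k - m + 1L, k)) {
      return(m)
    }
  }
  0L
}

#' Pairwise k-mer score matrices
#'
#' @param labels Character vector of k-mers.
#' @param score `"chain"` for [overlap_score()], `"affix"` for
#'   [affix_score()].
#' @return Integer matrix (0 diagonal).
#' @export
kmer_score_matrix <- function(labels, score = c("chain", "affix")) {
  score <- match.arg(score)
  k <- nchar(labels[1])
  n <- length(labels)
  O <- matrix(0L, n, n)
  if (k > 1) {
    pref <- lapply(1:(k - 1), function(m) substr(labels, 1L, m))
    suf <- lapply(1:(k - 1), function(m) substr(labels, k - m + 1L, k))
    for (m in 1:(k - 1)) {
      hit <- if (score == "chain") {
        outer(suf[[m]], pref[[m]], "==") | outer(pref[[m]], suf[[m]], "==")
      } else {
        outer(pref[[m]], pref[[m]], "==") | outer(suf[[m]], suf[[m]], "==")
      }
      O[hit] <- m  # increasing m overwrites smaller scores
    }
  }
  diag(O) <- 0L
  dimnames(O) <- list(labels, labels)
  O
}

#' @rdname kmer_score_matrix
#' @export
overlap_score_matrix <- function(labels) {
  kmer_score_matrix(labels, "chain")
}

cosine_distance_matrix <- function(M) {
  nrm <- sqrt(rowSums(M * M))
  nrm[nrm == 0] <- 1
  S <- tcrossprod(M / nrm)
  D <- 1 - S
  D[D < 0] <- 0
  diag(D) <- 0
  D
}

euclidean_distance_matrix <- function(M) {
  as.matrix(stats::dist(M))
}

table_distances <- function(t, metric) {
  switch(metric,
         cosine = cosine_distance_matrix(t$matrix),
         euclidean = euclidean_distance_matrix(t$matrix),
         stop_param("unknown metric '%s'", metric))
}

#' Nearest-neighbor overlap-consistency statistic with a permutation null
#'
#' For every k-mer, its `n_neighbors` nearest rows (self excluded, distance
#' ties broken by lexicographic token order) are found and the mean pairwise
#' score with them recorded; the statistic is the grand mean
#' over k-mers (in characters, range `[0, k-1]`). The null distribution is
#' obtained by randomly permuting the row labels `permutations` times --
#' geometry fixed, identity of the points destroyed -- and
#' `empirical_p = (1 + #{null >= observed}) / (M + 1)`.
#'
#' @param t An `embedding_table` containing only k-mer rows (use
#'   [drop_specials()] first).
#' @param n_neighbors Neighbors per k-mer (default 10).
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @param permutations Number of label permutations M (default 999).
#' @param seed Integer seed for the permutations.
#' @param score Pairwise k-mer similarity: `"affix"` (default; shared
#'   prefix/suffix length, the clustering trained models display) or
#'   `"chain"` (the chainability [overlap_score()]).
#' @return An object of class `overlap_consistency_report`:
#'   `observed_mean_overlap`, `null_mean`, `null_sd`, `empirical_p`, `z`,
#'   plus the settings.
#' @export
neighbor_overlap_statistic <- function(t, n_neighbors = 10L,
                                       metric = c("cosine", "euclidean"),
                                       permutations = 999L, seed = 1L,
                                       score = c("affix", "chain")) {
  stopifnot(inherits(t, "embedding_table"))
  metric <- match.arg(metric)
  score <- match.arg(score)
  if (any(grepl("^\\[", t$labels))) {
    stop_param("table contains special tokens; call drop_specials() first")
  }
  n <- length(t$labels)
  if (n_neighbors < 1L || n_neighbors >= n) {
    stop_param("n_neighbors must be in [1, %d]", n - 1L)
  }
  ord_lex <- order(t$labels)
  lex_rank <- integer(n); lex_rank[ord_lex] <- seq_len(n)
  D <- table_distances(t, metric)
  nb <- matrix(0L, n, n_neighbors)
  for (i in seq_len(n)) {
    o <- order(D[i, ], lex_rank)  # ties by lexicographic label order
    o <- o[o != i]
    nb[i, ] <- o[seq_len(n_neighbors)]
  }
  O <- kmer_score_matrix(t$labels, score)
  mean_overlap_for <- function(perm) {
    # perm maps row -> label slot; score between permuted labels
    tot <- 0
    for (i in seq_len(n)) tot <- tot + mean(O[perm[i], perm[nb[i, ]]])
    tot / n
  }
  observed <- mean_overlap_for(seq_len(n))
  null_vals <- local_seed(seed, {
    vapply(seq_len(permutations), function(m) {
      mean_overlap_for(sample.int(n))
    }, numeric(1))
  })
  null_mean <- mean(null_vals)
  null_sd <- stats::sd(null_vals)
  structure(
    list(n_neighbors = as.integer(n_neighbors), metric = metric,
         score = score,
         observed_mean_overlap = observed, null_mean = null_mean,
         null_sd = null_sd, permutations = as.integer(permutations),
         empirical_p = (1 + sum(null_vals >= observed)) / (permutations + 1),
         z = if (null_sd > 0) (observed - null_mean) / null_sd else Inf),
    class = "overlap_consistency_report"
  )
}

#' @export
print.overlap_consistency_report <- function(x, ...) {
  cat(sprintf(
    "<overlap_consistency> observed=%.3f null=%.3f+/-%.3f z=%.1f p=%.4g\n",
    x$observed_mean_overlap, x$null_mean, x$null_sd, x$z, x$empirical_p))
  invisible(x)
}

central_base <- function(labels) {
  k <- nchar(labels[1])
  if (k %% 2 == 0) stop_param("no unique central position for even k = %d", k)
  substr(labels, (k + 1L) %/% 2L, (k + 1L) %/% 2L)
}

#' Central-nucleotide cluster separation
#'
#' Mean silhouette width of the four classes defined by the nucleotide at
#' each k-mer's central position, computed on the full-dimensional rows.
#' Values near 1 indicate perfectly separated central-base clusters; 0
#' indicates no separation (e.g. a one-hot table where all inter-row
#' distances are equal).
#'
#' @param t An `embedding_table` with k-mer rows only and odd k.
#' @param metric `"cosine"` (default) or `"euclidean"`.
#' @return An object of class `separation_report` with fields `silhouette`,
#'   `groups` (sizes), `metric`.
#' @export
central_nucleotide_separation <- function(t, metric = c("cosine", "euclidean")) {
  stopifnot(inherits(t, "embedding_table"))
  metric <- match.arg(metric)
  if (any(grepl("^\\[", t$labels))) {
    stop_param("table contains special tokens; call drop_specials() first")
  }
  grp <- factor(central_base(t$labels), levels = DNA_BASES)
  D <- table_distances(t, metric)
  sil <- cluster::silhouette(as.integer(grp), dmatrix = D)
  structure(
    list(silhouette = mean(sil[, "sil_width"]),
         groups = table(grp), metric = metric),
    class = "separation_report"
  )
}

#' @export
print.separation_report <- function(x, ...) {
  cat(sprintf("<separation_report> mean silhouette %.3f (%s metric)\n",
              x$silhouette, x$metric))
  invisible(x)
}

#' 2-D t-SNE projection of an embedding table
#'
#' @param t An `embedding_table` (>= 10 rows).
#' @param perplexity t-SNE perplexity (default 30, reduced automatically for
#'   small tables).
#' @param iterations Gradient-descent iterations (default 1000).
#' @param seed Integer seed; coordinates are deterministic given the seed.
#' @param plot_file Optional PNG/SVG path; a scatter colored by central base
#'   (odd k, specials shown in grey) is written when given.
#' @return An object of class `projection_2d` with `coordinates`
#'   (n x 2 matrix, labeled rows) and the parameters.
#' @export
project_2d <- function(t, perplexity = 30, iterations = 1000L, seed = 1L,
                       plot_file = NULL) {
  stopifnot(inherits(t, "embedding_table"))
  n <- nrow(t$matrix)
  if (n < 10) stop_param("need at least 10 rows for a 2-D projection")
  if (nrow(unique(t$matrix)) == 1) {
    stop_param("degenerate table: all rows identical")
  }
  perplexity <- min(perplexity, floor((n - 1) / 3))
  coords <- local_seed(seed, {
    Rtsne::Rtsne(t$matrix, dims = 2, perplexity = perplexity,
                 max_iter = as.integer(iterations), pca = FALSE,
                 check_duplicates = FALSE, verbose = FALSE)$Y
  })
  rownames(coords) <- t$labels
  out <- structure(
    list(coordinates = coords, perplexity = perplexity,
         iterations = as.integer(iterations), seed = as.integer(seed)),
    class = "projection_2d"
  )
  if (!is.null(plot_file)) plot_projection(out, t, plot_file)
  out
}

plot_projection <- function(proj, t, path) {
  is_special <- grepl("^\\[", t$labels)
  kmers <- t$labels[!is_special]
  col <- rep("grey40", length(t$labels))
  if (length(kmers) > 0 && nchar(kmers[1]) %% 2 == 1) {
    pal <- c(A = "#1b9e77", T = "#d95f02", G = "#7570b3", C = "#e7298a")
    col[!is_special] <- pal[central_base(kmers)]
  }
  opener <- if (grepl("\\.svg$", path)) {
    function(p) grDevices::svg(p, width = 7, height = 7)
  } else {
    function(p) grDevices::png(p, width = 900, height = 900, res = 130)
  }
  opener(path)
  on.exit(grDevices::dev.off())
  graphics::plot(proj$coordinates, col = col, pch = 19, cex = 0.6,
                 xlab = "t-SNE 1", ylab = "t-SNE 2",
                 main = "k-mer embedding projection (central base)")
  graphics::legend("topright", legend = c("A", "T", "G", "C", "special"),
                   col = c("#1b9e77", "#d95f02", "#7570b3", "#e7298a",
                           "grey40"), pch = 19, cex = 0.8)
  invisible(path)
}
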