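test_that("one-hot tables have dimension 4^k and identity structure", {
  expect_identical(dim(one_hot_table(4)$matrix), c(256L, 256L))
  expect_identical(dim(one_hot_table(5)$matrix), c(1024L, 1024L))
  t1 <- one_hot_table(1)
  expect_identical(unname(t1$matrix), diag(4))
  expect_identical(t1$labels, c("A", "C", "G", "T"))
  expect_false(t1$includes_specials)
  expect_error(one_hot_table(9), "1 <= k <= 8")
})

test_that("word2vec text format round trips and rejects malformed input", {
  tab <- embedding_table(all_kmers(2), matrix(rnorm(16 * 5), 16, 5),
                         source = "external")
  path <- withr::local_tempfile(fileext = ".txt")
  write_embedding_table(tab, path)
  back <- load_embedding_table(path, expected_k = 2)
  expect_identical(back$labels, tab$labels)
  expect_equal(back$matrix, tab$matrix, tolerance = 1e-6,
               ignore_attr = TRUE)
  # row with wrong arity
  lines <- readLines(path)
  lines[3] <- paste(strsplit(lines[3], " ")[[1]][1:4], collapse = " ")
  writeLines(lines, path)
  expect_error(load_embedding_table(path), "line 3")
  # duplicate label
  writeLines(c("2 2", "AA 1 2", "AA 3 4"), path)
  expect_error(load_embedding_table(path), "duplicate")
  # wrong k
  writeLines(c("1 2", "AAA 1 2"), path)
  expect_error(load_embedding_table(path, expected_k = 2), "not a 2-mer")
  writeLines(c("garbage"), path)
  expect_error(load_embedding_table(path), "header")
})

test_that("the bundled synthetic word2vec example table loads", {
  path <- system.file("extdata", "synthetic_dna2vec_2mer.w2v.txt",
                      package = "kmerlm")
  tab <- load_embedding_table(path, expected_k = 2)
  expect_identical(dim(tab$matrix), c(16L, 10L))
  expect_identical(tab$source, "external")
})

test_that("overlap_score matches spec examples and brute force for k <= 4", {
  expect_identical(overlap_score("GATCT", "ATCTG"), 4L)
  expect_identical(overlap_score("AAAAA", "CCCCC"), 0L)
  expect_identical(overlap_score("ACGTA", "GTACG"), 3L)
  expect_error(overlap_score("ACG", "ACGT"), "lengths differ")
  brute <- function(a, b) {
    k <- nchar(a)
    best <- 0L
    for (m in 1:(k - 1)) {
      if (substr(a, k - m + 1, k) == substr(b, 1, m) ||
          substr(b, k - m + 1, k) == substr(a, 1, m)) best <- m
    }
    best
  }
  for (k in 2:4) {
    km <- all_kmers(k)
    set.seed(k)
    pairs <- cbind(sample(km, 300, TRUE), sample(km, 300, TRUE))
    for (i in seq_len(nrow(pairs))) {
      expect_identical(overlap_score(pairs[i, 1], pairs[i, 2]),
                       brute(pairs[i, 1], pairs[i, 2]))
    }
    O <- overlap_score_matrix(km)
    idx <- cbind(sample(length(km), 100, TRUE), sample(length(km), 100, TRUE))
    for (i in 1:100) {
      expect_identical(O[idx[i, 1], idx[i, 2]],
                       if (idx[i, 1] == idx[i, 2]) 0L else
                         overlap_score(km[idx[i, 1]], km[idx[i, 2]]))
    }
  }
})

test_that("affix score matches a brute-force definition", {
  expect_identical(affix_score("CTCCA", "CTCCG"), 4L)
  expect_identical(affix_score("AGCTT", "GGCTT"), 4L)  # shared suffix
  expect_identical(affix_score("AAAAA", "CCCCC"), 0L)
  brute <- function(a, b) {
    k <- nchar(a); best <- 0L
    for (m in 1:(k - 1)) {
      if (substr(a, 1, m) == substr(b, 1, m) ||
          substr(a, k - m + 1, k) == substr(b, k - m + 1, k)) best <- m
    }
    best
  }
  set.seed(9)
  km <- all_kmers(3)
  A <- kmer_score_matrix(km, "affix")
  for (t in 1:150) {
    i <- sample(64, 1); j <- sample(64, 1)
    expect_identical(A[i, j],
                     if (i == j) 0L else brute(km[i], km[j]))
  }
})

test_that("affix statistic flags substitution-family clustering", {
  # spec-style indicator-block table: each k-mer is the concatenation of
  # position-specific one-hot blocks, so one-substitution partners (which
  # share long prefixes/suffixes) are the nearest neighbours
  tab <- fixture_block_table(3)
  rep_ <- neighbor_overlap_statistic(tab, n_neighbors = 6,
                                     permutations = 499, seed = 2)
  expect_gt(rep_$observed_mean_overlap, rep_$null_mean + 3 * rep_$null_sd)
  expect_identical(rep_$empirical_p, 1 / 500)
})

test_that("neighbor overlap statistic separates chainability-structured tables", {
  # table whose rows encode chain position: embeddings built from suffix
  # content so that chainable k-mers (suffix of a = prefix of b) are close
  k <- 3L
  kmers <- all_kmers(k)
  M <- matrix(0, length(kmers), 32L)
  set.seed(10)
  proto <- matrix(rnorm(16 * 32), 16, 32)  # one prototype per 2-mer
  two <- all_kmers(2)
  for (i in seq_along(kmers)) {
    suf <- substr(kmers[i], 2, 3)
    pre <- substr(kmers[i], 1, 2)
    M[i, ] <- proto[match(suf, two), ] + proto[match(pre, two), ]
  }
  tab <- embedding_table(kmers, M, source = "external")
  rep_ <- neighbor_overlap_statistic(tab, n_neighbors = 6, permutations = 499,
                                     seed = 2, score = "chain")
  expect_gt(rep_$observed_mean_overlap, rep_$null_mean + 3 * rep_$null_sd)
  expect_identical(rep_$empirical_p, 1 / 500)
  # one-hot table: all inter-row distances are equal, so the neighbour sets
  # are purely the lexicographic tie-break; under the chain score that
  # neighbourhood is null-like (lexicographic neighbours are not chainable
  # beyond chance), while the affix score is deterministically inflated by
  # shared prefixes and says nothing about geometry
  oh <- one_hot_table(3)
  rep_oh <- neighbor_overlap_statistic(oh, n_neighbors = 6,
                                       permutations = 299, seed = 3,
                                       score = "chain")
  expect_lt(abs(rep_oh$observed_mean_overlap - rep_oh$null_mean),
            2 * rep_oh$null_sd)
  expect_gt(rep_oh$empirical_p, 0.01)
})

test_that("neighbor overlap statistic validates inputs", {
  m <- fixture_untrained_k3()
  with_specials <- extract_token_embeddings(m, include_specials = TRUE)
  expect_error(neighbor_overlap_statistic(with_specials), "drop_specials")
  tab <- extract_token_embeddings(m)
  expect_error(neighbor_overlap_statistic(tab, n_neighbors = 64), "n_neighbors")
})

test_that("central nucleotide separation behaves on reference geometries", {
  # rows depend only on the central base -> silhouette ~ 1
  kmers <- all_kmers(3)
  centers <- substr(kmers, 2, 2)
  proto <- diag(4)[match(centers, c("A", "C", "G", "T")), ]
  set.seed(4)
  M <- proto + matrix(rnorm(length(kmers) * 4, 0, 1e-3), length(kmers), 4)
  sep <- central_nucleotide_separation(
    embedding_table(kmers, M, source = "external"))
  expect_gt(sep$silhouette, 0.95)
  expect_identical(unname(as.integer(sep$groups)), rep(16L, 4))
  # one-hot: all distances equal -> silhouette ~ 0
  sep_oh <- central_nucleotide_separation(one_hot_table(3))
  expect_lt(abs(sep_oh$silhouette), 0.05)
  expect_error(central_nucleotide_separation(one_hot_table(2)), "even k")
})

test_that("2-D projection is deterministic and complete", {
  m <- build_model(mini_model_config(k = 3, hidden = 16, heads = 2, ffn = 32,
                                     seed = 15))
  tab <- extract_token_embeddings(m, include_specials = TRUE)
  p1 <- project_2d(tab, perplexity = 10, iterations = 150, seed = 7)
  expect_identical(dim(p1$coordinates), c(69L, 2L))
  expect_true(all(is.finite(p1$coordinates)))
  p2 <- project_2d(tab, perplexity = 10, iterations = 150, seed = 7)
  expect_identical(p1$coordinates, p2$coordinates)
  png_path <- withr::local_tempfile(fileext = ".png")
  project_2d(tab, perplexity = 10, iterations = 100, seed = 7,
             plot_file = png_path)
  expect_true(file.exists(png_path) && file.size(png_path) > 0)
  degen <- embedding_table(all_kmers(2), matrix(1, 16, 4), source = "external")
  expect_error(project_2d(degen), "degenerate")
})
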