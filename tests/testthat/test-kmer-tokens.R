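test_that("vocabulary has 4^k + 5 tokens with stable contiguous ids", {
  for (k in c(1L, 2L, 5L)) {
    v <- build_vocabulary(k)
    expect_length(v$tokens, 4^k + 5)
    expect_identical(unname(v$index[v$tokens]), 0:(4^k + 4L))
    expect_identical(v$special_tokens,
                     c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]"))
    kmers <- v$tokens[-(1:5)]
    expect_identical(kmers, sort(kmers))     # lexicographic
    expect_true(all(nchar(kmers) == k))
    expect_identical(anyDuplicated(v$tokens), 0L)
  }
  expect_error(build_vocabulary(0), "1 <= k <= 8")
  expect_error(build_vocabulary(9), "1 <= k <= 8")
})

test_that("k=2 k-mer portion enumerates AA..TT in order", {
  v <- build_vocabulary(2)
  expect_length(v$tokens, 21)
  expect_identical(v$tokens[6:9], c("AA", "AC", "AG", "AT"))
  expect_identical(v$tokens[21], "TT")
})

test_that("tokenize produces overlapping k-mers with optional specials", {
  v <- build_vocabulary(5)
  ts <- tokenize("GATCTG", v, add_specials = FALSE)
  expect_identical(v$tokens[ts$ids + 1L], c("GATCT", "ATCTG"))
  ts2 <- tokenize("GATCTGAC", v)
  expect_identical(n_interior(ts2), 4L)      # L - k + 1
  expect_identical(v$tokens[ts2$ids[1] + 1L], "[CLS]")
  expect_identical(v$tokens[ts2$ids[length(ts2$ids)] + 1L], "[SEP]")
  ts3 <- tokenize("ACGT", build_vocabulary(1), add_specials = FALSE)
  expect_identical(build_vocabulary(1)$tokens[ts3$ids + 1L],
                   c("A", "C", "G", "T"))
  expect_error(tokenize("ACGN", v), "position 4")
  expect_error(tokenize("ACG", v), "shorter than k")
})

test_that("detokenize inverts tokenize and flags inconsistent overlaps", {
  v <- build_vocabulary(5)
  ts <- tokenize("GATCTG", v, add_specials = FALSE)
  expect_identical(detokenize(ts), "GATCTG")
  bad <- structure(list(vocab = v,
                        ids = unname(v$index[c("GATCT", "GTTTG")]),
                        has_cls = FALSE, has_sep = FALSE),
                   class = "token_seq")
  expect_error(detokenize(bad), "GATCT.*GTTTG")
  single <- structure(list(vocab = v, ids = unname(v$index["AAAAA"]),
                           has_cls = FALSE, has_sep = FALSE),
                      class = "token_seq")
  expect_identical(detokenize(single), "AAAAA")
})

test_that("round trip holds for random sequences (property)", {
  set.seed(101)
  for (i in 1:40) {
    k <- sample(1:6, 1)
    L <- k + sample(0:60, 1)
    s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    v <- build_vocabulary(k)
    expect_identical(detokenize(tokenize(s, v)), s)
  }
})

test_that("mask_contiguous places whole non-overlapping runs of k", {
  v <- build_vocabulary(5)
  s <- paste(rep("ACGTG", 21), collapse = "")  # 105 bp -> 101 tokens
  ts <- tokenize(s, v)
  n <- n_interior(ts)
  plan <- mask_contiguous(ts, 0.15, rng_seed = 9)
  expect_true(all(plan$runs$length == 5L))
  expect_identical(length(plan$masked_pos), nrow(plan$runs) * 5L)
  expect_identical(anyDuplicated(plan$masked_pos), 0L)  # no overlap
  expect_true(abs(plan$achieved_rate - 0.15) <= 0.05)
  expect_true(all(plan$masked_pos >= 1 & plan$masked_pos <= n))
  # 100 interior tokens, rate .15, k=5 -> 3 runs, 15 masked
  s2 <- paste(rep("A", 104), collapse = "")
  ts2 <- tokenize(s2, v)
  plan2 <- mask_contiguous(ts2, 0.15, rng_seed = 1)
  expect_identical(nrow(plan2$runs), 3L)
  expect_identical(length(plan2$masked_pos), 15L)
})

test_that("mask_contiguous minimum one run and determinism", {
  v <- build_vocabulary(5)
  ts <- tokenize(paste(rep("A", 10), collapse = ""), v)  # 6 interior tokens
  plan <- mask_contiguous(ts, 0.15, rng_seed = 2)
  expect_identical(nrow(plan$runs), 1L)
  expect_identical(length(plan$masked_pos), 5L)
  p1 <- mask_contiguous(ts, 0.3, rng_seed = 77)
  p2 <- mask_contiguous(ts, 0.3, rng_seed = 77)
  expect_identical(p1, p2)
  expect_error(mask_contiguous(ts, 1.5, 1), "rate")
  tiny <- tokenize("ACGTGA", v)  # 2 interior < k
  expect_error(mask_contiguous(tiny, 0.15, 1), "at least k")
})

test_that("masked fraction approaches target rate on long sequences", {
  v <- build_vocabulary(5)
  s <- paste(sample(c("A", "C", "G", "T"), 1004, TRUE), collapse = "")
  ts <- tokenize(s, v)  # 1000 interior tokens
  for (seed in 1:5) {
    plan <- mask_contiguous(ts, 0.15, rng_seed = seed)
    expect_true(abs(plan$achieved_rate - 0.15) < 0.05)
  }
})

# brute-force oracle: enumerate all completions of the masked span that are
# consistent with the unmasked tokens; a position is free iff > 1 value
# occurs among consistent completions
brute_force_free <- function(ts, plan) {
  v <- ts$vocab
  k <- v$k
  src <- strsplit(ts$source, "")[[1]]
  n <- n_interior(ts)
  masked <- logical(n)
  masked[plan$masked_pos] <- TRUE
  unknown <- setdiff(seq_along(src),
                     unlist(lapply(which(!masked), function(i) i:(i + k - 1L))))
  if (length(unknown) == 0L) return(integer(0))
  grid <- expand.grid(rep(list(c("A", "C", "G", "T")), length(unknown)),
                      stringsAsFactors = FALSE)
  free <- rep(FALSE, length(unknown))
  values <- vector("list", length(unknown))
  for (r in seq_len(nrow(grid))) {
    cand <- src
    cand[unknown] <- unlist(grid[r, ])
    # all completions are consistent (unmasked tokens already fixed);
    # track which positions vary
    for (j in seq_along(unknown)) {
      values[[j]] <- union(values[[j]], cand[unknown[j]])
    }
  }
  unknown[vapply(values, length, integer(1)) > 1]
}

test_that("inferability: isolated interior run of k leaves one free position", {
  v <- build_vocabulary(5)
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  ts <- tokenize(s, v)
  plan <- manual_plan(ts, 12, 5)
  rep_ <- analyze_inferability(ts, plan)
  expect_identical(rep_$count_free, 1L)
  # the free position is the centre of the masked nucleotide span
  expect_identical(rep_$free_pos, 12L + 5L - 1L)
  # single masked token: everything deducible from neighbours
  plan1 <- manual_plan(ts, 12, 1)
  expect_identical(analyze_inferability(ts, plan1)$count_free, 0L)
  # all tokens masked: every position free
  plan_all <- manual_plan(ts, 1, n_interior(ts))
  expect_identical(analyze_inferability(ts, plan_all)$count_free, 40L)
})

test_that("inferability agrees with brute-force enumeration (property)", {
  v <- build_vocabulary(3)
  set.seed(42)
  for (i in 1:12) {
    L <- sample(12:20, 1)
    s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    ts <- tokenize(s, v)
    n <- n_interior(ts)
    start <- sample.int(n, 1)
    len <- sample(1:4, 1)
    plan <- manual_plan(ts, start, len)   # may truncate at boundary
    rep_ <- analyze_inferability(ts, plan)
    expect_identical(rep_$free_pos, brute_force_free(ts, plan),
                     info = sprintf("seq %s start %d len %d", s, start, len))
  }
})

test_that("runs truncated at the left boundary free extra positions", {
  v <- build_vocabulary(5)
  s <- paste(rep("ACGTG", 6), collapse = "")
  ts <- tokenize(s, v)
  plan <- manual_plan(ts, 1, 2)  # masked run abutting the sequence start
  rep_ <- analyze_inferability(ts, plan)
  # chars 1..6 covered only by masked tokens except 6? tokens 1,2 masked;
  # token 3 (unmasked) covers chars 3..7 -> chars 1,2 free
  expect_identical(rep_$free_pos, c(1L, 2L))
})

test_that("non-trivial label space is 4 + 5 independent of k", {
  for (k in c(1L, 3L, 5L)) {
    expect_identical(non_trivial_label_space(build_vocabulary(k)), 9L)
  }
})

test_that("vocabulary and token-line serialization round trip", {
  v <- build_vocabulary(3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_vocabulary(v, tsv)
  v2 <- read_vocabulary(tsv)
  expect_identical(v2$tokens, v$tokens)
  lines <- withr::local_tempfile(fileext = ".txt")
  ts_list <- list(tokenize("ACGTACG", v), tokenize("GGGTTT", v, FALSE))
  write_token_lines(ts_list, lines)
  back <- read_token_lines(lines, v)
  expect_identical(back[[1]]$ids, ts_list[[1]]$ids)
  expect_identical(back[[2]]$ids, ts_list[[2]]$ids)
  expect_identical(back[[1]]$source, "ACGTACG")
})
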