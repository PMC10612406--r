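test_that("order-0 background matches requested composition", {
  bg <- background_model(0)
  s <- generate_background(bg, 100000, seed = 1)
  freqs <- table(strsplit(s, "")[[1]]) / 100000
  expect_true(all(abs(freqs - 0.25) < 0.01))
  expect_identical(generate_background(bg, 500, seed = 9),
                   generate_background(bg, 500, seed = 9))
  skewed <- background_model(0, c(0.7, 0.1, 0.1, 0.1))
  s2 <- generate_background(skewed, 50000, seed = 2)
  expect_true(abs(mean(strsplit(s2, "")[[1]] == "A") - 0.7) < 0.01)
  expect_error(background_model(0, c(0.5, 0.5, 0.5, 0.5)), "sum")
})

test_that("order-1 degenerate chain repeats its forced state", {
  P <- matrix(0, 4, 4); P[, 1] <- 1  # every state -> A
  bg <- background_model(1, P, initial = c(1, 0, 0, 0))
  expect_identical(generate_background(bg, 8, seed = 1), "AAAAAAAA")
})

test_that("order-1 empirical transitions converge to the specified matrix", {
  bg <- default_markov_model()
  s <- generate_background(bg, 100000, seed = 3)
  emp <- empirical_transitions(s)
  expect_lt(max(abs(emp - bg$composition)), 0.02)
})

test_that("PWM sampling respects column distributions", {
  one_hot <- consensus_pwm("TTTTTT", noise = 0)
  for (i in 1:5) expect_identical(sample_pwm_instance(one_hot, seed = i),
                                  "TTTTTT")
  tata <- tata_pwm()
  expect_identical(pwm_consensus(tata), "TATAAA")
  draws <- vapply(1:400, function(i) sample_pwm_instance(tata, seed = i),
                  character(1))
  expect_identical(names(which.max(table(draws))), "TATAAA")  # modal sample
  # uniform PWM: all bases near-equiprobable per column
  unif <- pwm_motif("u", matrix(0.25, 4, 4))
  draws2 <- vapply(1:2000, function(i) sample_pwm_instance(unif, seed = i),
                   character(1))
  counts <- table(substr(draws2, 1, 1))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
  expect_error(pwm_motif("bad", matrix(0.3, 4, 4)), "sum to 1")
})

test_that("dinucleotide shuffle preserves exact dinucleotide counts (oracle)", {
  set.seed(7)
  for (i in 1:60) {
    L <- sample(5:120, 1)
    s <- generate_background(background_model(0), L, seed = i)
    sh <- dinucleotide_shuffle(s, seed = i + 5000)
    expect_identical(dinucleotide_counts(sh), dinucleotide_counts(s))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
    expect_identical(substr(sh, L, L), substr(s, L, L))
  }
  expect_identical(dinucleotide_shuffle("ACACAC", seed = 1) |>
                     dinucleotide_counts() |>
                     (\(x) x[x > 0])(),
                   c(AC = 3L, CA = 2L))
  sh <- dinucleotide_shuffle("AATT", seed = 2)
  expect_identical(substr(sh, 1, 1), "A")
  expect_identical(substr(sh, 4, 4), "T")
  expect_identical(dinucleotide_shuffle("ACGCGATTAC", seed = 3),
                   dinucleotide_shuffle("ACGCGATTAC", seed = 3))
})

test_that("motif discovery dataset implants motifs and pairs shuffles", {
  motif <- consensus_pwm("TTTTTT", noise = 0)
  ds <- make_motif_discovery_dataset(motif, background_model(0), n = 200,
                                     L = 101, seed = 21)
  rec <- ds$records
  expect_identical(nrow(rec), 200L)
  expect_identical(sum(rec$label == 1), 100L)
  pos <- rec$sequence[rec$label == 1]
  neg <- rec$sequence[rec$label == 0]
  expect_true(all(grepl("TTTTTT", pos, fixed = TRUE)))
  for (i in seq_along(pos)) {
    expect_identical(dinucleotide_counts(neg[i]), dinucleotide_counts(pos[i]))
  }
  expect_identical(as.integer(table(rec$split)[c("train", "dev", "test")]),
                   c(160L, 20L, 20L))
  expect_error(make_motif_discovery_dataset(motif, background_model(0),
                                            n = 10, L = 5), "exceed")
})

test_that("motif occupancy dataset matches GC and motif strength", {
  motif <- consensus_pwm("TATAAACG", noise = 0.05)
  ds <- make_motif_occupancy_dataset(motif, background_model(0), n = 60,
                                     L = 101, seed = 31)
  rec <- ds$records
  expect_identical(sum(rec$label == 1), 30L)
  pos <- rec$sequence[rec$label == 1]
  neg <- rec$sequence[rec$label == 0]
  gc <- function(x) mean(strsplit(x, "")[[1]] %in% c("G", "C"))
  center <- (101 - 8) %/% 2 + 1
  for (i in seq_along(pos)) {
    expect_lte(abs(gc(pos[i]) - gc(neg[i])), 0.02 + 1e-9)
    # centered implant: motif-strength score at the centre within tolerance
    ps <- pwm_score(motif, substr(pos[i], center, center + 7))
    ns <- pwm_score(motif, substr(neg[i], center, center + 7))
    expect_lte(abs(ps - ns), 1.0 + 1e-9)
  }
})

test_that("tata promoter dataset places motif canonically in positives only", {
  ds <- make_promoter_dataset(tata_pwm(), background_model(0), n = 60,
                              L = 300, variant = "tata", seed = 41)
  rec <- ds$records
  expect_true(all(nchar(rec$sequence) == 300))
  canonical <- 250 - 30  # 1-based motif start
  pos <- rec$sequence[rec$label == 1]
  neg <- rec$sequence[rec$label == 0]
  tata <- tata_pwm()
  # every positive has a high-scoring instance exactly at the canonical slot
  pos_scores <- vapply(pos, function(s) {
    pwm_score(tata, substr(s, canonical, canonical + 5))
  }, numeric(1))
  bg_scores <- vapply(neg, function(s) {
    pwm_score(tata, substr(s, canonical, canonical + 5))
  }, numeric(1))
  expect_gt(mean(pos_scores), mean(bg_scores) + 2)
  # both classes contain an implanted instance somewhere (motif presence
  # alone cannot classify); compare each sequence's best-window score to a
  # pure background reference
  best_score <- function(s) {
    max(vapply(1:295, function(i) {
      pwm_score(tata, substr(s, i, i + 5))
    }, numeric(1)))
  }
  ref <- vapply(1:30, function(i) {
    best_score(generate_background(background_model(0), 300, seed = 7000 + i))
  }, numeric(1))
  neg_best <- vapply(neg, best_score, numeric(1))
  expect_gt(mean(neg_best), mean(ref))  # negatives carry an implant too
})

test_that("nontata promoter negatives differ only in substituted segments", {
  ds <- make_promoter_dataset(NULL, background_model(0), n = 20, L = 300,
                              variant = "nontata", seed = 51)
  rec <- ds$records
  pos <- rec$sequence[rec$label == 1]
  neg <- rec$sequence[rec$label == 0]
  seg <- function(s, j) substr(s, (j - 1) * 15 + 1, j * 15)
  for (i in seq_along(pos)) {
    same <- vapply(1:20, function(j) {
      identical(seg(pos[i], j), seg(neg[i], j))
    }, logical(1))
    expect_identical(sum(!same), 12L)  # exactly 12 of 20 segments replaced
  }
  # GC-biased positives vs uniform substitutions
  gc <- function(x) mean(strsplit(x, "")[[1]] %in% c("G", "C"))
  expect_gt(mean(vapply(pos, gc, numeric(1))), 0.55)
})

test_that("split_dataset honors ratio, stratification and determinism", {
  motif <- consensus_pwm("TTTTTT", noise = 0)
  ds <- make_motif_discovery_dataset(motif, background_model(0), n = 100,
                                     L = 51, seed = 61)
  ds2 <- split_dataset(ds, c(0.8, 0.1, 0.1), seed = 5)
  expect_identical(as.integer(table(ds2$records$split)[c("train", "dev", "test")]),
                   c(80L, 10L, 10L))
  tb <- table(ds2$records$split, ds2$records$label)
  expect_true(all(tb[, "0"] == tb[, "1"]))  # stratified balance
  ds3 <- split_dataset(ds, c(0.8, 0.1, 0.1), seed = 5)
  expect_identical(ds2$records$split, ds3$records$split)
  expect_error(split_dataset(ds, c(0.6, 0.2, 0.1)), "sum")
})

test_that("dataset TSV and FASTA round trips", {
  motif <- consensus_pwm("TTTTTT", noise = 0)
  ds <- make_motif_discovery_dataset(motif, background_model(0), n = 20,
                                     L = 51, seed = 71)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_dataset_tsv(ds, tsv)
  back <- read_dataset_tsv(tsv, task = "motif_discovery")
  expect_identical(back$records$sequence, ds$records$sequence)
  expect_identical(back$records$label, ds$records$label)
  expect_identical(back$records$split, ds$records$split)
  fa <- withr::local_tempfile(fileext = ".fa")
  seqs <- c(a = "ACGT", b = "GGGTTTAA")
  write_fasta(seqs, fa)
  expect_identical(read_fasta(fa), seqs)
})

test_that("generators are bit-reproducible given (config, seed)", {
  motif <- consensus_pwm("GATTACAG", noise = 0.02)
  a <- make_motif_discovery_dataset(motif, background_model(0), n = 30,
                                    L = 101, seed = 77)
  b <- make_motif_discovery_dataset(motif, background_model(0), n = 30,
                                    L = 101, seed = 77)
  expect_identical(a$records, b$records)
  p1 <- make_promoter_dataset(tata_pwm(), background_model(0), 10, 300,
                              "tata", seed = 8)
  p2 <- make_promoter_dataset(tata_pwm(), background_model(0), 10, 300,
                              "tata", seed = 8)
  expect_identical(p1$records, p2$records)
})
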