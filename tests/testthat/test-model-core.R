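test_that("model config validates divisibility and ranges", {
  expect_error(model_config(hidden = 65, heads = 4), "divisible")
  expect_s3_class(mini_model_config(), "model_config")
  cfg <- model_config(k = 5)
  expect_identical(cfg$vocab_size, 1029L)
})

test_that("parameter accounting matches the closed form and the shape walk", {
  cfg <- model_config(k = 5, hidden = 768, layers = 12, heads = 12,
                      ffn = 3072, max_positions = 512, type_vocab = 2)
  pc <- count_parameters(cfg)
  expect_identical(pc$encoding_params, 85054464)
  expect_true(abs(pc$fraction_encoding - 0.986) < 0.001)
  mini <- mini_model_config(k = 3)
  walk <- count_parameters_walk(build_model(mini))
  closed <- count_parameters(mini)
  expect_identical(walk$embedding_params, closed$embedding_params)
  expect_identical(walk$encoding_params, closed$encoding_params)
  expect_identical(walk$head_params, closed$head_params)
})

test_that("closed form equals shape walk over random configs (property)", {
  set.seed(33)
  for (i in 1:12) {
    heads <- sample(c(1L, 2L, 4L), 1)
    cfg <- model_config(k = sample(1:4, 1), hidden = heads * sample(2:8, 1),
                        layers = sample(1:3, 1), heads = heads,
                        ffn = sample(c(16L, 32L, 64L), 1),
                        max_positions = 64L,
                        type_vocab = sample(1:2, 1), seed = i)
    walk <- count_parameters_walk(build_model(cfg))
    closed <- count_parameters(cfg)
    expect_identical(walk$embedding_params, closed$embedding_params)
    expect_identical(walk$encoding_params, closed$encoding_params)
    expect_identical(walk$head_params, closed$head_params)
  }
})

test_that("build_model is deterministic given the seed", {
  cfg <- mini_model_config(k = 2, seed = 12)
  m1 <- build_model(cfg); m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(mini_model_config(k = 2, seed = 13))
  expect_false(identical(m1$params$emb.tok, m3$params$emb.tok))
})

test_that("forward pass runs on a batch of tokenized strings", {
  m <- build_model(mini_model_config(k = 3, seed = 2))
  ids <- rbind(tokenize("ACGTACGTACGT", m$vocab)$ids,
               tokenize("GGGTTTAAACCC", m$vocab)$ids)
  fw <- forward_transformer(m, ids)
  expect_identical(dim(fw$X), c(2L * ncol(ids), 64L))
  expect_true(all(is.finite(fw$X)))
})

test_that("reinitialize_module touches exactly the named partition", {
  m <- build_model(mini_model_config(k = 2, seed = 3))
  enc <- reinitialize_module(m, "encoding", seed = 99)
  expect_identical(enc$params$emb.tok, m$params$emb.tok)   # embeddings kept
  expect_identical(enc$params$head.W, m$params$head.W)
  expect_false(identical(enc$params$enc.L1.Wq, m$params$enc.L1.Wq))
  emb <- reinitialize_module(m, "embedding", seed = 99)
  expect_identical(emb$params$enc.L1.Wq, m$params$enc.L1.Wq)
  expect_false(identical(emb$params$emb.tok, m$params$emb.tok))
  allr <- reinitialize_module(m, "all", seed = 99)
  ref <- build_model(mini_model_config(k = 2, seed = 99))
  expect_identical(allr$params, ref$params)
  expect_error(reinitialize_module(m, "heads"), "arg")
})

test_that("knockout then extraction returns the pre-ablation table", {
  m <- fixture_untrained_k3()
  before <- extract_token_embeddings(m)
  after <- extract_token_embeddings(reinitialize_module(m, "encoding", 5))
  expect_identical(after$matrix, before$matrix)
})

test_that("extract_token_embeddings labels rows by token", {
  m <- build_model(mini_model_config(k = 5, hidden = 16, heads = 2,
                                     ffn = 32, seed = 4))
  tab <- extract_token_embeddings(m, include_specials = TRUE)
  expect_identical(dim(tab$matrix), c(1029L, 16L))
  tab2 <- extract_token_embeddings(m)
  expect_identical(nrow(tab2$matrix), 1024L)
  expect_same_vector(tab2$matrix["AAAAA", ],
                     m$params$emb.tok[m$vocab$index["AAAAA"] + 1L, ])
})

test_that("mlm_loss is near ln(vocab) at init and masked-only", {
  m <- build_model(mini_model_config(k = 5, hidden = 16, heads = 2,
                                     ffn = 32, max_positions = 64, seed = 8))
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  ts <- tokenize(s, m$vocab)
  plan <- mask_contiguous(ts, 0.15, rng_seed = 3,
                          action_probs = c(mask = 1, random = 0, keep = 0))
  res <- mlm_loss(m, ts, plan)
  expect_lt(abs(res$loss - log(1029)), 0.3)
  expect_length(res$predictions, length(plan$masked_pos))
  # head bias fully toward the true token drives the loss toward zero
  s_aa <- paste(rep("A", 40), collapse = "")   # every token is AAAAA
  ts_aa <- tokenize(s_aa, m$vocab)
  plan_aa <- mask_contiguous(ts_aa, 0.15, rng_seed = 4,
                             action_probs = c(mask = 1, random = 0, keep = 0))
  m2 <- m
  m2$params$head.W[] <- 0
  m2$params$head.b[] <- -50
  m2$params$head.b[m$vocab$index["AAAAA"] + 1L] <- 50
  res2 <- mlm_loss(m2, ts_aa, plan_aa)
  expect_lt(res2$loss, 1e-6)
  expect_true(all(res2$predictions == m$vocab$index["AAAAA"]))
  expect_error(mlm_loss(m, ts, manual_plan(ts, integer(0), integer(0))),
               "masks no positions")
})

test_that("analytic gradients match finite differences", {
  cfg <- mini_model_config(k = 2, hidden = 8, layers = 2, heads = 2,
                           ffn = 16, max_positions = 32, seed = 5)
  m <- build_model(cfg)
  set.seed(1)
  ids <- matrix(sample(0:20, 2 * 10, TRUE), 2, 10)
  batch <- list(ids = ids, predict_pos = c(3L, 8L, 15L),
                target_ids = c(7L, 9L, 12L))
  sg <- mlm_step_grads(m, batch)
  eps <- 1e-5
  for (nm in c("emb.tok", "emb.pos", "enc.L1.Wq", "enc.L1.ln1.g",
               "enc.L2.W2", "enc.L2.bo", "head.W")) {
    p0 <- m$params[[nm]]
    for (trial in 1:3) {
      i <- sample(length(p0), 1)
      mp <- m; mp$params[[nm]][i] <- p0[i] + eps
      mm <- m; mm$params[[nm]][i] <- p0[i] - eps
      fd <- (mlm_step_grads(mp, batch)$loss -
               mlm_step_grads(mm, batch)$loss) / (2 * eps)
      an <- sg$grads[[nm]][i]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-3,
                label = sprintf("grad of %s[%d]", nm, i))
    }
  }
})

test_that("checkpoints round trip and reject shape mismatches", {
  m <- build_model(mini_model_config(k = 2, hidden = 16, heads = 2,
                                     ffn = 32, seed = 6))
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$params, m$params)
  expect_identical(m2$config$k, m$config$k)
  expect_identical(m2$provenance$seed, m$provenance$seed)  # config echo
  # tamper: claim a different k
  obj <- readRDS(path)
  obj$config$k <- 3L
  saveRDS(obj, path)
  expect_error(load_model(path), "shape mismatch")
})

test_that("forward is equivariant under consistent vocabulary relabeling", {
  cfg <- mini_model_config(k = 1, hidden = 8, layers = 1, heads = 2,
                           ffn = 16, max_positions = 16, seed = 9)
  m <- build_model(cfg)
  V <- cfg$vocab_size
  set.seed(2)
  perm <- sample(V)  # new id p gets old id perm[p]
  m2 <- m
  m2$params$emb.tok <- m$params$emb.tok[perm, , drop = FALSE]
  m2$params$head.W <- m$params$head.W[, perm, drop = FALSE]
  m2$params$head.b <- m$params$head.b[perm]
  ids_old <- matrix(c(5L, 6L, 7L, 8L, 5L), 1)
  ids_new <- matrix(match(ids_old + 1L, perm) - 1L, 1)
  fw1 <- mlm_head_fwd_bwd(m, forward_transformer(m, ids_old)$X, 2L,
                          ids_old[2], want_grad = FALSE)
  fw2 <- mlm_head_fwd_bwd(m2, forward_transformer(m2, ids_new)$X, 2L,
                          ids_new[2], want_grad = FALSE)
  expect_equal(fw1$loss, fw2$loss, tolerance = 1e-10)
})
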