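# Shared fixtures. Expensive trained models are built once per test run and
# cached in this environment so acceptance and property tests can share them.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# Uniform random corpus shared across pre-training fixtures
fixture_random_corpus <- function() {
  cached("random_corpus", {
    generate_corpus(background_model(0), 400L, 500L, seed = 20260910L)
  })
}

fixture_markov_corpus <- function() {
  cached("markov_corpus", {
    generate_corpus(default_markov_model(), 400L, 500L, seed = 20260911L)
  })
}

# Mini k=3 model pre-trained on uniform random text: the central fixture for
# the overlap-consistency analyses (acceptance criterion on emergence) and
# for the model-extracted embedding arm of the downstream comparison.
fixture_trained_k3 <- function() {
  cached("trained_k3", {
    state <- build_model(mini_model_config(k = 3L, seed = 7L))
    pretrain(state, fixture_random_corpus(),
             mask_cfg = list(rate = 0.15),
             opt_cfg = list(steps = 5000L, eval_every = 250L, batch = 16L,
                            window_tokens = 32L, lr = 3e-3),
             seed = 42L)
  })
}

fixture_untrained_k3 <- function() {
  cached("untrained_k3", build_model(mini_model_config(k = 3L, seed = 7L)))
}

# 1-mer mini model pre-trained on uniform random text (entropy-floor runs)
fixture_trained_k1 <- function() {
  cached("trained_k1", {
    state <- build_model(mini_model_config(k = 1L, seed = 3L))
    # eval_every 25 gives the exponential smoother (alpha = 0.1) enough
    # updates to reflect the plateau it is estimating
    pretrain(state, fixture_random_corpus(),
             mask_cfg = list(rate = 0.15),
             opt_cfg = list(steps = 1200L, eval_every = 25L, batch = 8L,
                            window_tokens = 48L, lr = 3e-3),
             seed = 11L)
  })
}

# Strongly separable motif-discovery dataset (one shared instance)
fixture_discovery_ds <- function(n = 2000L, seed = 404L) {
  key <- sprintf("discovery_%d_%d", n, seed)
  cached(key, {
    make_motif_discovery_dataset(consensus_pwm("GATTACAG", noise = 0.02),
                                 background_model(0), n = n, L = 101L,
                                 seed = seed)
  })
}

# Tiny deterministic embedding table fixture
fixture_block_table <- function(k = 3L) {
  # each k-mer's vector is the concatenation of 4*k position-specific
  # one-hot indicator blocks: known overlap geometry (shared prefixes or
  # suffixes => shared blocks => high cosine similarity)
  kmers <- all_kmers(k)
  M <- matrix(0, length(kmers), 4L * k)
  for (i in seq_along(kmers)) {
    chars <- strsplit(kmers[i], "")[[1]]
    for (j in seq_len(k)) {
      M[i, (j - 1L) * 4L + match(chars[j], c("A", "C", "G", "T"))] <- 1
    }
  }
  embedding_table(kmers, M, source = "external")
}

expect_same_vector <- function(a, b, tol = 1e-12) {
  expect_true(max(abs(a - b)) <= tol)
}
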