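#' Contiguous-k masking plans
#'
#' For overlapping k-mer tokens, masking a single token is trivially
#' recoverable from its unmasked neighbours (they share `k - 1` characters).
#' The masking scheme therefore masks runs of exactly `k` contiguous tokens,
#' leaving only one nucleotide per isolated run non-deducible.
#'
#' Runs are placed by rejection sampling of non-overlapping start positions
#' uniformly over the interior tokens; special tokens are never masked. Each
#' masked position gets a BERT-style replacement action: `mask` (replace by
#' `[MASK]`), `random` (replace by a random k-mer) or `keep` (leave as is),
#' with configurable probabilities (default 80/10/10).
#'
#' @param ts A [tokenize()] result with at least `k` interior tokens.
#' @param rate Target masked fraction of interior tokens, in (0, 1).
#' @param rng_seed Integer seed; plans are deterministic given the seed.
#' @param action_probs Named numeric vector of probabilities for
#'   `c(mask=, random=, keep=)`; must sum to 1. Set `c(mask=1, random=0,
#'   keep=0)` for pure-`[MASK]` masking.
#' @return An object of class `masking_plan`: `runs` (data.frame of 1-based
#'   interior `start` and `length`), `masked_pos` (1-based interior token
#'   indices), `actions` (per masked position), `target_rate`,
#'   `achieved_rate`, `seed`, `k`.
#' @export
mask_contiguous <- function(ts, rate, rng_seed,
                            action_probs = c(mask = 0.8, random = 0.1, keep = 0.1)) {
  stopifnot(inherits(ts, "token_seq"))
  k <- ts$vocab$k
  n <- n_interior(ts)
  if (n < k) stop_param("need at least k = %d interior tokens, got %d", k, n)
  if (!is.numeric(rate) || rate <= 0 || rate >= 1) {
    stop_param("rate must be in (0, 1)")
  }
  if (abs(sum(action_probs) - 1) > 1e-9 ||
      !all(c("mask", "random", "keep") %in% names(action_probs))) {
    stop_param("action_probs must be named mask/random/keep and sum to 1")
  }
  n_runs_target <- max(1L, as.integer(round(rate * n / k)))
  local_seed(rng_seed, {
    starts <- integer(0)
    occupied <- logical(n)
    max_start <- n - k + 1L
    attempts <- 0L
    while (length(starts) < n_runs_target && attempts < 200L * n_runs_target) {
      cand <- sample.int(max_start, 1L)
      span <- cand:(cand + k - 1L)
      if (!any(occupied[span])) {
        starts <- c(starts, cand)
        occupied[span] <- TRUE
      }
      attempts <- attempts + 1L
    }
    starts <- sort(starts)
    masked_pos <- as.integer(unlist(lapply(starts, function(s) s:(s + k - 1L))))
    actions <- sample(names(action_probs), length(masked_pos),
                      replace = TRUE, prob = action_probs)
    structure(
      list(runs = data.frame(start = starts, length = rep(k, length(starts))),
           masked_pos = masked_pos, actions = actions,
           target_rate = rate, achieved_rate = length(masked_pos) / n,
           seed = as.integer(rng_seed), k = k),
      class = "masking_plan"
    )
  })
}

#' @export
print.masking_plan <- function(x, ...) {
  cat(sprintf("<masking_plan> %d runs of %d, %d masked (rate %.3f, target %.3f)\n",
              nrow(x$runs), x$k, length(x$masked_pos),
              x$achieved_rate, x$target_rate))
  invisible(x)
}

#' Construct a masking plan from explicit runs
#'
#' Used for boundary-truncated runs and hand-crafted evaluation plans; run
#' spans are clipped to the interior token range.
#' @param ts A `token_seq`.
#' @param starts 1-based interior token start indices.
#' @param lengths Run lengths (recycled).
#' @param action Single action applied to every masked position.
#' @return A `masking_plan`.
#' @export
manual_plan <- function(ts, starts, lengths, action = "mask") {
  k <- ts$vocab$k
  n <- n_interior(ts)
  lengths <- rep_len(lengths, length(starts))
  pos <- unlist(mapply(function(s, l) {
    span <- s:(s + l - 1L)
    span[span >= 1L & span <= n]
  }, starts, lengths, SIMPLIFY = FALSE))
  pos <- sort(unique(as.integer(pos)))
  structure(
    list(runs = data.frame(start = pmax(1L, as.integer(starts)),
                           length = as.integer(lengths)),
         masked_pos = pos, actions = rep(action, length(pos)),
         target_rate = length(pos) / n, achieved_rate = length(pos) / n,
         seed = NA_integer_, k = k),
    class = "masking_plan"
  )
}

#' Apply a masking plan to token ids
#'
#' Returns the corrupted id vector the model sees as input (full `ts$ids`
#' layout including specials) and the 1-based positions (in that layout) to
#' be predicted.
#' @noRd
apply_plan <- function(ts, plan) {
  ids <- ts$ids
  off <- interior_offset(ts)
  vocab <- ts$vocab
  pos_full <- plan$masked_pos + off
  mask_id <- vocab_id(vocab, "[MASK]")
  nk <- 4^vocab$k
  for (j in seq_along(pos_full)) {
    a <- plan$actions[j]
    if (a == "mask") {
      ids[pos_full[j]] <- mask_id
    } else if (a == "random") {
      ids[pos_full[j]] <- 4L + sample.int(nk, 1L)  # random k-mer id (0-based 5..)
    } # keep: unchanged
  }
  list(input_ids = ids, predict_pos = pos_full, target_ids = ts$ids[pos_full])
}

#' Nucleotide-level inferability of a masking plan
#'
#' Classifies every nucleotide of the source string as `observed` (covered by
#' at least one unmasked interior token), `deducible` (covered only by masked
#' tokens but forced to a single value by propagating the overlap
#' constraints), or `free` (more than one consistent value). For an isolated
#' interior run of `k` masked tokens exactly one position is free.
#'
#' @param ts A [tokenize()] result carrying its `source` string.
#' @param plan A [mask_contiguous()] or [manual_plan()] result for `ts`.
#' @return An object of class `inferability_report`: `status` (factor over
#'   source positions), `count_free`, and `free_pos`.
#' @export
analyze_inferability <- function(ts, plan) {
  stopifnot(inherits(ts, "token_seq"), inherits(plan, "masking_plan"))
  if (is.null(ts$source)) stop_param("token sequence has no source string")
  k <- ts$vocab$k
  L <- nchar(ts$source)
  n <- n_interior(ts)
  if (length(plan$masked_pos) > 0 &&
      (min(plan$masked_pos) < 1L || max(plan$masked_pos) > n)) {
    stop_param("plan refers to token positions outside 1..%d", n)
  }
  masked <- logical(n)
  masked[plan$masked_pos] <- TRUE

  # Each source position p is one variable; token i (unmasked) fixes
  # positions i..i+k-1. Positions fixed by no unmasked token keep all 4
  # candidate values: the overlap constraints between masked tokens only
  # equate a position with itself, so propagation cannot shrink them further.
  n_candidates <- rep.int(4L, L)
  for (i in which(!masked)) n_candidates[i:(i + k - 1L)] <- 1L

  covered_unmasked <- rep.int(FALSE, L)
  for (i in which(!masked)) covered_unmasked[i:(i + k - 1L)] <- TRUE

  status <- ifelse(covered_unmasked, "observed",
                   ifelse(n_candidates == 1L, "deducible", "free"))
  status <- factor(status, levels = c("observed", "deducible", "free"))
  free_pos <- which(status == "free")
  structure(
    list(status = status, count_free = length(free_pos), free_pos = free_pos),
    class = "inferability_report"
  )
}

#' @export
print.inferability_report <- function(x, ...) {
  tb <- table(x$status)
  cat(sprintf("<inferability_report> observed=%d deducible=%d free=%d\n",
              tb["observed"], tb["deducible"], tb["free"]))
  invisible(x)
}
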