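#' Labeled sequence sets
#'
#' Fixed-length synthetic sequences with binary labels and train/dev/test
#' splits, the input format of the downstream classifiers.
#'
#' @param task One of `promoter_tata`, `promoter_nontata`, `motif_discovery`,
#'   `motif_occupancy`.
#' @param records data.frame with columns `id`, `sequence`, `label` (0/1),
#'   `split` (train/dev/test).
#' @param length Common sequence length L.
#' @param provenance List echoing the generator configuration.
#' @return An object of class `labeled_seqset`.
#' @export
labeled_seqset <- function(task, records, length, provenance = list()) {
  task <- match.arg(task, c("promoter_tata", "promoter_nontata",
                            "motif_discovery", "motif_occupancy"))
  stopifnot(all(c("id", "sequence", "label", "split") %in% names(records)))
  if (!all(nchar(records$sequence) == length)) {
    stop_param("all sequences must have length %d", length)
  }
  if (!all(records$label %in% c(0L, 1L))) stop_param("labels must be 0/1")
  structure(list(task = task, records = records, length = as.integer(length),
                 provenance = provenance),
            class = "labeled_seqset")
}

#' @export
print.labeled_seqset <- function(x, ...) {
  tb <- table(x$records$split, x$records$label)
  cat(sprintf("<labeled_seqset> task=%s, n=%d, L=%d\n",
              x$task, nrow(x$records), x$length))
  print(tb)
  invisible(x)
}

#' Assign train/dev/test splits
#'
#' Split sizes match the ratio up to rounding (largest-remainder); with
#' `stratified = TRUE` the ratio is applied within each label class.
#'
#' @param ds A `labeled_seqset`.
#' @param ratio Length-3 numeric (train, dev, test) summing to 1.
#' @param seed Integer seed (deterministic assignment).
#' @param stratified Stratify by label (default `TRUE`).
#' @return The dataset with its `split` column reassigned.
#' @export
split_dataset <- function(ds, ratio = c(0.8, 0.1, 0.1), seed = 1L,
                          stratified = TRUE) {
  stopifnot(inherits(ds, "labeled_seqset"))
  if (length(ratio) != 3 || abs(sum(ratio) - 1) > 1e-9) {
    stop_param("ratio must have 3 entries summing to 1")
  }
  rec <- ds$records
  assign_group <- function(idx, stream) {
    n <- length(idx)
    if (n == 0L) stop_param("empty class under stratification")
    sizes <- floor(ratio * n)
    rem <- n - sum(sizes)
    if (rem > 0) {
      frac <- ratio * n - sizes
      extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
      sizes[extra] <- sizes[extra] + 1L
    }
    perm <- local_seed(mix_seed(seed, stream), sample(idx))
    s <- character(n)
    s[match(perm, idx)] <- rep(c("train", "dev", "test"), sizes)
    s
  }
  if (stratified) {
    for (lab in unique(rec$label)) {
      idx <- which(rec$label == lab)
      rec$split[idx] <- assign_group(idx, stream = lab + 1L)
    }
  } else {
    rec$split <- assign_group(seq_len(nrow(rec)), stream = 0L)
  }
  ds$records <- rec
  ds$provenance$split <- list(ratio = ratio, seed = seed,
                              stratified = stratified)
  ds
}

#' Motif discovery dataset (dinucleotide-shuffled negatives)
#'
#' Positives are background sequences with one PWM instance implanted;
#' negatives are dinucleotide-preserving shuffles of the paired positives,
#' so both classes share exact dinucleotide composition and the classifier
#' must detect the intact motif.
#'
#' @param motif A [pwm_motif()].
#' @param bg A [background_model()].
#' @param n Total number of records (even; n/2 per class).
#' @param L Sequence length (default 101, the TFBS window).
#' @param seed Integer seed.
#' @param centered Implant at the central position instead of uniformly at
#'   random (default `FALSE`).
#' @param ratio Train/dev/test ratio (default 80:10:10).
#' @return A `labeled_seqset` with task `motif_discovery`.
#' @export
make_motif_discovery_dataset <- function(motif, bg, n, L = 101L, seed = 1L,
                                         centered = FALSE,
                                         ratio = c(0.8, 0.1, 0.1)) {
  stopifnot(inherits(motif, "pwm_motif"), inherits(bg, "background_model"))
  if (n %% 2 != 0) stop_param("n must be even")
  w <- motif$width
  if (L <= w) stop_param("L (%d) must exceed motif width (%d)", L, w)
  npos <- n / 2
  pos <- character(npos); neg <- character(npos)
  for (i in seq_len(npos)) {
    s0 <- generate_background(bg, L, seed = mix_seed(seed, i))
    inst <- sample_pwm_instance(motif, seed = mix_seed(seed, i + npos))
    start <- if (centered) (L - w) %/% 2 + 1L else {
      local_seed(mix_seed(seed, i + 2L * npos), sample.int(L - w + 1L, 1L))
    }
    pos[i] <- implant(s0, inst, start)
    neg[i] <- dinucleotide_shuffle(pos[i], seed = mix_seed(seed, i + 3L * npos))
  }
  rec <- data.frame(
    id = sprintf("md_%04d_%s", seq_len(n), rep(c("pos", "neg"), each = npos)),
    sequence = c(pos, neg),
    label = rep(c(1L, 0L), each = npos),
    split = NA_character_, stringsAsFactors = FALSE
  )
  ds <- labeled_seqset("motif_discovery", rec, L,
                       provenance = list(motif = motif$name, n = n, L = L,
                                         seed = seed, centered = centered))
  split_dataset(ds, ratio, seed = mix_seed(seed, 999983L))
}

#' Motif occupancy dataset (GC- and strength-matched negatives)
#'
#' Positives carry a centered PWM instance. Each negative is a fresh
#' background string whose GC fraction is rejection-matched to its paired
#' positive within `gc_tol`, with a motif instance of matched PWM
#' log-likelihood (within `score_tol` nats) implanted at the center; class
#' labels therefore cannot be read off motif presence, size, GC or motif
#' strength.
#'
#' @inheritParams make_motif_discovery_dataset
#' @param gc_tol GC-fraction matching tolerance (default 0.02).
#' @param score_tol Motif-strength matching tolerance in nats (default 1.0).
#' @param max_attempts Rejection-sampling cap per record (default 1000).
#' @return A `labeled_seqset` with task `motif_occupancy`.
#' @export
make_motif_occupancy_dataset <- function(motif, bg, n, L = 101L, seed = 1L,
                                         gc_tol = 0.02, score_tol = 1.0,
                                         max_attempts = 1000L,
                                         ratio = c(0.8, 0.1, 0.1)) {
  stopifnot(inherits(motif, "pwm_motif"), inherits(bg, "background_model"))
  if (n %% 2 != 0) stop_param("n must be even")
  w <- motif$width
  if (L <= w) stop_param("L (%d) must exceed motif width (%d)", L, w)
  npos <- n / 2
  center <- (L - w) %/% 2 + 1L
  pos <- character(npos); neg <- character(npos)
  for (i in seq_len(npos)) {
    s0 <- generate_background(bg, L, seed = mix_seed(seed, i))
    inst <- sample_pwm_instance(motif, seed = mix_seed(seed, i + npos))
    pos[i] <- implant(s0, inst, center)
    target_gc <- gc_fraction(pos[i])
    target_score <- pwm_score(motif, inst)
    found <- FALSE
    for (att in seq_len(max_attempts)) {
      sub <- mix_seed(seed, i + 2L * npos + att * 7919L)
      cand <- generate_background(bg, L, seed = sub)
      cinst <- sample_pwm_instance(motif, seed = mix_seed(sub, att))
      cand <- implant(cand, cinst, center)
      if (abs(gc_fraction(cand) - target_gc) <= gc_tol &&
          abs(pwm_score(motif, cinst) - target_score) <= score_tol) {
        neg[i] <- cand
        found <- TRUE
        break
      }
    }
    if (!found) {
      stop_param("could not GC/strength-match negative for record %d after %d attempts",
                 i, max_attempts)
    }
  }
  rec <- data.frame(
    id = sprintf("mo_%04d_%s", seq_len(n), rep(c("pos", "neg"), each = npos)),
    sequence = c(pos, neg),
    label = rep(c(1L, 0L), each = npos),
    split = NA_character_, stringsAsFactors = FALSE
  )
  ds <- labeled_seqset("motif_occupancy", rec, L,
                       provenance = list(motif = motif$name, n = n, L = L,
                                         seed = seed, gc_tol = gc_tol,
                                         score_tol = score_tol))
  split_dataset(ds, ratio, seed = mix_seed(seed, 999983L))
}

#' Synthetic promoter datasets
#'
#' Emulates 300 bp promoter windows spanning -249..+50 around a transcription
#' start site (TSS at index 250 of the window).
#'
#' For the `tata` variant, positives implant the TATA PWM at the canonical
#' offset (motif start ~= TSS - 30, i.e. 1-based position 220 by default);
#' negatives are background strings carrying the same PWM at a uniformly
#' random *non-canonical* position, so motif presence alone cannot separate
#' the classes -- only its position can.
#'
#' For the `nontata` variant, positives are drawn from a GC-biased
#' "regulatory" background; negatives are derived from their paired positive
#' by cutting it into `n_segments` equal segments and replacing
#' `n_substituted` randomly chosen segments with fresh uniform background.
#'
#' @param tata_motif A [pwm_motif()] (used by the `tata` variant).
#' @param bg A [background_model()] for the bulk sequence.
#' @param n Total records (even).
#' @param L Window length (default 300).
#' @param variant `"tata"` or `"nontata"`.
#' @param seed Integer seed.
#' @param tss_offset 1-based TSS index in the window (default 250).
#' @param tata_offset Motif start relative to the TSS (default -30).
#' @param reg_gc GC content of the regulatory background for `nontata`
#'   positives (default 0.6).
#' @param n_segments,n_substituted Segmenting scheme for `nontata` negatives
#'   (defaults 20 and 12).
#' @param ratio Train/dev/test ratio.
#' @return A `labeled_seqset`.
#' @export
make_promoter_dataset <- function(tata_motif, bg, n, L = 300L,
                                  variant = c("tata", "nontata"), seed = 1L,
                                  tss_offset = 250L, tata_offset = -30L,
                                  reg_gc = 0.6, n_segments = 20L,
                                  n_substituted = 12L,
                                  ratio = c(0.8, 0.1, 0.1)) {
  variant <- match.arg(variant)
  stopifnot(inherits(bg, "background_model"))
  if (n %% 2 != 0) stop_param("n must be even")
  if (L < 300L) stop_param("L must be >= 300 (got %d)", L)
  npos <- n / 2
  pos <- character(npos); neg <- character(npos)
  if (variant == "tata") {
    stopifnot(inherits(tata_motif, "pwm_motif"))
    w <- tata_motif$width
    canonical <- tss_offset + tata_offset  # 1-based motif start
    if (canonical < 1L || canonical + w - 1L > L) {
      stop_param("canonical motif position out of window")
    }
    for (i in seq_len(npos)) {
      s0 <- generate_background(bg, L, seed = mix_seed(seed, i))
      inst <- sample_pwm_instance(tata_motif, seed = mix_seed(seed, i + npos))
      pos[i] <- implant(s0, inst, canonical)
      s1 <- generate_background(bg, L, seed = mix_seed(seed, i + 2L * npos))
      inst2 <- sample_pwm_instance(tata_motif,
                                   seed = mix_seed(seed, i + 3L * npos))
      start <- local_seed(mix_seed(seed, i + 4L * npos), {
        repeat {
          cand <- sample.int(L - w + 1L, 1L)
          if (cand != canonical) break
        }
        cand
      })
      neg[i] <- implant(s1, inst2, start)
    }
  } else {
    reg_bg <- background_model(0, c((1 - reg_gc) / 2, reg_gc / 2,
                                    reg_gc / 2, (1 - reg_gc) / 2))
    if (n_substituted > n_segments) {
      stop_param("n_substituted must be <= n_segments")
    }
    seg_bounds <- floor(seq(0, L, length.out = n_segments + 1L))
    for (i in seq_len(npos)) {
      pos[i] <- generate_background(reg_bg, L, seed = mix_seed(seed, i))
      chosen <- local_seed(mix_seed(seed, i + npos),
                           sort(sample.int(n_segments, n_substituted)))
      s <- pos[i]
      for (j in seq_along(chosen)) {
        a <- seg_bounds[chosen[j]] + 1L
        b <- seg_bounds[chosen[j] + 1L]
        repl <- generate_background(bg, b - a + 1L,
                                    seed = mix_seed(seed, i + (2L + j) * npos))
        s <- paste0(substr(s, 1, a - 1L), repl, substr(s, b + 1L, L))
      }
      neg[i] <- s
    }
  }
  rec <- data.frame(
    id = sprintf("pr_%04d_%s", seq_len(n), rep(c("pos", "neg"), each = npos)),
    sequence = c(pos, neg),
    label = rep(c(1L, 0L), each = npos),
    split = NA_character_, stringsAsFactors = FALSE
  )
  ds <- labeled_seqset(paste0("promoter_", variant), rec, L,
                       provenance = list(variant = variant, n = n, L = L,
                                         seed = seed,
                                         tss_offset = tss_offset,
                                         tata_offset = tata_offset))
  split_dataset(ds, ratio, seed = mix_seed(seed, 999983L))
}

#' Write / read labeled datasets as TSV (id, sequence, label, split)
#' @param ds A `labeled_seqset`.
#' @param path File path.
#' @param task Task tag used when reading.
#' @export
write_dataset_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "labeled_seqset"))
  data.table::fwrite(ds$records, path, sep = "\t")
  invisible(path)
}

#' @rdname write_dataset_tsv
#' @export
read_dataset_tsv <- function(path, task = "motif_discovery") {
  rec <- as.data.frame(data.table::fread(path, sep = "\t",
                                         colClasses = list(character = c("id", "sequence", "split"))))
  rec$label <- as.integer(rec$label)
  labeled_seqset(task, rec, nchar(rec$sequence[1]),
                 provenance = list(file = path))
}
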