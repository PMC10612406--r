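#' Position weight matrix motifs
#'
#' A PWM is a 4 x w column-stochastic matrix of per-position base
#' probabilities (rows in A,C,G,T order).
#'
#' @param name Motif name.
#' @param matrix 4 x w numeric matrix; columns must sum to 1.
#' @return An object of class `pwm_motif` with fields `name`, `width`,
#'   `matrix`.
#' @export
pwm_motif <- function(name, matrix) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 4) stop_param("PWM must have 4 rows (A,C,G,T)")
  if (ncol(matrix) < 4) stop_param("PWM width must be >= 4 (got %d)", ncol(matrix))
  if (any(matrix < 0) || any(abs(colSums(matrix) - 1) > 1e-9)) {
    stop_param("PWM columns must be non-negative and sum to 1")
  }
  rownames(matrix) <- DNA_BASES
  structure(list(name = name, width = ncol(matrix), matrix = matrix),
            class = "pwm_motif")
}

#' @export
print.pwm_motif <- function(x, ...) {
  cat(sprintf("<pwm_motif> '%s', width %d, consensus %s\n",
              x$name, x$width, pwm_consensus(x)))
  invisible(x)
}

#' Build a PWM from a consensus string
#'
#' Each column puts `1 - 3 * noise` on the consensus base and `noise` on the
#' others; `noise = 0` gives a deterministic (one-hot) motif.
#' @param consensus Nucleotide string (width >= 4).
#' @param noise Per-alternative-base probability, in `[0, 1/4)`.
#' @param name Motif name (defaults to the consensus).
#' @return A `pwm_motif`.
#' @export
consensus_pwm <- function(consensus, noise = 0, name = consensus) {
  chars <- check_dna(consensus, "consensus")
  if (noise < 0 || noise >= 0.25) stop_param("noise must be in [0, 0.25)")
  m <- matrix(noise, 4, length(chars))
  m[cbind(match(chars, DNA_BASES), seq_along(chars))] <- 1 - 3 * noise
  pwm_motif(name, m)
}

#' Canonical TATA-box-like PWM
#'
#' A TATAAA-consensus PWM (width 6) with mild positional degeneracy,
#' reflecting the canonical TATA element found ~30 bp upstream of
#' transcription start sites.
#' @return A `pwm_motif` of width 6.
#' @export
tata_pwm <- function() {
  #            T     A     T     A     A     A
  m <- matrix(c(0.04, 0.82, 0.04, 0.82, 0.70, 0.58,   # A
                0.04, 0.04, 0.04, 0.04, 0.06, 0.06,   # C
                0.04, 0.04, 0.04, 0.04, 0.06, 0.18,   # G
                0.88, 0.10, 0.88, 0.10, 0.18, 0.18),  # T
              nrow = 4, byrow = TRUE)
  pwm_motif("TATA-box", m)
}

#' Consensus (modal) string of a PWM
#' @param motif A `pwm_motif`.
#' @return Nucleotide string of length `width`.
#' @export
pwm_consensus <- function(motif) {
  paste(DNA_BASES[apply(motif$matrix, 2, which.max)], collapse = "")
}

#' Sample one motif instance from a PWM
#'
#' Column-independent sampling from the per-position base distributions.
#' @param motif A `pwm_motif`.
#' @param seed Optional integer seed.
#' @return Nucleotide string of length `width`.
#' @export
sample_pwm_instance <- function(motif, seed = NULL) {
  stopifnot(inherits(motif, "pwm_motif"))
  local_seed(seed, {
    paste(vapply(seq_len(motif$width), function(j) {
      sample(DNA_BASES, 1, prob = motif$matrix[, j])
    }, character(1)), collapse = "")
  })
}

#' PWM log-likelihood score of a motif-length string
#'
#' Sum over positions of `log` PWM probability (natural log; a pseudo
#' probability of 1e-9 guards zero entries).
#' @param motif A `pwm_motif`.
#' @param instance Nucleotide string of length `width`.
#' @return Log-likelihood in nats.
#' @export
pwm_score <- function(motif, instance) {
  chars <- check_dna(instance, "instance")
  if (length(chars) != motif$width) {
    stop_param("instance length %d != motif width %d", length(chars), motif$width)
  }
  p <- motif$matrix[cbind(match(chars, DNA_BASES), seq_along(chars))]
  sum(log(pmax(p, 1e-9)))
}

#' Implant a motif instance into a sequence
#' @noRd
implant <- function(seq, instance, start) {
  paste0(substr(seq, 1, start - 1L), instance,
         substr(seq, start + nchar(instance), nchar(seq)))
}

#' Count exact occurrences of a pattern in a sequence
#' @noRd
count_exact_hits <- function(seq, pattern) {
  m <- gregexpr(pattern, seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}
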