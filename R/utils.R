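#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library calls do not disturb the
#' caller's RNG stream.
#' @noRd
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a reproducible sub-seed from a base seed and a stream index
#'
#' Keeps derived seeds inside the 32-bit integer range.
#' @noRd
mix_seed <- function(seed, stream) {
  s <- (as.double(seed) * 2654435761 + as.double(stream) * 97531) %% 2147483629
  as.integer(s) + 1L
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

#' Validate a nucleotide string, reporting the first offending position
#' @noRd
check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L) {
    stop_param("%s must be a single character string", what)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% DNA_BASES))
  if (length(bad) > 0L) {
    stop_param("%s contains non-ACGT character '%s' at position %d",
               what, chars[bad[1]], bad[1])
  }
  invisible(chars)
}

#' Short stable hash of an R object (config provenance)
#' @noRd
config_hash <- function(x) substr(digest::digest(x, algo = "xxhash64"), 1, 12)

gc_fraction <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  mean(chars %in% c("G", "C"))
}
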