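# shared internal helpers

.datatable.aware <- TRUE

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so library calls never perturb
#' user-level randomness.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_invalid("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic, keeps results within 32-bit integer range.
#' @param master master seed (integer)
#' @param stage stage index or offset (integer)
#' @export
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 7919 + as.numeric(stage) * 104729) %% 2147483629)
}

stop_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("satkit_invalid_parameter", "satkit_error")))
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA sequences
#' @return character vector
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate random DNA of given length and A+T content
#' @noRd
random_dna <- function(n, at_content = 0.5) {
  p <- c(at_content / 2, (1 - at_content) / 2, (1 - at_content) / 2, at_content / 2)
  paste0(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Truncate (not round) a value to a number of decimals
#' @noRd
truncate_decimals <- function(x, digits) {
  trunc(x * 10^digits) / 10^digits
}

`%||%` <- function(a, b) if (is.null(a)) b else a
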