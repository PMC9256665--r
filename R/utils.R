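#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a stage seed from a global seed
#'
#' Deterministic stream splitting for pipeline stages: each (seed, index)
#' pair maps to a distinct seed below 2^31 so stages are reproducible
#' independently of how many random draws earlier stages consumed.
#'
#' @param seed integer global seed.
#' @param index non-negative integer stage index.
#' @return an integer seed in [0, 2^31).
#' @export
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) + 104729 * as.double(index)) %% 2147483647)
}

# Draw, for each ancestral base, one of the 3 alternative bases uniformly.
# `anc` is a character vector of single bases; returns same-length vector.
random_alt_base <- function(anc, n = length(anc)) {
  offset <- sample.int(3L, n, replace = TRUE)
  idx <- match(anc, DNA_BASES)
  DNA_BASES[((idx - 1L + offset) %% 4L) + 1L]
}

# Random ancestral sequence as a character vector of bases.
random_sequence <- function(L) {
  sample(DNA_BASES, L, replace = TRUE)
}

# collapse a base vector into a single string
seq_string <- function(x) paste(x, collapse = "")

stopf <- function(...) stop(sprintf(...), call. = FALSE)
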