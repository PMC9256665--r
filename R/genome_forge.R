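#' Inject divergence into an ancestral sequence (truth set D)
#'
#' Builds a diverged reference genome by mutating each non-excluded site
#' independently with probability \code{d}, placing a uniformly chosen
#' alternative base. This emulates a reference genome whose most recent
#' common ancestor with the simulated population lies at phylogenetic
#' distance d: the reference carries the mutant base while every
#' individual in the population carries the ancestral base, so a correct
#' caller reports a homozygous-alternative SNV at each D site in all
#' samples. By default D sites are drawn disjoint from the supplied
#' excluded positions (typically the P truth sites) so every called site
#' classifies unambiguously as TPP, TPD or FP.
#'
#' @param ancestral character vector of bases (the ancestral sequence).
#' @param d divergence fraction, per-site mutation probability in [0, 1).
#' @param excluded_positions integer vector of 0-based positions that must
#'   not be mutated (default none).
#' @param seed optional integer seed.
#' @param fixed_count if TRUE, place exactly \code{round(d * L_eligible)}
#'   mutations at distinct eligible sites instead of per-site Bernoulli
#'   draws (exact reproducibility of |D|).
#' @return an object of class \code{diverged_reference}: list with
#'   \code{sequence} (character vector of bases), \code{d_level}, and
#'   \code{truth_d}, a data.frame (class \code{truth_d}) with columns
#'   \code{pos} (0-based), \code{ancestral}, \code{ref_base},
#'   \code{d_level}.
#' @examples
#' anc <- rep(c("A", "C", "G", "T"), 25)
#' ref <- inject_divergence(anc, d = 0.1, seed = 1)
#' nrow(ref$truth_d)
#' @export
inject_divergence <- function(ancestral, d, excluded_positions = integer(0),
                              seed = NULL, fixed_count = FALSE) {
  if (d < 0 || d >= 1) stopf("d must be in [0, 1), got %g", d)
  L <- length(ancestral)
  if (!is.null(seed)) set.seed(seed)
  eligible <- rep(TRUE, L)
  if (length(excluded_positions) > 0L) eligible[excluded_positions + 1L] <- FALSE
  idx_el <- which(eligible)
  if (d == 0 || length(idx_el) == 0L) {
    pos <- integer(0)
  } else if (fixed_count) {
    k <- round(d * length(idx_el))
    pos <- sort.int(sample(idx_el, k)) - 1L
  } else {
    hit <- stats::runif(length(idx_el)) < d
    pos <- idx_el[hit] - 1L
  }
  sequence <- ancestral
  ref_base <- character(0)
  if (length(pos) > 0L) {
    ref_base <- random_alt_base(ancestral[pos + 1L])
    sequence[pos + 1L] <- ref_base
  }
  truth_d <- data.frame(pos = pos,
                        ancestral = if (length(pos)) ancestral[pos + 1L] else character(0),
                        ref_base = ref_base,
                        d_level = rep(d, length(pos)))
  class(truth_d) <- c("truth_d", "data.frame")
  structure(list(sequence = sequence, d_level = d, truth_d = truth_d),
            class = "diverged_reference")
}

#' @export
print.diverged_reference <- function(x, ...) {
  cat(sprintf("Diverged reference: L = %d bp, d = %g, |D| = %d sites\n",
              length(x$sequence), x$d_level, nrow(x$truth_d)))
  invisible(x)
}

#' Build per-individual diploid genome sequences
#'
#' Applies each sampled haplotype's mutation set to the ancestral sequence,
#' yielding two full-length sequences per individual (SNVs only, so length
#' is preserved).
#'
#' @param sample a \code{population_sample}.
#' @return a \code{\link[Biostrings]{DNAStringSet}} of 2*n_sample sequences
#'   named \code{ind<i>_hap<1|2>}.
#' @export
build_diploid_sequences <- function(sample) {
  stopifnot(inherits(sample, "population_sample"))
  L <- sample$L
  seqs <- lapply(sample$haps, function(h) {
    if (any(h >= L)) stopf("mutation position >= L")
    s <- sample$ancestral
    if (length(h) > 0L) s[h + 1L] <- sample$alt[h + 1L]
    seq_string(s)
  })
  n <- sample$n_sample
  names(seqs) <- paste0("ind", rep(seq_len(n), each = 2L), "_hap",
                        rep(1:2, n))
  Biostrings::DNAStringSet(unlist(seqs))
}

#' Write a diverged reference (or any sequence) as FASTA
#'
#' @param x a \code{diverged_reference}, a character vector of bases, or a
#'   \code{DNAStringSet}.
#' @param path output file path.
#' @param name sequence name for single-sequence inputs (default encodes
#'   the d level for diverged references).
#' @return the path, invisibly.
#' @export
write_fasta <- function(x, path, name = NULL) {
  if (inherits(x, "diverged_reference")) {
    if (is.null(name)) name <- sprintf("ref_d%g", x$d_level)
    x <- Biostrings::DNAStringSet(stats::setNames(seq_string(x$sequence), name))
  } else if (is.character(x)) {
    if (is.null(name)) name <- "seq"
    x <- Biostrings::DNAStringSet(stats::setNames(seq_string(x), name))
  }
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Read a single-sequence FASTA into a base vector
#'
#' @param path FASTA file path.
#' @return character vector of single bases.
#' @export
read_fasta_bases <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  strsplit(as.character(s[[1]]), "", fixed = TRUE)[[1]]
}
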