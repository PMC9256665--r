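#' Parameters for paired-end read simulation
#'
#' Defaults mirror a typical Illumina resequencing design: 150 bp reads,
#' 300 +/- 30 bp inserts, 20-fold coverage per diploid genome, a uniform
#' per-base substitution error rate and a constant Phred base quality.
#'
#' @param read_len read length in bp.
#' @param insert_mean mean fragment (insert) length in bp.
#' @param insert_sd fragment length standard deviation in bp.
#' @param coverage fold coverage per diploid genome.
#' @param error_rate per-base substitution probability in [0, 1).
#' @param base_qual constant Phred quality written for every base.
#' @param seed integer seed.
#' @return an object of class \code{read_sim_params}.
#' @export
read_sim_params <- function(read_len = 150L, insert_mean = 300, insert_sd = 30,
                            coverage = 20, error_rate = 1e-3, base_qual = 30L,
                            seed = 1L) {
  read_len <- as.integer(read_len)
  if (read_len < 1L) stopf("read_len must be >= 1")
  if (insert_mean < read_len) stopf("insert_mean must be >= read_len")
  if (coverage < 0) stopf("coverage must be >= 0")
  if (error_rate < 0 || error_rate >= 1) stopf("error_rate must be in [0, 1)")
  structure(list(read_len = read_len, insert_mean = insert_mean,
                 insert_sd = insert_sd, coverage = coverage,
                 error_rate = error_rate, base_qual = as.integer(base_qual),
                 seed = as.integer(seed)),
            class = "read_sim_params")
}

# substitute sequencing errors into a character vector of read strings
add_read_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0L) return(reads)
  rl <- nchar(reads[1])
  n_err <- stats::rbinom(length(reads), rl, error_rate)
  for (i in which(n_err > 0L)) {
    b <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    at <- sample.int(rl, n_err[i])
    b[at] <- random_alt_base(b[at])
    reads[i] <- paste(b, collapse = "")
  }
  reads
}

#' Simulate paired-end reads from a diploid genome
#'
#' Emits \code{round(coverage * L / (2 * read_len))} read pairs split evenly
#' between the two haplotypes (haplotype 1 receives the odd remainder).
#' Fragment starts are uniform; fragment lengths are Normal(insert_mean,
#' insert_sd) truncated to [read_len, L - start]. Mate 1 is the fragment's
#' leading bases; mate 2 is the reverse complement of its trailing bases.
#' Substitution errors are applied per base at \code{error_rate}, and read
#' names encode individual, haplotype, fragment index and mate.
#'
#' @param hap_pair the two haplotype sequences: a \code{DNAStringSet} of
#'   length 2, or a list/character vector of two sequence strings.
#' @param params a \code{read_sim_params}.
#' @param ind_id individual identifier used in read names.
#' @param seed optional seed (defaults to the seed in \code{params}).
#' @return list of class \code{read_pairs} with elements \code{r1},
#'   \code{r2} (named character vectors of read sequences), \code{qual}
#'   (constant Phred quality) and \code{frag} (data.frame with hap, start
#'   (0-based), length per fragment).
#' @export
simulate_read_pairs <- function(hap_pair, params, ind_id = "ind1",
                                seed = params$seed) {
  stopifnot(inherits(params, "read_sim_params"))
  if (inherits(hap_pair, "DNAStringSet")) hap_pair <- as.character(hap_pair)
  if (is.list(hap_pair)) hap_pair <- unlist(hap_pair)
  stopifnot(length(hap_pair) == 2L)
  L <- nchar(hap_pair[1])
  if (nchar(hap_pair[2]) != L) stopf("haplotype lengths differ")
  if (params$insert_mean > L) stopf("insert_mean exceeds sequence length")
  if (!is.null(seed)) set.seed(seed)
  rl <- params$read_len
  n_pairs <- round(params$coverage * L / (2 * rl))
  n1 <- ceiling(n_pairs / 2); n2 <- n_pairs - n1
  hap_of <- rep(1:2, c(n1, n2))
  start <- sample.int(L - rl + 1L, n_pairs, replace = TRUE) - 1L  # 0-based
  flen <- round(stats::rnorm(n_pairs, params$insert_mean, params$insert_sd))
  flen <- pmax(rl, pmin(flen, L - start))
  r1 <- substring(hap_pair[hap_of], start + 1L, start + rl)
  r2_fwd <- substring(hap_pair[hap_of], start + flen - rl + 1L, start + flen)
  r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(r2_fwd)))
  r1 <- add_read_errors(r1, params$error_rate)
  r2 <- add_read_errors(r2, params$error_rate)
  nm <- sprintf("%s_hap%d_frag%d", ind_id, hap_of, seq_len(n_pairs))
  names(r1) <- paste0(nm, "/1")
  names(r2) <- paste0(nm, "/2")
  structure(list(r1 = r1, r2 = r2, qual = params$base_qual,
                 frag = data.frame(hap = hap_of, start = start, length = flen)),
            class = "read_pairs")
}

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("%d read pairs, read length %d bp, mean insert %.1f bp\n",
              length(x$r1), nchar(x$r1[1]), mean(x$frag$length)))
  invisible(x)
}

#' Write simulated read pairs as a FASTQ file pair
#'
#' Standard 4-line FASTQ records with the constant base quality from the
#' simulation parameters.
#'
#' @param pairs a \code{read_pairs} object.
#' @param prefix output path prefix; writes \code{<prefix>_R1.fastq} and
#'   \code{<prefix>_R2.fastq}.
#' @param gzip compress output with gzip.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq_pair <- function(pairs, prefix, gzip = FALSE) {
  stopifnot(inherits(pairs, "read_pairs"))
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- paste0(prefix, c("_R1", "_R2"), ext)
  qc <- rawToChar(as.raw(pairs$qual + 33L))
  for (m in 1:2) {
    reads <- if (m == 1) pairs$r1 else pairs$r2
    qual <- strrep(qc, nchar(reads))
    rec <- as.vector(rbind(paste0("@", names(reads)), unname(reads),
                           "+", qual))
    con <- if (gzip) gzfile(paths[m], "w") else file(paths[m], "w")
    writeLines(rec, con)
    close(con)
  }
  invisible(paths)
}

#' Per-site depth profile of simulated fragments
#'
#' Coverage of the reference coordinate space by the sequenced portions of
#' each fragment (both mates), for checking the realised depth against the
#' target coverage.
#'
#' @param pairs a \code{read_pairs} object.
#' @param L genome length.
#' @param read_len read length used in the simulation.
#' @return numeric vector of per-site depths (length L).
#' @export
fragment_depth <- function(pairs, L, read_len) {
  fr <- pairs$frag
  m1 <- IRanges::IRanges(start = fr$start + 1L, width = read_len)
  m2 <- IRanges::IRanges(end = fr$start + fr$length, width = read_len)
  cov <- IRanges::coverage(c(m1, m2), width = L)
  as.numeric(cov)
}
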