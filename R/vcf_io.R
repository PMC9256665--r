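vcf_num <- function(x) {
  ifelse(is.na(x), ".", formatC(x, digits = 4, format = "f"))
}

#' Write a call set as a VCF 4.2 file
#'
#' Serializes an SNV call set with QUAL, the five annotation scores as
#' INFO keys (QD, FS, MQ, MQRankSum, ReadPosRankSum) and per-sample GT
#' fields.
#'
#' @param calls a \code{vcf_calls} data.frame.
#' @param path output path.
#' @param sample_names names for the genotype columns (default s1..sn).
#' @return the path, invisibly.
#' @export
write_calls_vcf <- function(calls, path, sample_names = NULL) {
  gt <- attr(calls, "gt")
  L <- attr(calls, "L")
  chrom <- if (nrow(calls) > 0L) calls$chrom[1] else "chr1"
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(L)) sprintf("##contig=<ID=%s,length=%d>", chrom, L),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum"),
            c("Variant quality by depth",
              "Phred-scaled strand bias",
              "RMS mapping quality",
              "Mapping quality rank-sum (ref vs alt)",
              "Read position rank-sum (ref vs alt)")),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(gt) && ncol(gt) > 0L) {
    if (is.null(sample_names)) sample_names <- paste0("s", seq_len(ncol(gt)))
    cols <- c(cols, "FORMAT", sample_names)
  }
  body <- character(0)
  if (nrow(calls) > 0L) {
    info <- sprintf("QD=%s;FS=%s;MQ=%s;MQRankSum=%s;ReadPosRankSum=%s",
                    vcf_num(calls$QD), vcf_num(calls$FS), vcf_num(calls$MQ),
                    vcf_num(calls$MQRankSum), vcf_num(calls$ReadPosRankSum))
    fields <- cbind(calls$chrom, calls$pos, ".", calls$ref, calls$alt,
                    vcf_num(calls$qual), ".", info)
    if (!is.null(gt) && ncol(gt) > 0L) fields <- cbind(fields, "GT", gt)
    body <- apply(fields, 1L, paste, collapse = "\t")
  }
  writeLines(c(hdr, paste(cols, collapse = "\t"), body), path)
  invisible(path)
}

#' Read an SNV call set from a VCF file
#'
#' Parses a VCF (e.g. from an external caller) into the internal call
#' table: multiallelic records are split into biallelic records, each
#' classified independently, and indel / non-SNV records are dropped with
#' a message reporting the count. The five annotation INFO keys are parsed
#' when present (NA otherwise).
#'
#' @param path VCF file path (plain or gzipped).
#' @return a data.frame of class \code{vcf_calls}.
#' @export
read_calls_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n <- nrow(fix)
  ann <- lapply(c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum"),
                function(k) {
                  x <- try(suppressWarnings(
                    vcfR::extract.info(v, element = k, as.numeric = TRUE)),
                    silent = TRUE)
                  if (inherits(x, "try-error") || is.null(x) || length(x) != n)
                    rep(NA_real_, n) else as.numeric(x)
                })
  names(ann) <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")
  qual <- suppressWarnings(as.numeric(fix$QUAL))
  gt <- NULL
  if (!is.null(v@gt) && ncol(v@gt) > 1L) {
    gt <- sub(":.*", "", v@gt[, -1L, drop = FALSE])
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = n)
  }
  # split multiallelic ALT
  alts <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep.int(seq_len(n), n_alt)
  calls <- data.frame(chrom = fix$CHROM[idx],
                      pos = as.integer(fix$POS[idx]),
                      ref = fix$REF[idx],
                      alt = unlist(alts),
                      qual = qual[idx])
  for (k in names(ann)) calls[[k]] <- ann[[k]][idx]
  if (!is.null(gt)) gt <- gt[idx, , drop = FALSE]
  snv <- nchar(calls$ref) == 1L & nchar(calls$alt) == 1L &
    calls$ref %in% DNA_BASES & calls$alt %in% DNA_BASES
  if (any(!snv))
    message(sum(!snv), " non-SNV record(s) dropped at ingestion")
  calls <- calls[snv, , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "gt") <- if (!is.null(gt)) gt[snv, , drop = FALSE] else NULL
  class(calls) <- c("vcf_calls", "data.frame")
  calls
}

#' Write the truth set P as TSV
#'
#' Columns: pos (0-based), ref, alt, allele_count, fixed.
#' @param truth a \code{truth_p} data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth_p_tsv <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth set P from TSV
#' @param path TSV path written by \code{\link{write_truth_p_tsv}}.
#' @return a \code{truth_p} data.frame (without the dosage attribute).
#' @export
read_truth_p_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("integer", "character", "character",
                                        "integer", "logical"))
  class(x) <- c("truth_p", "data.frame")
  x
}

#' Write the truth set D as TSV
#'
#' Columns: pos (0-based), ancestral, ref_base, d_level.
#' @param truth a \code{truth_d} data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth_d_tsv <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth set D from TSV
#' @param path TSV path written by \code{\link{write_truth_d_tsv}}.
#' @return a \code{truth_d} data.frame.
#' @export
read_truth_d_tsv <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("integer", "character", "character",
                                        "numeric"))
  class(x) <- c("truth_d", "data.frame")
  x
}

#' Write a truth set as VCF
#'
#' P truth sets are written with REF = ancestral base, ALT = derived base
#' and the per-sample genotypes from the dosage attribute. D truth sets
#' are written in reference coordinates as a caller would report them:
#' REF = diverged reference base, ALT = ancestral base, every sample
#' homozygous-alternative.
#'
#' @param truth a \code{truth_p} or \code{truth_d} data.frame.
#' @param path output path.
#' @param chrom chromosome name.
#' @param L contig length for the header (optional).
#' @return the path, invisibly.
#' @export
write_truth_vcf <- function(truth, path, chrom = "chr1", L = NULL) {
  n <- nrow(truth)
  na <- rep(NA_real_, n)
  if (inherits(truth, "truth_p")) {
    dos <- attr(truth, "dosage")
    gt <- if (!is.null(dos))
      matrix(c("0/0", "0/1", "1/1")[dos + 1L], n) else NULL
    calls <- data.frame(chrom = rep(chrom, n), pos = truth$pos + 1L,
                        ref = truth$ref, alt = truth$alt,
                        qual = na, QD = na, FS = na,
                        MQ = na, MQRankSum = na, ReadPosRankSum = na)
  } else if (inherits(truth, "truth_d")) {
    gt <- NULL
    calls <- data.frame(chrom = rep(chrom, n), pos = truth$pos + 1L,
                        ref = truth$ref_base, alt = truth$ancestral,
                        qual = na, QD = na, FS = na,
                        MQ = na, MQRankSum = na, ReadPosRankSum = na)
  } else stopf("truth must be a truth_p or truth_d object")
  attr(calls, "gt") <- gt
  attr(calls, "L") <- L
  class(calls) <- c("vcf_calls", "data.frame")
  write_calls_vcf(calls, path)
}
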