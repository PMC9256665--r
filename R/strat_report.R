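#' Stratify false-positive calls by repeat class
#'
#' Counts false positives per repeat class, plus the transposable-element
#' total (TotalTE = LTR + LINE + DNA + RollingCircle). The per-class
#' counts (excluding TotalTE) sum to the total number of false positives.
#'
#' @param classification a \code{classification} from
#'   \code{\link{classify_calls}}.
#' @param track a \code{repeat_track}.
#' @param chrom chromosome name of the calls.
#' @return named integer vector over NonRepetitive, LTR, DNA, LINE,
#'   RollingCircle, TotalTE, SimpleLowComplexitySatellite, OtherRepeat.
#' @export
stratify_fp_counts <- function(classification, track, chrom = "chr1") {
  fp_pos <- classification$calls$pos[classification$label == "FP"] - 1L
  labels <- annotate_repeat_class(fp_pos, track, chrom)
  strat_counts(labels)
}

# counts from a label vector (exposed for direct label input in tests)
strat_counts <- function(labels) {
  lev <- c("NonRepetitive", REPEAT_CLASSES)
  cnt <- table(factor(labels, levels = lev))
  te <- sum(cnt[c("LTR", "DNA", "LINE", "RollingCircle")])
  out <- c(NonRepetitive = unname(cnt["NonRepetitive"]),
           LTR = unname(cnt["LTR"]), DNA = unname(cnt["DNA"]),
           LINE = unname(cnt["LINE"]),
           RollingCircle = unname(cnt["RollingCircle"]),
           TotalTE = te,
           SimpleLowComplexitySatellite = unname(cnt["SimpleLowComplexitySatellite"]),
           OtherRepeat = unname(cnt["OtherRepeat"]))
  vapply(out, as.integer, integer(1))
}

# round half away from zero
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Caller-to-caller ratio table of stratified FP counts
#'
#' For each repeat class, the ratio of caller A's to caller B's
#' false-positive count, rounded to the nearest integer (ties away from
#' zero); NA where caller B's count is zero.
#'
#' @param counts_a,counts_b named count vectors (same names, e.g. from
#'   \code{\link{stratify_fp_counts}}).
#' @return a data.frame with columns repeat_class, count_a, count_b,
#'   ratio.
#' @export
ratio_table <- function(counts_a, counts_b) {
  stopifnot(identical(names(counts_a), names(counts_b)))
  if (any(counts_a < 0) || any(counts_b < 0)) stopf("counts must be non-negative")
  ratio <- ifelse(counts_b == 0, NA_real_,
                  round_half_away(counts_a / counts_b))
  data.frame(repeat_class = names(counts_a),
             count_a = unname(counts_a), count_b = unname(counts_b),
             ratio = unname(ratio))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value: the sum of probabilities of all
#' tables (at fixed margins) no more probable than the observed one.
#'
#' @param a,b,c_,d_ the four cell counts (row-wise).
#' @return the two-sided p-value.
#' @examples fisher_exact_2x2(1, 9, 11, 3)
#' @export
fisher_exact_2x2 <- function(a, b, c_, d_) {
  x <- c(a, b, c_, d_)
  if (any(x < 0) || any(x != round(x))) stopf("counts must be non-negative integers")
  stats::fisher.test(matrix(x, 2, 2, byrow = TRUE))$p.value
}

#' Odds ratio of repeat-localised false positives between two callers
#'
#' From each caller's proportion of false positives inside repeats,
#' returns the odds ratio (caller A's odds of a repeat FP over caller
#' B's) and the excess in percent, 100 * (OR - 1).
#'
#' @param prop_a,prop_b repeat-FP proportions in (0, 1).
#' @return a list with \code{odds_ratio} and \code{excess_pct}.
#' @export
repeat_fp_odds <- function(prop_a, prop_b) {
  if (any(c(prop_a, prop_b) <= 0) || any(c(prop_a, prop_b) >= 1))
    stopf("proportions must be in (0, 1)")
  or <- (prop_a / (1 - prop_a)) / (prop_b / (1 - prop_b))
  list(odds_ratio = or, excess_pct = 100 * (or - 1))
}

#' Fraction of calls below an MQ threshold, per class
#'
#' For each classification label, the fraction of records with MQ strictly
#' below the threshold. Records lacking MQ are excluded from numerator and
#' denominator; their count is reported in the \code{n_missing} attribute.
#'
#' @param classification a \code{classification}.
#' @param threshold MQ threshold (default 40).
#' @return named numeric vector over TPP, TPD, FP (NA for empty classes),
#'   with attribute \code{n_missing}.
#' @export
mq_threshold_proportions <- function(classification, threshold = 40) {
  mq <- classification$calls$MQ
  lab <- classification$label
  miss <- is.na(mq)
  out <- vapply(levels(lab), function(k) {
    i <- lab == k & !miss
    if (!any(i)) return(NA_real_)
    mean(mq[i] < threshold)
  }, numeric(1))
  attr(out, "n_missing") <- sum(miss)
  out
}

#' Sarle's bimodality coefficient
#'
#' b = (g1^2 + 1) / (g2 + 3(n-1)^2 / ((n-2)(n-3))) with g1 the
#' bias-corrected sample skewness and g2 the bias-corrected excess
#' kurtosis. Values above 5/9 (the uniform-distribution benchmark) flag a
#' bimodal (or heavily skewed) distribution.
#'
#' @param values numeric vector, n >= 4, non-zero variance.
#' @return list with \code{coefficient}, \code{is_bimodal}, \code{n}.
#' @export
qd_bimodality <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 4L) stopf("bimodality undefined for n < 4")
  if (stats::var(values) == 0) stopf("bimodality undefined for zero variance")
  g1 <- e1071::skewness(values, type = 2)
  g2 <- e1071::kurtosis(values, type = 2)
  b <- (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
  list(coefficient = b, is_bimodal = b > 5 / 9, n = n)
}

#' Spearman correlation trend with exact small-sample p-value
#'
#' Spearman's rho on average ranks, with a two-sided p-value from the
#' exact permutation distribution of the rank statistic for n <= 8
#' (asymptotic approximation otherwise, or whenever ties are present).
#'
#' @param d_values predictor values (e.g. divergence levels).
#' @param metric_values response values.
#' @return a data.frame of class \code{trend_result} with rho, p_value, n.
#' @export
spearman_trend <- function(d_values, metric_values) {
  if (length(d_values) != length(metric_values)) stopf("length mismatch")
  n <- length(d_values)
  if (n < 3L) stopf("need at least 3 points")
  if (stats::sd(metric_values) == 0 || stats::sd(d_values) == 0) {
    out <- data.frame(rho = NA_real_, p_value = NA_real_, n = n)
    class(out) <- c("trend_result", "data.frame")
    return(out)
  }
  ties <- anyDuplicated(d_values) > 0L || anyDuplicated(metric_values) > 0L
  ct <- suppressWarnings(
    stats::cor.test(d_values, metric_values, method = "spearman",
                    exact = n <= 8L && !ties))
  out <- data.frame(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
  class(out) <- c("trend_result", "data.frame")
  out
}

#' Score diagnostics for a classified call set
#'
#' Bundles the analytics used to characterise caller score behaviour:
#' pooled QD bimodality, per-class MQ-below-threshold fractions, and raw
#' per-class score tables for downstream plotting.
#'
#' @param classification a \code{classification}.
#' @param mq_threshold MQ threshold (default 40).
#' @return list with \code{qd} (bimodality result), \code{mq_below}
#'   (per-class fractions), and \code{scores} (data.frame of label + the
#'   five annotations + QUAL).
#' @export
score_diagnostics <- function(classification, mq_threshold = 40) {
  calls <- classification$calls
  qd <- calls$QD[!is.na(calls$QD)]
  qd_res <- if (length(qd) >= 4L && stats::var(qd) > 0) qd_bimodality(qd)
            else list(coefficient = NA_real_, is_bimodal = NA, n = length(qd))
  list(qd = qd_res,
       mq_below = mq_threshold_proportions(classification, mq_threshold),
       scores = data.frame(label = classification$label,
                           qual = calls$qual, QD = calls$QD, FS = calls$FS,
                           MQ = calls$MQ, MQRankSum = calls$MQRankSum,
                           ReadPosRankSum = calls$ReadPosRankSum))
}
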