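#' Classify calls against the dual truth set
#'
#' A call is a true positive from P (TPP) if its position matches a truth-P
#' site and its ALT equals the derived allele; a true positive from D (TPD)
#' if it matches a truth-D site with ALT equal to the ancestral base; any
#' other call, including one at a truth site with the wrong ALT base, is a
#' false positive. Matching is by site and ALT allele only; genotype
#' concordance is not required for TP status (SNV discovery, not genotype
#' accuracy, is being scored). With \code{match_alt = FALSE} positional
#' overlap alone confers TP status.
#'
#' @param calls a \code{vcf_calls} data.frame (multiallelic records already
#'   split; positions 1-based).
#' @param truth_p a \code{truth_p} data.frame (0-based positions).
#' @param truth_d a \code{truth_d} data.frame (0-based positions).
#' @param match_alt require ALT-allele identity for TP status (default).
#' @param permissive if TRUE, duplicate call positions keep the first
#'   record with a warning instead of erroring.
#' @return an object of class \code{classification}: list with
#'   \code{label} (per-call factor TPP/TPD/FP), \code{fn_p} and
#'   \code{fn_d} (0-based truth positions with no surviving true call),
#'   and the call table.
#' @export
classify_calls <- function(calls, truth_p, truth_d = NULL,
                           match_alt = TRUE, permissive = FALSE) {
  if (is.null(truth_d))
    truth_d <- data.frame(pos = integer(0), ancestral = character(0),
                          ref_base = character(0), d_level = numeric(0))
  if (anyDuplicated(calls$pos)) {
    if (!permissive) stopf("duplicate call positions; use permissive = TRUE to keep the first record")
    warning("duplicate call positions: keeping first record at each position")
    keep <- !duplicated(calls$pos)
    calls <- calls[keep, , drop = FALSE]
    attr(calls, "gt") <- attr(calls, "gt")[keep, , drop = FALSE]
  }
  pos0 <- calls$pos - 1L
  ip <- match(pos0, truth_p$pos)
  id <- match(pos0, truth_d$pos)
  is_tpp <- !is.na(ip) & (!match_alt | calls$alt == truth_p$alt[ip])
  is_tpd <- !is.na(id) & !is_tpp &
    (!match_alt | calls$alt == truth_d$ancestral[id])
  label <- factor(ifelse(is_tpp, "TPP", ifelse(is_tpd, "TPD", "FP")),
                  levels = c("TPP", "TPD", "FP"))
  structure(list(label = label,
                 fn_p = setdiff(truth_p$pos, pos0[is_tpp]),
                 fn_d = setdiff(truth_d$pos, pos0[is_tpd]),
                 calls = calls,
                 n_truth_p = nrow(truth_p), n_truth_d = nrow(truth_d)),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  tab <- table(x$label)
  cat(sprintf("Call classification: %d calls (TPP %d, TPD %d, FP %d); FN_P %d, FN_D %d\n",
              length(x$label), tab["TPP"], tab["TPD"], tab["FP"],
              length(x$fn_p), length(x$fn_d)))
  invisible(x)
}

#' Recovery rate (sensitivity over a truth set)
#'
#' @param n_tp number of true positives.
#' @param n_fn number of false negatives.
#' @return TP / (TP + FN).
#' @examples recovery_rate(90, 10)
#' @export
recovery_rate <- function(n_tp, n_fn) {
  if (n_tp < 0 || n_fn < 0) stopf("counts must be non-negative")
  if (n_tp + n_fn == 0) stopf("recovery rate undefined: no truth sites")
  n_tp / (n_tp + n_fn)
}

#' Proportion of false positives among all calls
#'
#' @param n_fp number of false positives.
#' @param n_calls total number of calls.
#' @return FP / total calls.
#' @export
fp_proportion <- function(n_fp, n_calls) {
  if (n_fp < 0 || n_calls < 0) stopf("counts must be non-negative")
  if (n_calls == 0) stopf("FP proportion undefined: no calls")
  n_fp / n_calls
}

#' F score combining recovery and precision
#'
#' Computed as the harmonic mean of the recovery rate and precision, with
#' precision = 1 - fp_prop: 2 * precision * recovery / (precision +
#' recovery); 0 when both terms are 0. \code{literal = TRUE} instead
#' evaluates the harmonic mean of recovery and the FP proportion itself
#' (an alternative combination kept for comparison; it collapses to near
#' zero whenever the FP proportion is small).
#'
#' @param recovery recovery rate in [0, 1].
#' @param fp_prop FP proportion in [0, 1].
#' @param literal use the literal recovery/FP-proportion combination.
#' @return the f score.
#' @examples f_score(0.8965, 0.0000286)
#' @export
f_score <- function(recovery, fp_prop, literal = FALSE) {
  if (recovery < 0 || recovery > 1 || fp_prop < 0 || fp_prop > 1)
    stopf("recovery and fp_prop must be in [0, 1]")
  a <- recovery
  b <- if (literal) fp_prop else 1 - fp_prop
  if (a + b == 0) return(0)
  2 * a * b / (a + b)
}

#' Filter calls on the QUAL field
#'
#' Retains records whose QUAL is at least \code{threshold} (strictly lower
#' values are discarded). Records with missing QUAL are discarded with a
#' warning (conservative).
#'
#' @param calls a \code{vcf_calls} data.frame.
#' @param threshold minimum QUAL retained (default 20).
#' @return the filtered call set.
#' @export
apply_qual_filter <- function(calls, threshold = 20) {
  if (nrow(calls) == 0L) return(calls)
  miss <- is.na(calls$qual)
  if (any(miss))
    warning(sum(miss), " record(s) with missing QUAL discarded")
  keep <- !miss & calls$qual >= threshold
  subset_calls(calls, keep)
}

#' GATK-style hard-filter criteria
#'
#' Default thresholds: QD < 2, FS > 60, MQ < 40, MQRankSum < -12.5,
#' ReadPosRankSum < -8 (a record violating any one is removed).
#'
#' @param qd_min minimum QD retained.
#' @param fs_max maximum FS retained.
#' @param mq_min minimum MQ retained.
#' @param mqrs_min minimum MQRankSum retained.
#' @param rprs_min minimum ReadPosRankSum retained.
#' @return an object of class \code{hard_filter_criteria}.
#' @export
hard_filter_criteria <- function(qd_min = 2, fs_max = 60, mq_min = 40,
                                 mqrs_min = -12.5, rprs_min = -8) {
  x <- list(qd_min = qd_min, fs_max = fs_max, mq_min = mq_min,
            mqrs_min = mqrs_min, rprs_min = rprs_min)
  if (!all(vapply(x, is.finite, logical(1)))) stopf("thresholds must be finite")
  structure(x, class = "hard_filter_criteria")
}

#' Apply hard filtering on annotation scores
#'
#' Removes a record if ANY present annotation violates its threshold
#' (strict inequalities): QD < qd_min, FS > fs_max, MQ < mq_min,
#' MQRankSum < mqrs_min, ReadPosRankSum < rprs_min. Missing annotations
#' never trigger removal, matching the convention that a record lacking an
#' annotation passes that criterion.
#'
#' @param calls a \code{vcf_calls} data.frame.
#' @param criteria a \code{hard_filter_criteria} object.
#' @return the filtered call set.
#' @export
apply_hard_filter <- function(calls, criteria = hard_filter_criteria()) {
  stopifnot(inherits(criteria, "hard_filter_criteria"))
  if (nrow(calls) == 0L) return(calls)
  viol <- function(x, bad) !is.na(x) & bad(x)
  drop <- viol(calls$QD, function(x) x < criteria$qd_min) |
    viol(calls$FS, function(x) x > criteria$fs_max) |
    viol(calls$MQ, function(x) x < criteria$mq_min) |
    viol(calls$MQRankSum, function(x) x < criteria$mqrs_min) |
    viol(calls$ReadPosRankSum, function(x) x < criteria$rprs_min)
  subset_calls(calls, !drop)
}

# subset a vcf_calls table keeping its attributes aligned
subset_calls <- function(calls, keep) {
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("gt", "truth_class")) {
    v <- attr(calls, a)
    if (!is.null(v)) {
      attr(out, a) <- if (is.matrix(v)) v[keep, , drop = FALSE] else v[keep]
    }
  }
  attr(out, "L") <- attr(calls, "L")
  class(out) <- class(calls)
  out
}

#' Evaluate a call set against the dual truth set
#'
#' Applies the requested filter, classifies the surviving calls, and
#' computes the benchmark metrics. Headline recovery is over truth P;
#' recovery over D and over the union are also reported, and sample-fixed
#' P sites are tabulated as their own category.
#'
#' @param calls a \code{vcf_calls} data.frame.
#' @param truth_p,truth_d truth sets (see \code{\link{classify_calls}}).
#' @param filter one of "none", "qual", "hard".
#' @param qual_threshold QUAL threshold when \code{filter = "qual"}.
#' @param hard_criteria \code{hard_filter_criteria} when
#'   \code{filter = "hard"}.
#' @param match_alt require ALT identity for TP status.
#' @return an object of class \code{eval_metrics}: a one-row data.frame
#'   with counts (n_calls, n_tpp, n_tpd, n_fp, n_fn_p, n_fixed_p) and
#'   metrics (recovery, recovery_d, recovery_all, fp_proportion, f_score,
#'   filter_label); the classification is attached as attribute
#'   \code{classification}.
#' @export
evaluate_calls <- function(calls, truth_p, truth_d = NULL,
                           filter = c("none", "qual", "hard"),
                           qual_threshold = 20,
                           hard_criteria = hard_filter_criteria(),
                           match_alt = TRUE) {
  filter <- match.arg(filter)
  filtered <- switch(filter,
                     none = calls,
                     qual = apply_qual_filter(calls, qual_threshold),
                     hard = apply_hard_filter(calls, hard_criteria))
  cl <- classify_calls(filtered, truth_p, truth_d, match_alt = match_alt)
  tab <- table(cl$label)
  n_tpp <- as.integer(tab["TPP"]); n_tpd <- as.integer(tab["TPD"])
  n_fp <- as.integer(tab["FP"])
  n_calls <- length(cl$label)
  rec <- if (cl$n_truth_p > 0) recovery_rate(n_tpp, length(cl$fn_p)) else NA_real_
  rec_d <- if (cl$n_truth_d > 0) recovery_rate(n_tpd, length(cl$fn_d)) else NA_real_
  n_tp_all <- n_tpp + n_tpd
  n_fn_all <- length(cl$fn_p) + length(cl$fn_d)
  rec_all <- if (n_tp_all + n_fn_all > 0) recovery_rate(n_tp_all, n_fn_all) else NA_real_
  fpp <- if (n_calls > 0) fp_proportion(n_fp, n_calls) else NA_real_
  f <- if (!is.na(rec) && !is.na(fpp)) f_score(rec, fpp) else NA_real_
  n_fixed <- if (!is.null(truth_p$fixed)) sum(truth_p$fixed) else 0L
  out <- data.frame(filter_label = filter, n_calls = n_calls,
                    n_tpp = n_tpp, n_tpd = n_tpd, n_fp = n_fp,
                    n_fn_p = length(cl$fn_p), n_fn_d = length(cl$fn_d),
                    n_fixed_p = n_fixed,
                    recovery = rec, recovery_d = rec_d,
                    recovery_all = rec_all,
                    fp_proportion = fpp, f_score = f)
  attr(out, "classification") <- cl
  class(out) <- c("eval_metrics", "data.frame")
  out
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("Evaluation (filter: %s)\n", x$filter_label))
  cat(sprintf("  calls %d = TPP %d + TPD %d + FP %d; FN_P %d\n",
              x$n_calls, x$n_tpp, x$n_tpd, x$n_fp, x$n_fn_p))
  cat(sprintf("  recovery %.4f | FP proportion %.6f | f %.4f\n",
              x$recovery, x$fp_proportion, x$f_score))
  invisible(x)
}

#' Per-sample genotype concordance at true-positive P sites
#'
#' Supplementary report: fraction of sample genotypes at TPP sites that
#' match the truth dosage exactly.
#'
#' @param classification a \code{classification} from
#'   \code{\link{classify_calls}}.
#' @param truth_p a \code{truth_p} with the dosage attribute.
#' @return a data.frame with n_sites, n_genotypes, n_concordant,
#'   concordance; NA concordance when genotypes are unavailable.
#' @export
genotype_concordance <- function(classification, truth_p) {
  dos <- attr(truth_p, "dosage")
  gt <- attr(classification$calls, "gt")
  idx <- which(classification$label == "TPP")
  if (is.null(dos) || is.null(gt) || length(idx) == 0L) {
    return(data.frame(n_sites = length(idx), n_genotypes = 0L,
                      n_concordant = 0L, concordance = NA_real_))
  }
  ti <- match(classification$calls$pos[idx] - 1L, truth_p$pos)
  truth_gt <- matrix(c("0/0", "0/1", "1/1")[dos[ti, , drop = FALSE] + 1L],
                     length(idx))
  called_gt <- gt[idx, , drop = FALSE]
  called_gt <- chartr("|", "/", called_gt)
  called_gt[called_gt == "1/0"] <- "0/1"
  ok <- called_gt == truth_gt
  data.frame(n_sites = length(idx), n_genotypes = length(ok),
             n_concordant = sum(ok), concordance = mean(ok))
}
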