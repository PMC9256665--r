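#' Default annotation-score model for the caller emulator
#'
#' Per-class distributions for QUAL and the five GATK-style annotations.
#' True calls get high mapping quality (MQ ~ Normal(59, 3) truncated to
#' [0, 60]) and rank-sum statistics near their null; false positives get
#' low, broad MQ (Normal(30, 8)) and inflated-variance annotations, echoing
#' the characteristic score separation seen in real caller output. QD for
#' true calls is a two-component model: a low mode Normal(8, 3) for sites
#' called from heterozygous carriers and a high mode Normal(25, 4) for
#' sites whose carriers are homozygous for the alternative allele, both
#' truncated at 0. These are free, configurable parameters shaping the
#' emulator's output, not fitted values.
#'
#' @return a list with components \code{TP} and \code{FP}, each a list of
#'   \code{c(mean, sd)} pairs: \code{qual}, \code{mq}, \code{fs},
#'   \code{mqrs}, \code{rprs}, plus \code{qd_low}/\code{qd_high} (TP) and
#'   \code{qd} (FP).
#' @export
default_score_model <- function() {
  list(
    TP = list(qual = c(500, 150), mq = c(59, 3), mq_baseline_low = 0.05,
              qd_low = c(8, 3), qd_high = c(25, 4),
              fs = c(2, 2), mqrs = c(0, 1), rprs = c(0, 1)),
    FP = list(qual = c(60, 40), mq = c(30, 8), qd = c(8, 4),
              fs = c(15, 25), mqrs = c(-2, 5), rprs = c(-1, 4))
  )
}

#' Parameters for the variant-caller emulator
#'
#' The emulator converts truth sets into an annotated call set with
#' configurable error behaviour, standing in for an external mapper +
#' caller so the evaluator can be exercised closed-loop.
#'
#' @param fn_rate per-truth-site miss (false negative) probability.
#' @param fp_per_mb expected false positives per megabase.
#' @param fp_repeat_enrichment multiplicative weight for placing false
#'   positives inside repeat intervals relative to outside (1 = uniform).
#' @param score_model per-class score distributions, see
#'   \code{\link{default_score_model}}.
#' @param mq_d_coupling strength of the divergence coupling: the MQ
#'   distribution of true calls is shifted toward the false-positive MQ
#'   distribution by the fraction \code{min(1, mq_d_coupling * d)},
#'   emulating the loss of mapping quality on a diverged reference.
#' @param seed integer seed.
#' @return an object of class \code{emulator_params}.
#' @export
emulator_params <- function(fn_rate = 0.05, fp_per_mb = 50,
                            fp_repeat_enrichment = 1,
                            score_model = default_score_model(),
                            mq_d_coupling = 20, seed = 1L) {
  if (fn_rate < 0 || fn_rate > 1) stopf("fn_rate must be in [0, 1]")
  if (fp_per_mb < 0) stopf("fp_per_mb must be >= 0")
  if (fp_repeat_enrichment < 0) stopf("fp_repeat_enrichment must be >= 0")
  structure(list(fn_rate = fn_rate, fp_per_mb = fp_per_mb,
                 fp_repeat_enrichment = fp_repeat_enrichment,
                 score_model = score_model,
                 mq_d_coupling = mq_d_coupling, seed = as.integer(seed)),
            class = "emulator_params")
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

# draw the five annotations + QUAL for n records of one class
draw_scores <- function(n, model, class, d = 0, coupling = 0,
                        qd_high_weight = NULL) {
  if (n == 0L) {
    return(data.frame(qual = numeric(0), QD = numeric(0), FS = numeric(0),
                      MQ = numeric(0), MQRankSum = numeric(0),
                      ReadPosRankSum = numeric(0)))
  }
  if (class == "FP") {
    m <- model$FP
    qd <- rnorm_trunc(n, m$qd[1], m$qd[2], lo = 0)
    mq <- rnorm_trunc(n, m$mq[1], m$mq[2], lo = 0, hi = 60)
  } else {
    m <- model$TP
    w <- if (is.null(qd_high_weight)) rep(0, n) else qd_high_weight
    hi <- stats::runif(n) < w
    qd <- ifelse(hi,
                 rnorm_trunc(n, m$qd_high[1], m$qd_high[2], lo = 0),
                 rnorm_trunc(n, m$qd_low[1], m$qd_low[2], lo = 0))
    # divergence pulls true-call MQ toward the FP distribution: a
    # baseline fraction of true calls already sits in the low-MQ
    # component, and that fraction grows with d
    base <- if (is.null(m$mq_baseline_low)) 0 else m$mq_baseline_low
    w_low <- min(1, base + (1 - base) * min(1, coupling * d))
    low <- stats::runif(n) < w_low
    mq <- ifelse(low,
                 rnorm_trunc(n, model$FP$mq[1], model$FP$mq[2], lo = 0, hi = 60),
                 rnorm_trunc(n, m$mq[1], m$mq[2], lo = 0, hi = 60))
  }
  data.frame(
    qual = rnorm_trunc(n, m$qual[1], m$qual[2], lo = 0),
    QD = qd,
    FS = rnorm_trunc(n, m$fs[1], m$fs[2], lo = 0),
    MQ = mq,
    MQRankSum = stats::rnorm(n, m$mqrs[1], m$mqrs[2]),
    ReadPosRankSum = stats::rnorm(n, m$rprs[1], m$rprs[2])
  )
}

# sample k false-positive positions, repeat-weighted, avoiding `avoid`
sample_fp_positions <- function(k, L, avoid, repeat_track, enrichment,
                                chrom) {
  if (k == 0L) return(integer(0))
  in_rep <- NULL
  if (!is.null(repeat_track) && enrichment != 1) {
    gr <- repeat_intervals(repeat_track, chrom)
    red <- IRanges::reduce(IRanges::ranges(gr))
    Lr <- sum(IRanges::width(red))
    Lr <- min(Lr, L)
    if (Lr > 0 && Lr < L) {
      p_rep <- enrichment * Lr / (enrichment * Lr + (L - Lr))
      in_rep <- list(red = red, Lr = Lr, p_rep = p_rep)
    }
  }
  pos <- integer(0)
  avoid_set <- avoid
  guard <- 0L
  while (length(pos) < k && guard < 100L) {
    need <- k - length(pos)
    if (is.null(in_rep)) {
      cand <- sample.int(L, need, replace = TRUE) - 1L
    } else {
      take_rep <- stats::runif(need) < in_rep$p_rep
      cand <- integer(need)
      if (any(take_rep)) {
        off <- sample.int(in_rep$Lr, sum(take_rep), replace = TRUE)
        starts0 <- IRanges::start(in_rep$red) - 1L
        widths <- IRanges::width(in_rep$red)
        iv <- findInterval(off - 1L, cumsum(c(0L, widths))[-(length(widths) + 1L)])
        cand[take_rep] <- starts0[iv] + (off - 1L) - cumsum(c(0L, widths))[iv]
      }
      if (any(!take_rep)) {
        # rejection-sample the non-repeat stratum
        nr <- sum(!take_rep)
        out <- integer(0)
        while (length(out) < nr) {
          c2 <- sample.int(L, 2L * nr, replace = TRUE) - 1L
          hit <- IRanges::overlapsAny(IRanges::IRanges(c2 + 1L, width = 1L),
                                      in_rep$red)
          out <- c(out, c2[!hit])
        }
        cand[!take_rep] <- out[seq_len(nr)]
      }
    }
    ok <- !(cand %in% avoid_set) & !duplicated(cand)
    pos <- c(pos, cand[ok])
    avoid_set <- c(avoid_set, cand[ok])
    guard <- guard + 1L
  }
  if (length(pos) < k) stopf("could not place %d false positives in L = %d", k, L)
  pos[seq_len(k)]
}

#' Emulate a variant caller on the dual truth set
#'
#' Generates an annotated SNV call set from the truth sets: each truth site
#' is emitted with probability 1 - fn_rate; false positives arrive as a
#' Poisson(fp_per_mb * L / 1e6) count at non-truth positions, preferentially
#' inside repeat intervals when \code{fp_repeat_enrichment > 1}. P-site
#' records carry REF = reference (ancestral) base and ALT = derived base
#' with the sample genotypes; D-site records carry REF = diverged reference
#' base and ALT = ancestral base, homozygous-alternative in every sample.
#' Scores are drawn from the class's score model; the QD high mode is
#' used for sites whose carriers are all homozygous for the alternative
#' allele, so D sites (and sample-fixed P sites) populate the high-QD
#' mode and a bimodal pooled QD distribution emerges whenever divergence
#' contributes calls, while a polymorphic-only call set stays unimodal.
#'
#' @param truth_p a \code{truth_p} data.frame (needs the \code{dosage}
#'   attribute for genotype-aware QD weighting; without it P sites use the
#'   low mode).
#' @param truth_d a \code{truth_d} data.frame (may have 0 rows).
#' @param L genome length in bp.
#' @param params an \code{emulator_params} object.
#' @param repeat_track optional \code{repeat_track} for FP placement.
#' @param d_level divergence level of the reference the calls are
#'   expressed against (drives the MQ coupling).
#' @param n_sample number of diploid samples (inferred from the dosage
#'   attribute when present).
#' @param chrom chromosome name written in the records.
#' @param seed optional seed (defaults to the seed in \code{params}).
#' @return a data.frame of class \code{vcf_calls} with columns
#'   \code{chrom}, \code{pos} (1-based), \code{ref}, \code{alt},
#'   \code{qual}, \code{QD}, \code{FS}, \code{MQ}, \code{MQRankSum},
#'   \code{ReadPosRankSum}; attribute \code{gt} is the per-sample genotype
#'   matrix and attribute \code{truth_class} records each record's
#'   generating class (for diagnostics; the evaluator never reads it).
#' @export
emulate_caller <- function(truth_p, truth_d, L, params,
                           repeat_track = NULL, d_level = 0,
                           n_sample = NULL, chrom = "chr1",
                           seed = params$seed) {
  stopifnot(inherits(params, "emulator_params"))
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(L)
  dos <- attr(truth_p, "dosage")
  if (!is.null(dos) && nrow(dos) != nrow(truth_p)) dos <- NULL  # stale attr
  if (is.null(n_sample)) n_sample <- if (!is.null(dos)) ncol(dos) else 1L
  if (max(c(-1L, truth_p$pos, truth_d$pos)) >= L)
    stopf("truth position >= L: truth and reference coordinates disagree")
  if (length(intersect(truth_p$pos, truth_d$pos)) > 0L)
    stopf("truth P and D share positions; regenerate D with P excluded")

  keep_p <- stats::runif(nrow(truth_p)) >= params$fn_rate
  keep_d <- stats::runif(nrow(truth_d)) >= params$fn_rate
  tp <- truth_p[keep_p, , drop = FALSE]
  td <- truth_d[keep_d, , drop = FALSE]
  dos_kept <- if (!is.null(dos)) dos[keep_p, , drop = FALSE] else NULL

  n_fp <- stats::rpois(1L, params$fp_per_mb * L / 1e6)
  fp_pos <- sample_fp_positions(n_fp, L, c(truth_p$pos, truth_d$pos),
                                repeat_track, params$fp_repeat_enrichment,
                                chrom)

  # QD high mode is reserved for sites whose carriers are all homozygous
  # for the alternative allele (dosage 2 in every carrier): divergence-like
  # sites. Sites with any heterozygous carrier draw from the low mode.
  w_p <- if (!is.null(dos_kept) && nrow(tp) > 0L) {
    carriers <- rowSums(dos_kept > 0L)
    hom <- rowSums(dos_kept == 2L)
    as.numeric(carriers > 0L & hom == carriers)
  } else rep(0, nrow(tp))

  sc_p <- draw_scores(nrow(tp), params$score_model, "TP", d_level,
                      params$mq_d_coupling, qd_high_weight = w_p)
  sc_d <- draw_scores(nrow(td), params$score_model, "TP", d_level,
                      params$mq_d_coupling, qd_high_weight = rep(1, nrow(td)))
  sc_f <- draw_scores(length(fp_pos), params$score_model, "FP")

  fp_ref <- sample(DNA_BASES, length(fp_pos), replace = TRUE)
  n_rec <- nrow(tp) + nrow(td) + length(fp_pos)
  calls <- data.frame(
    chrom = rep(chrom, n_rec),
    pos = c(tp$pos, td$pos, fp_pos) + 1L,
    ref = c(tp$ref, td$ref_base, fp_ref),
    alt = c(tp$alt, td$ancestral, random_alt_base(fp_ref)),
    rbind(sc_p, sc_d, sc_f)
  )

  # genotypes
  gt_p <- if (!is.null(dos_kept) && nrow(tp) > 0L) {
    matrix(c("0/0", "0/1", "1/1")[dos_kept + 1L], nrow(tp), n_sample)
  } else matrix("0/1", nrow(tp), n_sample)
  gt_d <- matrix("1/1", nrow(td), n_sample)
  gt_f <- matrix(ifelse(stats::runif(length(fp_pos) * n_sample) < 0.3,
                        "0/1", "0/0"), length(fp_pos), n_sample)
  if (length(fp_pos) > 0L && n_sample > 0L) {
    none <- rowSums(gt_f != "0/0") == 0L
    gt_f[none, 1L] <- "0/1"
  }
  gt <- rbind(gt_p, gt_d, gt_f)
  cls <- c(rep("TPP", nrow(tp)), rep("TPD", nrow(td)),
           rep("FP", length(fp_pos)))

  o <- order(calls$pos)
  calls <- calls[o, , drop = FALSE]
  rownames(calls) <- NULL
  attr(calls, "gt") <- gt[o, , drop = FALSE]
  attr(calls, "truth_class") <- cls[o]
  attr(calls, "L") <- L
  class(calls) <- c("vcf_calls", "data.frame")
  calls
}
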