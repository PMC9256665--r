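ten_site_fixture <- function() {
  # truth P at 10,20,...,50; truth D at 60,...,80 (0-based)
  tp <- make_truth_p(pos = c(10, 20, 30, 40, 50),
                     ref = c("A", "C", "G", "T", "A"),
                     alt = c("C", "T", "A", "G", "T"),
                     dosage = matrix(c(1, 2, 1, 1, 2,
                                       0, 0, 1, 1, 2), 5, 2))
  td <- make_truth_d(pos = c(60, 70, 80),
                     ancestral = c("A", "C", "G"),
                     ref_base = c("G", "A", "T"))
  list(tp = tp, td = td)
}

test_that("classification matches definitions and brute force on a fixture", {
  fx <- ten_site_fixture()
  calls <- make_calls(pos = c(11, 21, 31, 41, 61, 71, 85, 96),
                      ref = c("A", "C", "G", "T", "G", "A", "A", "C"),
                      alt = c("C", "T", "C", "G", "A", "C", "G", "T"))
  cl <- classify_calls(calls, fx$tp, fx$td)
  # pos 31 (0-based 30) has the wrong ALT base -> FP; 85/96 not in truth -> FP
  expect_equal(as.character(cl$label),
               c("TPP", "TPP", "FP", "TPP", "TPD", "TPD", "FP", "FP"))
  expect_identical(as.character(cl$label),
                   brute_force_classify(calls, fx$tp, fx$td))
  expect_setequal(cl$fn_p, c(30, 50))
  expect_setequal(cl$fn_d, 80)
  # positional matching mode accepts the wrong-ALT call
  cl2 <- classify_calls(calls, fx$tp, fx$td, match_alt = FALSE)
  expect_equal(as.character(cl2$label)[3], "TPP")
})

test_that("classification equals brute force on random call sets", {
  for (seed in 1:5) {
    set.seed(seed)
    tp <- random_truth_p(30, 1000, 4, seed)
    anc <- vcbench:::random_sequence(1000)
    td <- inject_divergence(anc, 0.03, excluded_positions = tp$pos,
                            seed = seed)$truth_d
    pos <- sample.int(1000, 60)
    ref <- sample(c("A", "C", "G", "T"), 60, replace = TRUE)
    alt <- vcbench:::random_alt_base(ref)
    calls <- make_calls(pos, ref, alt)
    cl <- classify_calls(calls, tp, td)
    expect_identical(as.character(cl$label),
                     brute_force_classify(calls, tp, td))
    # partition invariant
    expect_equal(sum(table(cl$label)), nrow(calls))
  }
})

test_that("duplicate call positions error unless permissive", {
  fx <- ten_site_fixture()
  calls <- make_calls(pos = c(11, 11), ref = c("A", "A"), alt = c("C", "G"))
  expect_error(classify_calls(calls, fx$tp, fx$td), "duplicate")
  expect_warning(cl <- classify_calls(calls, fx$tp, fx$td, permissive = TRUE),
                 "duplicate")
  expect_length(cl$label, 1)
})

test_that("metric arithmetic follows the definitions", {
  expect_equal(recovery_rate(90, 10), 0.90)
  expect_equal(recovery_rate(0, 5), 0)
  expect_equal(recovery_rate(173, 27), 0.865)
  expect_error(recovery_rate(0, 0), "undefined")
  expect_equal(fp_proportion(0, 100), 0)
  expect_equal(fp_proportion(5, 200), 0.025)
  expect_equal(fp_proportion(200, 200), 1)
  expect_error(fp_proportion(1, 0), "undefined")
})

test_that("f score is F1 with precision = 1 - FP proportion", {
  expect_equal(f_score(1, 0), 1)
  expect_equal(f_score(0, 0.5), 0)
  expect_equal(f_score(0.8965, 0.0000286), 0.94542, tolerance = 1e-5)
  expect_error(f_score(1.2, 0), "must be in")
  # the literal recovery/FP-proportion combination collapses to ~0 when
  # the FP proportion is small
  expect_lt(f_score(0.8965, 0.0000286, literal = TRUE), 1e-4)
  expect_equal(f_score(0, 0, literal = TRUE), 0)
})

test_that("QUAL filter boundary is exact and missing QUAL is discarded", {
  calls <- make_calls(pos = 1:4, ref = "A", alt = "C",
                      qual = c(19.99, 20, 60, NA))
  expect_warning(out <- apply_qual_filter(calls), "missing QUAL")
  expect_equal(out$pos, c(2L, 3L))
  # identity on all-passing input, empty in empty out
  all60 <- make_calls(pos = 1:3, ref = "A", alt = "C", qual = 60)
  expect_equal(apply_qual_filter(all60), all60)
  expect_equal(nrow(apply_qual_filter(all60[0, ])), 0)
})

test_that("hard filter applies strict thresholds and passes missing scores", {
  base <- make_calls(pos = 1:7, ref = "A", alt = "C",
                     QD = c(1.9, 2.0, 25, 25, 25, 25, 25),
                     FS = c(1, 1, 60.01, 1, 1, 1, 1),
                     MQ = c(60, 60, 60, 40.0, 39.9, 60, 60),
                     MQRankSum = c(0, 0, 0, 0, 0, -12.6, 0),
                     ReadPosRankSum = c(0, 0, 0, 0, 0, 0, -8.5))
  out <- apply_hard_filter(base)
  # removed: QD 1.9, FS 60.01, MQ 39.9, MQRS -12.6, RPRS -8.5
  expect_equal(out$pos, c(2L, 4L))
  # a record lacking MQRankSum with all present scores passing is retained
  miss <- make_calls(pos = 1, ref = "A", alt = "C", MQRankSum = NA_real_)
  expect_equal(nrow(apply_hard_filter(miss)), 1)
  # filter idempotence
  expect_equal(apply_hard_filter(out), out)
})

test_that("evaluate composes filters, classification and metrics", {
  fx <- ten_site_fixture()
  ep <- emulator_params(fn_rate = 0, fp_per_mb = 0, seed = 2)
  calls <- emulate_caller(fx$tp, fx$td, 100, ep)
  em <- evaluate_calls(calls, fx$tp, fx$td)
  expect_equal(em$recovery, 1)
  expect_equal(em$fp_proportion, 0)
  expect_equal(em$f_score, 1)
  expect_equal(em$n_calls, em$n_tpp + em$n_tpd + em$n_fp)
  # filtering can only shrink the call set and the recovery
  tp2 <- random_truth_p(200, 1e5, 6, 77)
  td2 <- make_truth_d(integer(0), character(0), character(0))
  ep2 <- emulator_params(fn_rate = 0.1, fp_per_mb = 300, seed = 3)
  calls2 <- emulate_caller(tp2, td2, 1e5, ep2)
  raw <- evaluate_calls(calls2, tp2, td2)
  for (f in c("qual", "hard")) {
    filt <- evaluate_calls(calls2, tp2, td2, filter = f)
    expect_lte(filt$n_calls, raw$n_calls)
    expect_lte(filt$recovery, raw$recovery)
  }
})

test_that("evaluator recovers emulator error rates across seeds", {
  tp <- random_truth_p(2000, 1e6, 6, 123)
  tp <- tp[seq_len(1000), ]
  td <- make_truth_d(integer(0), character(0), character(0))
  ep <- emulator_params(fn_rate = 0.1, fp_per_mb = 50, seed = 1)
  res <- t(vapply(1:20, function(s) {
    calls <- emulate_caller(tp, td, 1e6, ep, seed = 1000 + s)
    em <- evaluate_calls(calls, tp, td)
    c(em$recovery, em$n_fp)
  }, numeric(2)))
  expect_lt(abs(mean(res[, 1]) - 0.9), 3 * sqrt(0.9 * 0.1 / 1000 / 20))
  expect_lt(abs(mean(res[, 2]) - 50), 3 * sqrt(50 / 20))
})

test_that("genotype concordance is perfect for the emulator's own output", {
  fx <- ten_site_fixture()
  ep <- emulator_params(fn_rate = 0, fp_per_mb = 0, seed = 4)
  calls <- emulate_caller(fx$tp, fx$td, 100, ep)
  cl <- classify_calls(calls, fx$tp, fx$td)
  gc <- genotype_concordance(cl, fx$tp)
  expect_equal(gc$concordance, 1)
  expect_equal(gc$n_sites, 5)
})
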