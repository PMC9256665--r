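test_that("repeat annotation applies precedence over nested intervals", {
  track <- toy_track()
  # 950-999 is covered by both Simple_repeat and LTR -> LTR wins
  expect_equal(annotate_repeat_class(c(150, 350, 550, 750, 920, 960, 50),
                                     track),
               c("LTR", "LINE", "DNA", "RollingCircle",
                 "SimpleLowComplexitySatellite", "LTR", "NonRepetitive"))
  # brute-force interval scan agrees
  df <- data.frame(start = c(100, 300, 500, 700, 900, 950),
                   end = c(200, 400, 600, 800, 1000, 1000),
                   class = c("LTR", "LINE", "DNA", "RollingCircle",
                             "SimpleLowComplexitySatellite", "LTR"))
  prec <- c("LTR", "LINE", "DNA", "RollingCircle",
            "SimpleLowComplexitySatellite", "OtherRepeat")
  pos <- 0:1050
  brute <- vapply(pos, function(p) {
    hit <- df$class[p >= df$start & p < df$end]
    if (length(hit) == 0) "NonRepetitive" else prec[min(match(hit, prec))]
  }, character(1))
  expect_identical(annotate_repeat_class(pos, track), brute)
  # all-classes mode returns every overlapping class
  allc <- annotate_repeat_class(960, track, all_classes = TRUE)[[1]]
  expect_setequal(allc, c("LTR", "SimpleLowComplexitySatellite"))
})

test_that("rmsk-style class names map into the controlled vocabulary", {
  tr <- repeat_track(data.frame(chrom = "chr1",
                                start = c(0, 10, 20, 30),
                                end = c(5, 15, 25, 35),
                                class = c("RC", "Low_complexity",
                                          "Satellite", "Unknown")))
  expect_equal(annotate_repeat_class(c(2, 12, 22, 32), tr),
               c("RollingCircle", "SimpleLowComplexitySatellite",
                 "SimpleLowComplexitySatellite", "OtherRepeat"))
  expect_error(repeat_track(data.frame(chrom = "chr1", start = 10,
                                       end = 5, class = "LTR")),
               "malformed")
})

test_that("repeat track files (BED and rmsk table) are ingested", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tLTR", "chr1\t300\t400\tSimple_repeat"), bed)
  tr <- repeat_track(bed)
  expect_equal(annotate_repeat_class(c(150, 350), tr),
               c("LTR", "SimpleLowComplexitySatellite"))
  rmsk <- tempfile(fileext = ".tsv")
  writeLines(c("genoName\tgenoStart\tgenoEnd\trepClass",
               "chr1\t100\t200\tLINE", "chr1\t300\t400\tRC"), rmsk)
  tr2 <- repeat_track(rmsk)
  expect_equal(annotate_repeat_class(c(150, 350), tr2),
               c("LINE", "RollingCircle"))
  file.remove(bed, rmsk)
})

test_that("stratified counts conserve the FP total and TotalTE sums TEs", {
  track <- toy_track()
  tp <- make_truth_p(5, "A", "C", matrix(1, 1, 1))
  td <- make_truth_d(integer(0), character(0), character(0))
  calls <- make_calls(pos = c(6, 151, 351, 551, 751, 921, 50, 61),
                      ref = "A", alt = "C")
  cl <- classify_calls(calls, tp, td)
  cnt <- stratify_fp_counts(cl, track)
  expect_equal(sum(cnt[c("NonRepetitive", "LTR", "DNA", "LINE",
                         "RollingCircle", "SimpleLowComplexitySatellite",
                         "OtherRepeat")]),
               sum(cl$label == "FP"))
  expect_equal(unname(cnt[["TotalTE"]]),
               unname(cnt[["LTR"]] + cnt[["DNA"]] + cnt[["LINE"]] +
                      cnt[["RollingCircle"]]))
  expect_equal(unname(cnt[["NonRepetitive"]]), 2L)  # pos 50 and 61
  # zero false positives give all-zero counts
  cl0 <- classify_calls(make_calls(6, "A", "C"), tp, td)
  expect_true(all(stratify_fp_counts(cl0, track) == 0L))
  # random emulator run conserves totals
  tp2 <- random_truth_p(50, 1e5, 4, 5)
  ep <- emulator_params(fn_rate = 0, fp_per_mb = 1000,
                        fp_repeat_enrichment = 3, seed = 6)
  track2 <- repeat_track(data.frame(chrom = "chr1", start = c(1e4, 5e4),
                                    end = c(2e4, 6e4),
                                    class = c("LTR", "DNA")))
  calls2 <- emulate_caller(tp2, td, 1e5, ep, repeat_track = track2)
  cl2 <- classify_calls(calls2, tp2, td)
  cnt2 <- stratify_fp_counts(cl2, track2)
  expect_equal(sum(cnt2) - cnt2[["TotalTE"]], sum(cl2$label == "FP"))
})

test_that("ratio table rounds to nearest integer, ties away from zero", {
  a <- c(x = 11441, y = 1167, z = 2637, w = 0)
  b <- c(x = 31, y = 0, z = 2, w = 0)
  rt <- ratio_table(a, b)
  expect_equal(rt$ratio, c(369, NA, 1319, NA))
  expect_error(ratio_table(c(x = -1), c(x = 1)), "non-negative")
  expect_equal(vcbench:::round_half_away(c(0.5, 1.5, 2.4)), c(1, 2, 2))
})

test_that("Fisher exact p-values match full hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1.0)
  expect_equal(fisher_exact_2x2(1, 9, 11, 3), 0.00276, tolerance = 1e-5 / 0.00276)
  expect_equal(fisher_exact_2x2(0, 10, 10, 0), 2 / choose(20, 10),
               tolerance = 1e-10)
  set.seed(42)
  for (i in 1:100) {
    x <- as.integer(rmultinom(1, sample(4:30, 1), rep(0.25, 4)))
    expect_equal(fisher_exact_2x2(x[1], x[2], x[3], x[4]),
                 fisher_enum_p(x[1], x[2], x[3], x[4]),
                 tolerance = 1e-9,
                 info = paste(x, collapse = ","))
  }
  # symmetry under row and column swaps
  expect_equal(fisher_exact_2x2(3, 8, 12, 2), fisher_exact_2x2(12, 2, 3, 8))
  expect_equal(fisher_exact_2x2(3, 8, 12, 2), fisher_exact_2x2(8, 3, 2, 12))
  expect_error(fisher_exact_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("repeat FP odds reproduce the caller-vs-caller excess", {
  odds <- repeat_fp_odds(0.8524, 0.7891)
  expect_equal(odds$excess_pct, 54, tolerance = 0.01)
  expect_error(repeat_fp_odds(0, 0.5), "proportions")
})

test_that("MQ threshold proportions are computed per class", {
  tp <- make_truth_p(c(10, 20), c("A", "C"), c("C", "T"),
                     matrix(1, 2, 1))
  td <- make_truth_d(30, "A", "G")
  calls <- make_calls(pos = c(11, 21, 31, 40, 41, 42, 43, 44),
                      ref = c("A", "C", "G", "T", "T", "T", "T", "T"),
                      alt = c("C", "T", "A", "G", "G", "G", "G", "G"),
                      MQ = c(60, 35, 60, 30, 30, 30, 30, 60))
  cl <- classify_calls(calls, tp, td)
  frac <- mq_threshold_proportions(cl, threshold = 40)
  expect_equal(as.numeric(frac), c(0.5, 0, 0.8))
  # missing MQ records are excluded and counted
  calls$MQ[1] <- NA
  cl2 <- classify_calls(calls, tp, td)
  frac2 <- mq_threshold_proportions(cl2)
  expect_equal(unname(frac2[["TPP"]]), 1)
  expect_equal(attr(frac2, "n_missing"), 1L)
  # empty class yields NA
  cl3 <- classify_calls(make_calls(11, "A", "C"), tp, td)
  expect_true(is.na(mq_threshold_proportions(cl3)[["TPD"]]))
})

test_that("bimodality coefficient separates one mode from two", {
  set.seed(7)
  uni <- vapply(1:5, function(s) {
    set.seed(s)
    qd_bimodality(rnorm(10000))$is_bimodal
  }, logical(1))
  expect_true(all(!uni))
  bi <- vapply(1:5, function(s) {
    set.seed(s)
    x <- c(rnorm(5000, 8, 3), rnorm(5000, 25, 4))
    qd_bimodality(x)$is_bimodal
  }, logical(1))
  expect_true(all(bi))
  expect_error(qd_bimodality(rep(1, 10)), "zero variance")
  expect_error(qd_bimodality(1:3), "n < 4")
})

test_that("Spearman trend matches the exact permutation oracle", {
  # strictly decreasing metric: rho = -1, exact p = 2/n!
  tr <- spearman_trend(c(0, 0.005, 0.01, 0.015, 0.02),
                       c(0.905, 0.902, 0.899, 0.896, 0.895))
  expect_equal(tr$rho, -1)
  expect_equal(tr$p_value, 2 / factorial(5))
  set.seed(31)
  for (i in 1:30) {
    n <- sample(4:6, 1)
    x <- runif(n); y <- runif(n)
    tr <- spearman_trend(x, y)
    expect_equal(tr$p_value, spearman_perm_p(x, y), tolerance = 1e-9)
    expect_equal(tr$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  }
  # constant metric: rho undefined -> NA
  expect_true(is.na(spearman_trend(1:5, rep(2, 5))$rho))
  expect_error(spearman_trend(1:2, 1:2), "at least 3")
})

test_that("repeat-enriched FPs are detected by the Fisher test with power", {
  track <- repeat_track(data.frame(chrom = "chr1", start = 2e4, end = 5e4,
                                   class = "LTR"))
  td <- make_truth_d(integer(0), character(0), character(0))
  tp <- random_truth_p(20, 1e5, 4, 3)
  reject <- vapply(1:20, function(s) {
    high <- emulate_caller(tp, td, 1e5,
                           emulator_params(fn_rate = 0, fp_per_mb = 5000,
                                           fp_repeat_enrichment = 6, seed = s),
                           repeat_track = track, seed = s)
    low <- emulate_caller(tp, td, 1e5,
                          emulator_params(fn_rate = 0, fp_per_mb = 5000,
                                          fp_repeat_enrichment = 1, seed = s),
                          repeat_track = track, seed = 100 + s)
    in_rep <- function(calls) {
      cls <- attr(calls, "truth_class")
      fp <- calls$pos[cls == "FP"] - 1L
      lab <- annotate_repeat_class(fp, track)
      c(sum(lab != "NonRepetitive"), sum(lab == "NonRepetitive"))
    }
    h <- in_rep(high); l <- in_rep(low)
    fisher_exact_2x2(h[1], h[2], l[1], l[2]) < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.9)
})
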