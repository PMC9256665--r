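#' Configuration for an end-to-end benchmark run
#'
#' Bundles every stage's parameters. The population-genetic defaults are
#' the rescaled Drosophila-like design: N = 1000 diploids, mu = 2.0e-5,
#' rec = 2.8e-6 per site per generation, 3000 generations, 20 diploid
#' samples; reads 150 bp with 300 +/- 30 bp inserts at 20x; divergence
#' grid {0, 0.005, 0.01, 0.015, 0.02}; QUAL threshold 20 and the standard
#' hard-filter thresholds. The genome length is a desk-scale choice (the
#' design scales linearly in L); pass a larger L for heavier runs.
#'
#' @param sim a \code{\link{sim_params}} object.
#' @param d_grid divergence fractions to benchmark across.
#' @param read a \code{\link{read_sim_params}} or NULL.
#' @param profiles named list of \code{\link{emulator_params}}, one per
#'   emulated caller profile (at least one).
#' @param filters filters to evaluate; subset of "none", "qual", "hard".
#' @param qual_threshold QUAL filter threshold.
#' @param hard_criteria \code{\link{hard_filter_criteria}}.
#' @param track optional \code{\link{repeat_track}}.
#' @param simulate_reads also generate FASTQ reads per individual
#'   (requires \code{out_dir}).
#' @param out_dir output directory (NULL = in-memory only).
#' @param seed global seed; propagated deterministically to every stage.
#' @return an object of class \code{benchmark_config}.
#' @export
benchmark_config <- function(sim = sim_params(L = 1e5),
                             d_grid = c(0, 0.005, 0.01, 0.015, 0.02),
                             read = NULL,
                             profiles = list(default = emulator_params()),
                             filters = c("none", "qual", "hard"),
                             qual_threshold = 20,
                             hard_criteria = hard_filter_criteria(),
                             track = NULL,
                             simulate_reads = FALSE,
                             out_dir = NULL,
                             seed = 1L) {
  stopifnot(inherits(sim, "sim_params"))
  if (any(d_grid < 0 | d_grid >= 1)) stopf("d_grid values must be in [0, 1)")
  if (length(profiles) < 1L) stopf("at least one caller profile required")
  if (is.null(names(profiles)) || any(names(profiles) == ""))
    names(profiles) <- paste0("profile", seq_along(profiles))
  filters <- match.arg(filters, c("none", "qual", "hard"), several.ok = TRUE)
  if (simulate_reads && is.null(read)) read <- read_sim_params()
  structure(list(sim = sim, d_grid = d_grid, read = read,
                 profiles = profiles, filters = filters,
                 qual_threshold = qual_threshold,
                 hard_criteria = hard_criteria, track = track,
                 simulate_reads = simulate_reads, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "benchmark_config")
}

bench_log <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full benchmark pipeline
#'
#' Executes simulate -> derive truth P -> forge a diverged reference per d
#' -> (optionally) simulate reads -> emulate each caller profile ->
#' evaluate raw and filtered calls -> stratify false positives ->
#' score diagnostics -> Spearman trends against d. With \code{out_dir}
#' set, truth files (TSV, VCF, FASTA), per-condition VCFs, the metrics
#' table, a JSON report, a file manifest and a stage log are written;
#' report content is fully determined by (config, seed).
#'
#' @param config a \code{\link{benchmark_config}}.
#' @return an object of class \code{benchmark_report}: list with
#'   \code{metrics} (one row per profile x d x filter), \code{diagnostics}
#'   (per profile x d), \code{trends} (per profile x filter x metric),
#'   \code{strat} (per profile x d FP counts by repeat class, when a
#'   track is configured), \code{ratio_tables} (caller-vs-caller ratio
#'   tables per d when two or more profiles are configured),
#'   \code{truth_p}, and \code{config}.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  out_dir <- config$out_dir
  log_con <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log_con <- file(file.path(out_dir, "log.txt"), "w")
    on.exit(close(log_con), add = TRUE)
  }
  manifest <- character(0)
  emit <- function(path) manifest <<- c(manifest, path)
  t_start <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    bench_log(log_con, "[%s] done in %.1fs", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  sim <- config$sim
  sim$seed <- derive_seed(config$seed, 1L)
  state <- stage("simulate", run_wright_fisher(sim))
  smp <- stage("sample", sample_population(state, seed = derive_seed(config$seed, 2L)))
  truth_p <- stage("truth_p", derive_truth_p(smp))
  L <- sim$L

  if (!is.null(out_dir)) {
    emit(write_fasta(state$ancestral, file.path(out_dir, "ancestral.fasta"),
                     name = "chr1"))
    emit(write_truth_p_tsv(truth_p, file.path(out_dir, "truth_p.tsv")))
    emit(write_truth_vcf(truth_p, file.path(out_dir, "truth_p.vcf"),
                         L = L))
  }

  refs <- stage("forge_references", lapply(seq_along(config$d_grid), function(i) {
    inject_divergence(state$ancestral, config$d_grid[i],
                      excluded_positions = truth_p$pos,
                      seed = derive_seed(config$seed, 10L + i))
  }))
  if (!is.null(out_dir)) {
    for (i in seq_along(refs)) {
      tag <- sprintf("d%g", config$d_grid[i])
      emit(write_fasta(refs[[i]], file.path(out_dir, paste0("ref_", tag, ".fasta")),
                       name = "chr1"))
      emit(write_truth_d_tsv(refs[[i]]$truth_d,
                             file.path(out_dir, paste0("truth_d_", tag, ".tsv"))))
      emit(write_truth_vcf(refs[[i]]$truth_d,
                           file.path(out_dir, paste0("truth_d_", tag, ".vcf")),
                           L = L))
    }
  }

  if (config$simulate_reads) {
    if (is.null(out_dir)) stopf("simulate_reads requires out_dir")
    stage("sim_reads", {
      genomes <- build_diploid_sequences(smp)
      for (i in seq_len(smp$n_sample)) {
        pr <- simulate_read_pairs(genomes[c(2L * i - 1L, 2L * i)],
                                  config$read, ind_id = paste0("ind", i),
                                  seed = derive_seed(config$seed, 100L + i))
        for (p in write_fastq_pair(pr, file.path(out_dir, paste0("ind", i))))
          emit(p)
      }
    })
  }

  metrics <- list(); diagnostics <- list(); strat <- list()
  k <- 0L
  for (pi_ in seq_along(config$profiles)) {
    pname <- names(config$profiles)[pi_]
    for (di in seq_along(config$d_grid)) {
      d <- config$d_grid[di]
      calls <- stage(sprintf("emulate_%s_d%g", pname, d),
        emulate_caller(truth_p, refs[[di]]$truth_d, L,
                       config$profiles[[pi_]], repeat_track = config$track,
                       d_level = d,
                       seed = derive_seed(config$seed, 1000L + 100L * pi_ + di)))
      if (!is.null(out_dir))
        emit(write_calls_vcf(calls,
          file.path(out_dir, sprintf("calls_%s_d%g.vcf", pname, d))))
      for (f in config$filters) {
        em <- evaluate_calls(calls, truth_p, refs[[di]]$truth_d, filter = f,
                             qual_threshold = config$qual_threshold,
                             hard_criteria = config$hard_criteria)
        k <- k + 1L
        metrics[[k]] <- cbind(profile = pname, d = d, as.data.frame(em))
        if (f == "none") {
          cl <- attr(em, "classification")
          diag <- score_diagnostics(cl)
          diagnostics[[length(diagnostics) + 1L]] <- data.frame(
            profile = pname, d = d,
            qd_coefficient = diag$qd$coefficient,
            qd_bimodal = diag$qd$is_bimodal,
            mq_below_tpp = diag$mq_below[["TPP"]],
            mq_below_tpd = diag$mq_below[["TPD"]],
            mq_below_fp = diag$mq_below[["FP"]])
          if (!is.null(config$track)) {
            cnt <- stratify_fp_counts(cl, config$track)
            strat[[length(strat) + 1L]] <- data.frame(
              profile = pname, d = d,
              repeat_class = names(cnt), count = unname(cnt))
          }
        }
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  diagnostics <- do.call(rbind, diagnostics)
  strat <- if (length(strat)) do.call(rbind, strat) else NULL

  trends <- list()
  if (length(config$d_grid) >= 3L) {
    for (pname in names(config$profiles)) {
      for (f in config$filters) {
        sub <- metrics[metrics$profile == pname & metrics$filter_label == f, ]
        for (m in c("recovery", "fp_proportion")) {
          tr <- spearman_trend(sub$d, sub[[m]])
          trends[[length(trends) + 1L]] <- data.frame(
            profile = pname, filter_label = f, metric = m,
            rho = tr$rho, p_value = tr$p_value, n = tr$n)
        }
      }
    }
  }
  trends <- if (length(trends)) do.call(rbind, trends) else NULL

  ratio_tables <- NULL
  if (length(config$profiles) >= 2L && !is.null(strat)) {
    ratio_tables <- lapply(config$d_grid, function(d) {
      a <- strat[strat$profile == names(config$profiles)[1] & strat$d == d, ]
      b <- strat[strat$profile == names(config$profiles)[2] & strat$d == d, ]
      ratio_table(stats::setNames(a$count, a$repeat_class),
                  stats::setNames(b$count, b$repeat_class))
    })
    names(ratio_tables) <- sprintf("d%g", config$d_grid)
  }

  report <- structure(list(metrics = metrics, diagnostics = diagnostics,
                           trends = trends, strat = strat,
                           ratio_tables = ratio_tables,
                           truth_p = truth_p, config = config),
                      class = "benchmark_report")
  if (!is.null(out_dir)) {
    mp <- file.path(out_dir, "metrics.tsv")
    utils::write.table(metrics, mp, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(mp)
    rp <- file.path(out_dir, "report.json")
    jsonlite::write_json(
      list(metrics = metrics, diagnostics = diagnostics, trends = trends,
           strat = strat, ratio_tables = ratio_tables),
      rp, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    emit(rp)
    writeLines(sort(basename(manifest)), file.path(out_dir, "manifest.txt"))
    bench_log(log_con, "benchmark complete in %.1fs, %d files written",
              as.numeric(difftime(Sys.time(), t_start, units = "secs")),
              length(manifest) + 1L)
  }
  report
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("Benchmark report: %d profiles x %d d levels x %d filters\n",
              length(x$config$profiles), length(x$config$d_grid),
              length(x$config$filters)))
  cols <- c("profile", "d", "filter_label", "n_calls", "recovery",
            "fp_proportion", "f_score")
  print(x$metrics[, cols], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Evaluate an externally produced VCF against pipeline truth files
#'
#' Entry point for benchmarking a real caller: consumes the caller's VCF
#' plus the truth files this pipeline wrote, and runs the evaluator,
#' repeat stratification and score diagnostics for each requested filter.
#'
#' @param vcf path to the caller's VCF (or a \code{vcf_calls} table).
#' @param truth_p path to the truth-P TSV (or a \code{truth_p} object).
#' @param truth_d path to the truth-D TSV (or a \code{truth_d} object),
#'   optional.
#' @param track a \code{repeat_track} or BED/rmsk path, optional.
#' @param filters subset of "none", "qual", "hard".
#' @param qual_threshold QUAL threshold.
#' @param hard_criteria \code{hard_filter_criteria}.
#' @return list with \code{metrics} (rows per filter), \code{diagnostics}
#'   and \code{strat} (unfiltered classification; NULL without a track).
#' @export
evaluate_external <- function(vcf, truth_p, truth_d = NULL, track = NULL,
                              filters = c("none", "qual"),
                              qual_threshold = 20,
                              hard_criteria = hard_filter_criteria()) {
  calls <- if (is.character(vcf)) read_calls_vcf(vcf) else vcf
  if (is.character(truth_p)) truth_p <- read_truth_p_tsv(truth_p)
  if (is.character(truth_d)) truth_d <- read_truth_d_tsv(truth_d)
  if (is.character(track)) track <- repeat_track(track)
  rows <- list(); diag <- NULL; strat <- NULL
  for (f in filters) {
    em <- evaluate_calls(calls, truth_p, truth_d, filter = f,
                         qual_threshold = qual_threshold,
                         hard_criteria = hard_criteria)
    rows[[f]] <- as.data.frame(em)
    if (f == "none") {
      cl <- attr(em, "classification")
      diag <- score_diagnostics(cl)
      if (!is.null(track))
        strat <- stratify_fp_counts(cl, track,
                                    chrom = if (nrow(calls)) calls$chrom[1] else "chr1")
    }
  }
  list(metrics = do.call(rbind, rows), diagnostics = diag, strat = strat)
}
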