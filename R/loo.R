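#' Leave-one-out genotyping benchmark
#'
#' For each diploid sample of a simulated truth set: remove the sample's
#' two haplotypes from the panel; drop variants carried by neither the
#' held-out haplotypes nor the remaining panel; build the pangenome graph
#' from the remaining haplotypes; simulate (or reuse) reads for the
#' sample; count spaced k-mers with each seed under test; genotype; and
#' score against the held-out truth, overall and per variant size class.
#'
#' @param truth A `simulated_truth` from [simulate_panel()].
#' @param seeds_to_test List of seeds (or pattern strings), named or not.
#' @param params_fn Function `seed -> genotyping_params`; defaults to
#'   auto-estimated coverage with default `epsilon` and `rho`.
#' @param samples Sample indices to run (default: all).
#' @param reads Optional list of read vectors per sample index; generated
#'   with [simulate_reads()] when missing.
#' @return Data frame with one row per (sample, seed, variant class —
#'   including `"all"`): tallies, precision/recall/F, wGC and the number
#'   of undefined calls.
#' @export
leave_one_out_run <- function(truth, seeds_to_test,
                              params_fn = function(seed) genotyping_params(seed),
                              samples = seq_along(truth$samples),
                              reads = NULL) {
  if (length(truth$samples) < 2L) stop("leave-one-out needs at least 2 samples")
  seeds_to_test <- lapply(seeds_to_test, as_seed)
  if (is.null(names(seeds_to_test)) || any(!nzchar(names(seeds_to_test))))
    names(seeds_to_test) <- vapply(seeds_to_test, function(s) s$pattern, "")
  rows <- list()
  for (s in samples) {
    hap_cols <- c(2L * s - 1L, 2L * s)
    held <- truth$panel[, hap_cols, drop = FALSE]
    rest <- truth$panel[, -hap_cols, drop = FALSE]
    keep <- rowSums(held) > 0L | rowSums(rest) > 0L
    variants <- truth$variants[keep, , drop = FALSE]
    panel <- list(variants = variants, hap = rest[keep, , drop = FALSE])
    tcs <- truth_callset(truth, s)[keep, , drop = FALSE]
    universe <- variants
    rds <- if (!is.null(reads)) reads[[s]] else
      simulate_reads(haplotype_sequence(truth, 2L * s - 1L),
                     haplotype_sequence(truth, 2L * s),
                     truth$config,
                     rng_seed = truth$config$rng_seed + 1000L * s)
    cls <- variant_class(variants)
    for (sn in names(seeds_to_test)) {
      seed <- seeds_to_test[[sn]]
      graph <- build_graph(truth$reference, panel, seed)
      counts <- count_reads(rds, seed)
      calls <- genotype(graph, counts, params_fn(seed))
      pred <- calls_to_callset(calls, graph)
      for (vc in c("all", unique(cls))) {
        in_cls <- if (vc == "all") rep(TRUE, nrow(universe)) else cls == vc
        key <- site_key(universe[in_cls, , drop = FALSE])
        res <- compare_callsets(
          tcs[site_key(tcs) %in% key, , drop = FALSE],
          pred[site_key(pred) %in% key, , drop = FALSE],
          universe[in_cls, , drop = FALSE])
        m <- precision_recall_f(res)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = truth$samples[s], seed = sn, class = vc,
          n_sites = sum(in_cls), TP = res$TP, FP = res$FP, FN = res$FN,
          precision = m[["precision"]], recall = m[["recall"]], F = m[["F"]],
          wGC = weighted_genotype_concordance(res),
          undefined = sum(is.na(pred$gt[site_key(pred) %in% key])),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Paired Wilcoxon tests across samples for a seed comparison
#'
#' For each variant class and metric in a [leave_one_out_run()] report,
#' pairs the per-sample values of two seeds and applies the exact
#' two-sided Wilcoxon signed-rank test.
#'
#' @param report Output of [leave_one_out_run()].
#' @param seed_a,seed_b Seed names as they appear in the report.
#' @param metrics Metric columns to test.
#' @return Data frame of (class, metric, mean_a, mean_b, p.value); p is
#'   `NA` when all per-sample differences are zero.
#' @export
loo_wilcoxon <- function(report, seed_a, seed_b,
                         metrics = c("precision", "recall", "F", "wGC")) {
  rows <- list()
  for (vc in unique(report$class)) for (m in metrics) {
    a <- report[report$class == vc & report$seed == seed_a, ]
    b <- report[report$class == vc & report$seed == seed_b, ]
    b <- b[match(a$sample, b$sample), ]
    p <- tryCatch(wilcoxon_exact(a[[m]], b[[m]])$p.value,
                  error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      class = vc, metric = m, mean_a = mean(a[[m]]), mean_b = mean(b[[m]]),
      p.value = p, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
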