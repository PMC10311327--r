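#' Compare a predicted callset against truth
#'
#' Strict benchmarking: sites are matched by (chrom, pos, ref, alt) within
#' a fixed universe of known variants; genotypes are compared unordered and
#' unphased.  A site whose truth genotype is undefined is removed from both
#' sets.  A matching non-absent genotype is a TP; a non-absent truth
#' genotype that is missed, called absent, called undefined or mismatched
#' is an FN; a non-absent prediction at a truth-absent site, or a genotype
#' mismatch at a non-absent truth site, is an FP (so one mismatch costs one
#' FN *and* one FP).  Per-genotype-class tallies (`0|0`, `0|1`, `1|1`,
#' classed by the truth genotype's count of reference alleles) record
#' correct (`T`) versus incorrect-or-undefined (`F`) calls.
#'
#' @param truth,predicted Callset data frames with columns `chrom`, `pos`,
#'   `ref`, `alt`, `gt`.  `gt` is an unphased genotype string such as
#'   `"0/1"`; `NA` means undefined.  Sites absent from a callset are
#'   treated as absent (`"0/0"`).
#' @param universe Data frame of known-variant sites (`chrom`, `pos`,
#'   `ref`, `alt`); both callsets must be subsets of it.
#' @return A `comparison_result`: list with `TP`, `FP`, `FN`, per-class
#'   vectors `T` and `F`, and `n_removed_undefined_truth`.
#' @export
compare_callsets <- function(truth, predicted, universe) {
  ukey <- site_key(universe)
  if (anyDuplicated(ukey)) stop("duplicate sites in universe")
  tkey <- site_key(truth)
  pkey <- site_key(predicted)
  if (!all(pkey %in% ukey)) stop("predicted callset contains sites outside the universe")
  if (!all(tkey %in% ukey)) stop("truth callset contains sites outside the universe")

  t_gt <- normalize_gt(truth$gt)[match(ukey, tkey)]
  t_gt[is.na(match(ukey, tkey))] <- "0/0"       # not in truth set -> absent
  t_undef <- ukey %in% tkey[is.na(truth$gt)]    # undefined in truth -> drop site
  p_gt <- normalize_gt(predicted$gt)[match(ukey, pkey)]
  p_gt[is.na(match(ukey, pkey))] <- "0/0"

  t_gt <- t_gt[!t_undef]
  p_gt <- p_gt[!t_undef]

  p_def <- !is.na(p_gt)
  t_nonabs <- t_gt != "0/0"
  correct <- p_def & p_gt == t_gt

  TP <- sum(t_nonabs & correct)
  FN <- sum(t_nonabs & !correct)
  FP <- sum(p_def & p_gt != "0/0" & (!t_nonabs | p_gt != t_gt))

  cls <- genotype_class(t_gt)
  levels <- c("0|0", "0|1", "1|1")
  Tc <- vapply(levels, function(k) sum(cls == k & correct), numeric(1))
  Fc <- vapply(levels, function(k) sum(cls == k & !correct), numeric(1))

  structure(list(TP = TP, FP = FP, FN = FN, T = Tc, F = Fc,
                 n_removed_undefined_truth = sum(t_undef)),
            class = "comparison_result")
}

site_key <- function(df) {
  if (!nrow(df)) return(character(0))
  paste(df$chrom, df$pos, df$ref, df$alt, sep = "\r")
}

# sort alleles within the genotype: "1/0" and "0|1" both become "0/1"
normalize_gt <- function(gt) {
  vapply(gt, function(g) {
    if (is.na(g) || g %in% c("./.", ".")) return(NA_character_)
    a <- sort(strsplit(g, "[/|]")[[1L]])
    paste(a, collapse = "/")
  }, character(1L), USE.NAMES = FALSE)
}

# class by number of reference alleles in the truth genotype
genotype_class <- function(gt) {
  nref <- vapply(strsplit(gt, "/", fixed = TRUE),
                 function(a) sum(a == "0"), numeric(1L))
  c("1|1", "0|1", "0|0")[nref + 1L]
}

#' @export
print.comparison_result <- function(x, ...) {
  m <- precision_recall_f(x)
  cat(sprintf("<comparison: TP=%d FP=%d FN=%d | precision=%.4f recall=%.4f F=%.4f wGC=%.4f>\n",
              x$TP, x$FP, x$FN, m["precision"], m["recall"], m["F"],
              weighted_genotype_concordance(x)))
  invisible(x)
}

#' Precision, recall and F-score
#'
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `F = 2*precision*recall/(precision+recall)`; any 0/0 ratio is 0.
#'
#' @param result A `comparison_result`.
#' @return Named numeric vector `precision`, `recall`, `F`.
#' @export
precision_recall_f <- function(result) {
  safe <- function(num, den) if (den == 0) 0 else num / den
  recall <- safe(result$TP, result$TP + result$FN)
  precision <- safe(result$TP, result$TP + result$FP)
  f <- safe(2 * precision * recall, precision + recall)
  c(precision = precision, recall = recall, F = f)
}

#' Weighted genotype concordance
#'
#' Mean over genotype classes of `conc(x|y) = T_x|y / (T_x|y + F_x|y)`,
#' correcting for the dominance of absent (`0|0`) sites in panel-wide
#' callsets.  Classes with no sites are excluded from the mean.
#'
#' @param result A `comparison_result`.
#' @return wGC in `[0,1]`.
#' @export
weighted_genotype_concordance <- function(result) {
  tot <- result$T + result$F
  if (all(tot == 0)) stop("all genotype classes are empty")
  conc <- (result$T / tot)[tot > 0]
  mean(conc)
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided exact test for paired data at small n.  Zero differences are
#' dropped; absolute differences are ranked with average ranks on ties; the
#' exact null distribution of the positive-rank sum W is obtained by
#' enumerating all `2^n` sign assignments (as a generating-function
#' convolution, so ties are handled exactly);
#' `p = min(1, 2*min(P(W <= w), P(W >= w)))`.
#'
#' @param x First measurement vector, or the differences if `y` is `NULL`.
#' @param y Optional second measurement vector, paired with `x`.
#' @return List with `statistic` (W), `n` (non-zero pairs) and `p.value`.
#' @examples
#' wilcoxon_exact(rep(1, 9))$p.value  # 2 * 2^-9
#' @export
wilcoxon_exact <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  if (n > 25) stop("exact enumeration limited to 25 non-zero pairs")
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))          # doubled ranks are integers even with ties
  total <- sum(r2)
  f <- c(1, numeric(total))               # f[s+1] = #assignments with doubled sum s
  for (ri in r2) {
    shifted <- c(numeric(ri), f[seq_len(total + 1L - ri)])
    f <- f + shifted
  }
  f <- f / 2^n
  w2 <- as.integer(round(2 * w_obs))
  p_le <- sum(f[seq_len(w2 + 1L)])
  p_ge <- sum(f[(w2 + 1L):(total + 1L)])
  list(statistic = w_obs, n = n, p.value = min(1, 2 * min(p_le, p_ge)))
}

#' Bonferroni upper bound on a corrected p-value
#'
#' @param p Uncorrected p-value.
#' @param m Number of tests, `m >= 1`.
#' @return `min(1, m * p)`.
#' @examples
#' bonferroni_bound(0.004, 24)  # 0.096
#' @export
bonferroni_bound <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

#' Correlation of metric improvements over a shared baseline
#'
#' Pearson correlation of `results_a - results_baseline` with
#' `results_b - results_baseline`, for metric vectors aligned by
#' (sample, variant class, metric).  High correlation indicates the two
#' methods improve on the baseline in the same places.
#'
#' @param results_a,results_b,results_baseline Equal-length numeric vectors.
#' @return Pearson correlation coefficient.
#' @export
improvement_correlation <- function(results_a, results_b, results_baseline) {
  stopifnot(length(results_a) == length(results_b),
            length(results_a) == length(results_baseline),
            length(results_a) >= 2)
  da <- results_a - results_baseline
  db <- results_b - results_baseline
  if (stats::sd(da) == 0 || stats::sd(db) == 0)
    stop("zero variance in a difference vector")
  cor(da, db)
}
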