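#' Spearman redundancy screen over a feature table
#'
#' Computes pairwise Spearman rank correlations (pairwise-complete
#' observations) between all numeric feature columns and flags pairs with
#' `rho > threshold` as redundant. Constant features have undefined
#' correlations and are reported as `NA`, never silently dropped.
#'
#' @param data Data frame of patients by features; non-numeric columns are
#'   ignored.
#' @param threshold Redundancy threshold on the correlation coefficient
#'   (flag when `rho > 0.75` by default; strongly negative pairs are not
#'   flagged).
#' @param min_pairs Minimum number of complete pairs required for a
#'   coefficient; pairs with fewer are reported as `NA`.
#' @return A `spearman_screen` tibble with one row per feature pair
#'   (`feature_a`, `feature_b`, `rho`, `n_pairs`, `flagged`); the full
#'   correlation matrix is available as `attr(., "matrix")`.
#' @export
spearman_screen <- function(data, threshold = 0.75, min_pairs = 3) {
  num <- data[vapply(data, is.numeric, logical(1))]
  if (ncol(num) < 2) abort_data("need at least two numeric features to screen")
  m <- suppressWarnings(
    stats::cor(as.matrix(num), method = "spearman", use = "pairwise.complete.obs")
  )
  nm <- names(num)
  pairs <- utils::combn(nm, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    n_pairs <- sum(stats::complete.cases(num[[a]], num[[b]]))
    rho <- if (n_pairs < min_pairs) NA_real_ else m[a, b]
    tibble::tibble(feature_a = a, feature_b = b, rho = rho, n_pairs = n_pairs,
                   flagged = !is.na(rho) & rho > threshold)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "matrix") <- m
  attr(out, "threshold") <- threshold
  class(out) <- c("spearman_screen", class(out))
  out
}

as_group_summary <- function(x, name) {
  if (is.list(x) || !is.null(names(x))) {
    x <- unlist(x)
    if (!all(c("mean", "sd", "n") %in% names(x))) {
      abort_config(sprintf("`%s` summary must have elements mean, sd and n", name))
    }
    return(c(mean = unname(x[["mean"]]), sd = unname(x[["sd"]]), n = unname(x[["n"]])))
  }
  if (!is.numeric(x) || length(x) == 0) {
    abort_config(sprintf("`%s` must be raw values or c(mean=, sd=, n=)", name))
  }
  c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0, n = length(x))
}

#' Welch two-sample t-test with Bonferroni adjustment
#'
#' Compares the plateau-time feature between outcome groups using the
#' unequal-variance (Welch) t statistic with Welch--Satterthwaite degrees of
#' freedom. The statistic is oriented as negative-group mean minus
#' positive-group mean, so a healing-associated increase yields a negative
#' t. Groups may be given as raw values or as `c(mean=, sd=, n=)` summaries
#' (the published group summaries are sufficient input). The two-sided p
#' value is Bonferroni-adjusted for `bonferroni_m` independent features
#' (default 3, the three patch-mean difference features).
#'
#' @param positive,negative Raw numeric values or `c(mean=, sd=, n=)` for the
#'   positive- and negative-outcome groups.
#' @param bonferroni_m Bonferroni multiplier.
#' @return A `welch_test` object; see [tidy.welch_test()].
#' @examples
#' welch_test(c(mean = 6.7, sd = 9.3, n = 9), c(mean = -7.1, sd = 4.3, n = 5))
#' @export
welch_test <- function(positive, negative, bonferroni_m = 3) {
  a <- as_group_summary(positive, "positive")
  b <- as_group_summary(negative, "negative")
  if (a[["n"]] < 2 || b[["n"]] < 2) abort_data("each group needs n >= 2")
  if (a[["sd"]] <= 0 && b[["sd"]] <= 0) abort_data("both group SDs are zero")
  if (!is_scalar_number(bonferroni_m) || bonferroni_m < 1) {
    abort_config("`bonferroni_m` must be >= 1")
  }
  va <- a[["sd"]]^2 / a[["n"]]
  vb <- b[["sd"]]^2 / b[["n"]]
  t_stat <- (b[["mean"]] - a[["mean"]]) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a[["n"]] - 1) + vb^2 / (b[["n"]] - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  structure(
    list(mean_positive = a[["mean"]], mean_negative = b[["mean"]],
         sd_positive = a[["sd"]], sd_negative = b[["sd"]],
         n_positive = a[["n"]], n_negative = b[["n"]],
         statistic = t_stat, df = df,
         p_value = p, p_adjusted = min(1, bonferroni_m * p),
         bonferroni_m = bonferroni_m),
    class = "welch_test"
  )
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf(
    "Welch t-test (negative - positive): t = %.2f, df = %.1f, p = %.4g (Bonferroni x%d: %.4g)\n",
    x$statistic, x$df, x$p_value, x$bonferroni_m, x$p_adjusted))
  cat(sprintf("  positive: %.2f +/- %.2f (n = %d); negative: %.2f +/- %.2f (n = %d)\n",
              x$mean_positive, x$sd_positive, x$n_positive,
              x$mean_negative, x$sd_negative, x$n_negative))
  invisible(x)
}

#' ROC analysis with Youden-index cutoff selection
#'
#' Builds the ROC curve of a single continuous feature against binary
#' outcomes on a threshold grid at the midpoints between adjacent distinct
#' scores (plus sentinels at plus/minus infinity). The AUC is the
#' Mann--Whitney probability that a positive outscores a negative (ties
#' count one half). The operating cutoff maximizes the Youden index
#' `J = Se + Sp - 1`; ties are broken by the point closest to the ideal
#' (0, 1) corner of ROC space and then by the larger cutoff.
#'
#' @param scores Continuous feature values (e.g. the follow-up minus
#'   postintervention plateau-time difference). `NA` pairs are dropped.
#' @param labels Binary outcomes (1/TRUE = positive outcome).
#' @param direction `">="` if larger scores indicate a positive outcome
#'   (default; patients are predicted to worsen below the cutoff), `"<="`
#'   for the reverse.
#' @return A `roc_result`: threshold grid with per-threshold `se`, `sp`,
#'   `j`; `auc`; the optimal `cutoff` with its `se`/`sp`; class counts.
#' @examples
#' roc_analysis(c(2, 3, 4, 0, 1), c(1, 1, 1, 0, 0))
#' @export
roc_analysis <- function(scores, labels, direction = c(">=", "<=")) {
  direction <- match.arg(direction)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as_binary_labels(labels[keep])
  if (length(scores) == 0) abort_data("no complete score/label pairs")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) abort_data("both outcome classes must be present")

  s <- if (direction == "<=") -scores else scores
  u <- sort(unique(s))
  thr <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, Inf)

  tp <- vapply(thr, function(ct) sum(s[labels == 1] >= ct), numeric(1))
  tn <- vapply(thr, function(ct) sum(s[labels == 0] < ct), numeric(1))
  se <- tp / n_pos
  sp <- tn / n_neg
  j <- se + sp - 1

  # Mann-Whitney AUC via midranks (ties count 1/2)
  r <- rank(s)
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  # tie-breaking on exact integer arithmetic so mathematically equal Youden
  # indices are true ties: J ~ tp*n_neg + tn*n_pos, distance to (0, 1) ~
  # (fp*n_pos)^2 + (fn*n_neg)^2 on the common denominator
  j_num <- tp * n_neg + tn * n_pos
  d2_num <- ((n_neg - tn) * n_pos)^2 + ((n_pos - tp) * n_neg)^2
  best <- order(-j_num, d2_num, -thr)[1]

  to_original <- function(ct) if (direction == "<=") -ct else ct
  curve <- tibble::tibble(threshold = vapply(thr, to_original, numeric(1)),
                          se = se, sp = sp, j = j)
  structure(
    list(curve = curve, auc = auc,
         cutoff = to_original(thr[best]),
         se = se[best], sp = sp[best], j = j[best],
         direction = direction, n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.character(labels)
  u <- sort(unique(labels))
  if (is.numeric(labels)) {
    if (!all(u %in% c(0, 1))) abort_data("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  if (length(u) != 2) abort_data("labels must have exactly two levels")
  as.integer(labels == u[2])
}

#' Predict outcomes from a ROC cutoff
#'
#' @param object A `roc_result`.
#' @param scores New feature values.
#' @param ... Unused.
#' @return Integer 0/1 predictions (`NA` propagated).
#' @export
predict.roc_result <- function(object, scores, ...) {
  if (object$direction == ">=") {
    ifelse(is.na(scores), NA_integer_, as.integer(scores >= object$cutoff))
  } else {
    ifelse(is.na(scores), NA_integer_, as.integer(scores <= object$cutoff))
  }
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d positive vs %d negative)\n", x$auc, x$n_pos, x$n_neg))
  cat(sprintf("Youden cutoff: predict positive when score %s %.3f (Se %.0f%%, Sp %.0f%%)\n",
              x$direction, x$cutoff, 100 * x$se, 100 * x$sp))
  invisible(x)
}

#' Diagnostic confusion metrics
#'
#' Counts true/false positives and negatives of a binary prediction against
#' the clinical outcome and derives sensitivity, specificity, positive and
#' negative predictive value, both as proportions and as percentages rounded
#' half-up to the nearest integer.
#'
#' @param predicted,truth Equal-length binary (0/1 or logical) vectors
#'   without missing values.
#' @return A `confusion_metrics` object.
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
confusion_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) == 0) {
    abort_data("`predicted` and `truth` must be non-empty and equal length")
  }
  if (anyNA(predicted) || anyNA(truth)) {
    abort_data("missing values are not allowed; subset to available patients first")
  }
  p <- as_binary_labels(predicted)
  t <- as_binary_labels(truth)
  tp <- sum(p == 1 & t == 1); fp <- sum(p == 1 & t == 0)
  tn <- sum(p == 0 & t == 0); fn <- sum(p == 0 & t == 1)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  se <- rate(tp, tp + fn); sp <- rate(tn, tn + fp)
  ppv <- rate(tp, tp + fp); npv <- rate(tn, tn + fn)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         se = se, sp = sp, ppv = ppv, npv = npv,
         se_pct = round_half_up(100 * se), sp_pct = round_half_up(100 * sp),
         ppv_pct = round_half_up(100 * ppv), npv_pct = round_half_up(100 * npv),
         n = length(t), misclassified = fp + fn),
    class = "confusion_metrics"
  )
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("confusion: TP %d FP %d TN %d FN %d (n = %d)\n", x$tp, x$fp, x$tn, x$fn, x$n))
  cat(sprintf("Se %g%%, Sp %g%%, PPV %g%%, NPV %g%%\n",
              x$se_pct, x$sp_pct, x$ppv_pct, x$npv_pct))
  invisible(x)
}

#' Two-group sample size for a standardized mean difference
#'
#' Per-group size `n = ceiling(2 * (z_{1-alpha/2} + z_{1-beta})^2 / delta^2)`
#' for detecting a difference of `delta` common standard deviations between
#' two equal groups; the total is twice that. With `alpha = 0.05`,
#' `beta = 0.04` and a one-SD effect this gives 28 patients per group, 56 in
#' total.
#'
#' @param alpha Two-sided type-I error rate.
#' @param beta Type-II error rate (power is `1 - beta`).
#' @param effect_sd Effect size in units of the common standard deviation.
#' @return A one-row tibble: `alpha`, `beta`, `effect_sd`, `z_alpha`,
#'   `z_beta`, `n_per_group`, `n_total`.
#' @export
sample_size <- function(alpha = 0.05, beta = 0.04, effect_sd = 1) {
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    abort_config("`alpha` must be in (0, 1)")
  }
  if (!is_scalar_number(beta) || beta <= 0 || beta >= 1) {
    abort_config("`beta` must be in (0, 1)")
  }
  stopifnot_scalar_positive(effect_sd, "effect_sd")
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(1 - beta)
  if (!is.finite(za) || !is.finite(zb)) abort_config("normal quantiles are not finite")
  n_per <- ceiling(2 * (za + zb)^2 / effect_sd^2)
  tibble::tibble(alpha = alpha, beta = beta, effect_sd = effect_sd,
                 z_alpha = za, z_beta = zb,
                 n_per_group = n_per, n_total = 2 * n_per)
}

#' Full statistical analysis of a per-patient feature table
#'
#' Reproduces the statistical layer on a feature table: Spearman redundancy
#' screen across the six difference features, Welch t-tests (negative minus
#' positive) with Bonferroni correction for the three patch-mean (Gen)
#' difference features, and ROC/Youden cutoff selection plus confusion
#' metrics for the follow-up minus postintervention feature.
#'
#' @param features Tibble from [patient_features()] (needs `outcome` and the
#'   difference-feature columns).
#' @param bonferroni_m Bonferroni multiplier for the t-tests.
#' @param cor_threshold Redundancy threshold for the Spearman screen.
#' @param roc_feature Feature used for classification.
#' @return A `cohort_analysis` object: `screen`, `tests` (tidy tibble),
#'   `roc`, `confusion`, and the classified feature name.
#' @export
analyze_features <- function(features, bonferroni_m = 3, cor_threshold = 0.75,
                             roc_feature = "fu1post_gen") {
  diff_cols <- intersect(
    c("postpre_gen", "fu1pre_gen", "fu1post_gen",
      "postpre_loc", "fu1pre_loc", "fu1post_loc"),
    names(features))
  gen_cols <- grep("_gen$", diff_cols, value = TRUE)
  if (!roc_feature %in% names(features)) {
    abort_config(sprintf("feature '%s' not present in the table", roc_feature))
  }
  screen <- spearman_screen(features[diff_cols], threshold = cor_threshold)

  tests <- dplyr::bind_rows(lapply(gen_cols, function(col) {
    pos <- features[[col]][features$outcome == 1]
    neg <- features[[col]][features$outcome == 0]
    wt <- welch_test(pos[!is.na(pos)], neg[!is.na(neg)], bonferroni_m = bonferroni_m)
    dplyr::mutate(tidy(wt), feature = col, .before = 1)
  }))

  roc <- roc_analysis(features[[roc_feature]], features$outcome, direction = ">=")
  scores <- features[[roc_feature]]
  ok <- !is.na(scores) & !is.na(features$outcome)
  confusion <- confusion_metrics(predict(roc, scores[ok]), features$outcome[ok])

  structure(
    list(screen = screen, tests = tests, roc = roc, confusion = confusion,
         roc_feature = roc_feature, n = nrow(features)),
    class = "cohort_analysis"
  )
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d patients; classified on %s\n", x$n, x$roc_feature))
  print(x$tests[, c("feature", "statistic", "df", "p_value", "p_adjusted")])
  print(x$roc)
  print(x$confusion)
  invisible(x)
}
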