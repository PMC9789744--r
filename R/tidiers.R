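#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Welch test
#'
#' @param x A `welch_test`.
#' @param ... Unused.
#' @return A one-row tibble with group summaries, the t statistic,
#'   Welch--Satterthwaite df, raw and Bonferroni-adjusted p values.
#' @export
tidy.welch_test <- function(x, ...) {
  tibble::tibble(
    mean_positive = x$mean_positive, sd_positive = x$sd_positive,
    n_positive = x$n_positive,
    mean_negative = x$mean_negative, sd_negative = x$sd_negative,
    n_negative = x$n_negative,
    statistic = x$statistic, df = x$df,
    p_value = x$p_value, p_adjusted = x$p_adjusted
  )
}

#' @rdname tidy.welch_test
#' @export
glance.welch_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df,
                 p_value = x$p_value, p_adjusted = x$p_adjusted)
}

#' Tidy a ROC result
#'
#' `tidy()` returns the per-threshold operating points; `glance()` the AUC
#' and selected cutoff.
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname tidy.roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, cutoff = x$cutoff, se = x$se, sp = x$sp,
                 j = x$j, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy confusion metrics
#'
#' @param x A `confusion_metrics`.
#' @param ... Unused.
#' @return A one-row tibble of counts, rates and rounded percentages.
#' @export
tidy.confusion_metrics <- function(x, ...) {
  tibble::tibble(
    tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn, n = x$n,
    n_misclassified = x$misclassified,
    se = x$se, sp = x$sp, ppv = x$ppv, npv = x$npv,
    se_pct = x$se_pct, sp_pct = x$sp_pct, ppv_pct = x$ppv_pct,
    npv_pct = x$npv_pct
  )
}
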