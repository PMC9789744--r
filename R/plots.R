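#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a chromophore concentration time course
#'
#' Shows the oxy-, deoxy- and total-hemoglobin concentration changes over the
#' protocol, with the two cuff-inflation phases shaded when the series
#' carries its schedule.
#'
#' @param object A `chromophore_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.chromophore_series <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), c("dHbO2_uM", "dHb_uM", "dHbT_uM"),
    names_to = "chromophore", values_to = "concentration_uM")
  long$chromophore <- factor(long$chromophore,
                             levels = c("dHbT_uM", "dHbO2_uM", "dHb_uM"),
                             labels = c("HbT", "HbO2", "Hb"))
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$time_s, y = .data$concentration_uM,
                                    colour = .data$chromophore))
  sched <- attr(object, "schedule")
  if (!is.null(sched)) {
    tw <- trial_windows(sched)
    p <- p + ggplot2::annotate("rect", xmin = tw$onset_s, xmax = tw$deflation_s,
                               ymin = -Inf, ymax = Inf, alpha = 0.12)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = expression(Delta * "concentration (" * mu * "M)"),
                  colour = NULL)
}

#' Plot a ROC curve with its Youden-index operating point
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_result <- function(object, ...) {
  curve <- object$curve[order(1 - object$curve$sp, object$curve$se), ]
  ggplot2::ggplot(curve, ggplot2::aes(x = 1 - .data$sp, y = .data$se)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::annotate("point", x = 1 - object$sp, y = object$se,
                      colour = "red", size = 2) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("AUC = %.2f, cutoff = %.2f", object$auc, object$cutoff))
}

#' Spaghetti plot of plateau-time trajectories by outcome
#'
#' One line per patient across the three acquisition time points, coloured by
#' clinical outcome; the hallmark pattern is the post-to-follow-up drop in
#' the negative-outcome group.
#'
#' @param features Feature table from [patient_features()].
#' @param which `"gen"` (patch mean, default) or `"loc"`.
#' @return A ggplot.
#' @export
plot_pt_trajectories <- function(features, which = c("gen", "loc")) {
  which <- match.arg(which)
  cols <- paste0("pt_", c("pre", "post", "fu1"), "_", which)
  long <- tidyr::pivot_longer(features[c("patient_id", "outcome", cols)],
                              dplyr::all_of(cols),
                              names_to = "time_point", values_to = "pt_s")
  long$time_point <- factor(long$time_point, levels = cols,
                            labels = c("Pre", "Post", "FU1"))
  long$outcome <- factor(long$outcome, levels = c(1, 0),
                         labels = c("positive", "negative"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_point, y = .data$pt_s,
                                     group = .data$patient_id,
                                     colour = .data$outcome)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "plateau time (s)", colour = "outcome")
}
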