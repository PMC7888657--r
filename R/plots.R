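#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   scale_x_log10 scale_x_reverse labs facet_wrap theme_minimal
#'   geom_abline
NULL

#' Plot a bifurcation sweep
#'
#' Steady-state promoter activity against dissolved O2 (log scale,
#' decreasing to the right, mirroring descent into the nodule), solid lines
#' for stable branches and dashed for unstable.
#'
#' @param object A `cascade_sweep` from [sweep_bifurcation()].
#' @param reporter `"fnrN"` or `"fixNOQP"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cascade_sweep <- function(object, reporter = c("fnrN", "fixNOQP"),
                                   ...) {
  reporter <- match.arg(reporter)
  ycol <- paste0("rate_", reporter)
  ggplot(object, aes(x = .data$oxygen, y = .data[[ycol]],
                     group = .data$branch, linetype = .data$stability)) +
    geom_line() +
    scale_x_log10(transform = c("log10", "reverse")) +
    ggplot2::scale_linetype_manual(values = c(stable = "solid",
                                              unstable = "dashed")) +
    labs(x = "dissolved O2 (uM, decreasing)",
         y = paste(reporter, "promoter activity"),
         linetype = NULL) +
    theme_minimal()
}

#' Plot a nodule zone profile
#'
#' Reporter promoter activity along the nodule axis (0 = tip, 1 =
#' root-proximal core).
#'
#' @param object A `zone_profile` from [nodule_zone_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zone_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$position, y = .data$activity)) +
    geom_line() +
    facet_wrap(~reporter, scales = "free_y") +
    labs(x = "position along nodule axis (tip → root)",
         y = "promoter activity") +
    theme_minimal()
}

#' Plot commitment fractions
#'
#' Fraction of cells committed to the high-expression basin against
#' dissolved O2 (decreasing to the right).
#'
#' @param object A `commitment_result` from [commitment_fraction()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.commitment_result <- function(object, ...) {
  ggplot(object, aes(x = .data$oxygen, y = .data$fraction)) +
    geom_line() + geom_point() +
    scale_x_log10(transform = c("log10", "reverse")) +
    labs(x = "dissolved O2 (uM, decreasing)",
         y = "fraction committed to high expression") +
    theme_minimal()
}

#' Plot calibration fit quality
#'
#' Observed versus predicted values for each calibration row on log-log
#' axes with the identity line.
#'
#' @param object A `cascade_fit` from [calibrate_cascade()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cascade_fit <- function(object, ...) {
  ggplot(object$table,
         aes(x = .data$observed, y = .data$predicted,
             shape = .data$scenario)) +
    geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    geom_point(size = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    labs(x = "observed (% of WT, or fold)",
         y = "model prediction", shape = NULL) +
    theme_minimal()
}
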