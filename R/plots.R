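#' Plot a fitted standard curve
#'
#' Dilution points with the fitted Ct-vs-log10(quantity) line; the subtitle
#' reports slope, efficiency, and r-squared.
#'
#' @param object A [fit_standard_curve()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.standard_curve <- function(object, ...) {
  d <- object$fit$model
  names(d) <- c("ct", "log10_quantity")
  ggplot2::ggplot(d, ggplot2::aes(.data$log10_quantity, .data$ct)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         linetype = "dashed") +
    ggplot2::labs(
      x = "log10(template quantity, pg)", y = "Ct",
      title = if (is.na(object$amplicon)) "Standard curve"
              else paste("Standard curve:", object$amplicon),
      subtitle = sprintf("slope %.3f cycles/decade, efficiency %.3f, r² %.4f",
                         object$slope, object$efficiency, object$r_squared))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a polysome gradient distribution
#'
#' Fraction-of-total mRNA across gradient fractions, one line per amplicon,
#' with portion boundaries shaded.
#'
#' @param profile A [polysome_distribution()] result.
#' @return A ggplot.
#' @export
plot_gradient_profile <- function(profile) {
  stopifnot(inherits(profile, "gradient_profile"))
  ggplot2::ggplot(profile$distribution,
                  ggplot2::aes(.data$fraction, .data$rel_abundance,
                               colour = .data$amplicon)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$portion)) +
    ggplot2::labs(x = "Gradient fraction", y = "Fraction of total mRNA",
                  shape = "Portion", colour = "Amplicon")
}

#' Plot empty-vector-normalized fold activities
#'
#' Bar plot of mean fold with SEM error bars and significance tiers.
#'
#' @param activity A [fold_activity()] result.
#' @return A ggplot.
#' @export
plot_fold_activity <- function(activity) {
  ggplot2::ggplot(activity,
                  ggplot2::aes(.data$construct, .data$mean_fold)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_fold - .data$sem_fold,
                   ymax = .data$mean_fold + .data$sem_fold),
      width = 0.25) +
    ggplot2::geom_text(ggplot2::aes(label = .data$tier,
                                    y = .data$mean_fold + .data$sem_fold),
                       vjust = -0.5, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "EGFP MFI fold vs empty vector")
}

#' Plot per-embryo long-isoform proportions by region
#'
#' @param embryos Per-embryo tibble from [pool_isoforms()].
#' @return A ggplot.
#' @export
plot_isoform_summary <- function(embryos) {
  d <- dplyr::filter(embryos, !.data$excluded)
  ggplot2::ggplot(d, ggplot2::aes(.data$region, .data$long_proportion)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.05,
                                                            height = 0)) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Long 5' UTR isoform proportion")
}
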