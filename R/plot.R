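#' Plot expression ratios with confidence-interval bars
#'
#' One point per comparison at the back-transformed expression ratio, with
#' asymmetric error bars at the back-transformed confidence-interval bounds
#' and a horizontal reference line at ratio 1 (no change). Error bars are
#' confidence intervals, never SD or SEM: only intervals transform
#' meaningfully from the log scale. No value is recomputed here; the figure
#' displays the result objects' own fields.
#'
#' @param object a [CommonBaseTest-class], a [CommonBaseAnova-class] (its
#'   post-hoc comparisons are plotted), or a data.frame with columns
#'   \code{comparison}, \code{ratio}, \code{ratio_ci_lower},
#'   \code{ratio_ci_upper}.
#' @param path optional output file (.png/.svg/.pdf); written via
#'   [ggplot2::ggsave()].
#' @param log_scale plot the ratio axis on a log10 scale (symmetric bars).
#' @param width,height figure size in inches when \code{path} is given.
#' @return the ggplot object, invisibly when written to file.
#' @examples
#' res <- unpairedTest(c(1.1387, 0.845, 0.499, 0.699),
#'                     c(1.4077, 1.291, 1.496, 1.172))
#' plotRatios(res)
#' @export
plotRatios <- function(object, path = NULL, log_scale = FALSE,
                       width = 4, height = 4) {
  df <- ratioFrame(object)
  if (nrow(df) == 0L) stop("no comparisons to plot", call. = FALSE)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison,
                                        y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ratio_ci_lower,
                                        ymax = .data$ratio_ci_upper),
                           width = 0.15) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = NULL, y = "Relative expression ratio",
                  caption = attr(df, "caption")) +
    ggplot2::theme_classic()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height)
    return(invisible(p))
  }
  p
}

ratioFrame <- function(object) {
  if (is(object, "CommonBaseTest")) {
    df <- data.frame(comparison = "A vs. B", ratio = object@ratio,
                     ratio_ci_lower = object@ratio.conf.int[1],
                     ratio_ci_upper = object@ratio.conf.int[2])
    attr(df, "caption") <- sprintf("%g%% confidence interval",
                                   100 * object@conf.level)
    return(df)
  }
  if (is(object, "CommonBaseAnova")) {
    ph <- object@posthoc
    df <- data.frame(comparison = paste(ph$level_a, "vs.", ph$level_b),
                     ratio = ph$ratio,
                     ratio_ci_lower = ph$ratio_ci_lower,
                     ratio_ci_upper = ph$ratio_ci_upper)
    attr(df, "caption") <- sprintf(
      "%g%% CIs (unadjusted); p-values Bonferroni-adjusted",
      100 * object@conf.level)
    return(df)
  }
  df <- as.data.frame(object)
  need <- c("comparison", "ratio", "ratio_ci_lower", "ratio_ci_upper")
  if (!all(need %in% names(df)))
    stop("data.frame input needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' @importFrom ggplot2 .data
#' @importFrom methods is new validObject
NULL
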