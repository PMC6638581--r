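verdict_palette <- c(GREEN = "#2e7d32", YELLOW = "#f9a825", RED = "#c62828")

#' Forest plot of trainees' systematic acquisition errors
#'
#' One panel per diameter type: each trainee's systematic error (posterior
#' median, two-sided 90% interval, mm relative to the instructor) drawn
#' over the shaded equivalence zone, colour-coded by verdict.
#'
#' @param x An `acq_assessment`.
#' @return A ggplot object.
#' @export
plot_systematic <- function(x) {
  stopifnot(inherits(x, "acq_assessment"))
  v <- x$verdicts
  ggplot2::ggplot(v, ggplot2::aes(x = .data$sys_estimate,
                                  y = .data$trainee)) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = -.data$sys_margin, xmax = .data$sys_margin),
      ymin = -Inf, ymax = Inf, fill = "grey85", colour = NA
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$sys_lower, xmax = .data$sys_upper,
                   colour = .data$sys_color),
      height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$sys_color), size = 2) +
    ggplot2::scale_colour_manual(values = verdict_palette, name = "Verdict") +
    ggplot2::facet_wrap(~diameter_type, scales = "free_x") +
    ggplot2::labs(
      x = "Systematic acquisition error vs. instructor (mm), 90% CI",
      y = NULL,
      title = "Systematic errors with equivalence zones"
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of trainees' sporadic acquisition errors
#'
#' One panel per diameter type: each trainee's image-level variance
#' (posterior median, one-sided 90% upper bound, mm²) over the shaded
#' noninferiority zone; the dashed line marks the instructor's image-level
#' variance.
#'
#' @param x An `acq_assessment`.
#' @return A ggplot object.
#' @export
plot_sporadic <- function(x) {
  stopifnot(inherits(x, "acq_assessment"))
  v <- x$verdicts
  v$instr_var <- v$spo_zone_upper - v$spo_margin
  ggplot2::ggplot(v, ggplot2::aes(x = .data$spo_estimate,
                                  y = .data$trainee)) +
    ggplot2::geom_rect(
      ggplot2::aes(xmax = .data$spo_zone_upper),
      xmin = 0, ymin = -Inf, ymax = Inf, fill = "grey85", colour = NA
    ) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$instr_var),
                        linetype = "dashed") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$spo_estimate, xmax = .data$spo_upper,
                   colour = .data$spo_color),
      height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$spo_color), size = 2) +
    ggplot2::scale_colour_manual(values = verdict_palette, name = "Verdict") +
    ggplot2::facet_wrap(~diameter_type, scales = "free_x") +
    ggplot2::labs(
      x = "Image-level variance (mm²), one-sided 90% upper bound",
      y = NULL,
      title = "Sporadic errors with noninferiority zones"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot an assessment
#'
#' @param object An `acq_assessment`.
#' @param type `"systematic"` or `"sporadic"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.acq_assessment <- function(object,
                                    type = c("systematic", "sporadic"),
                                    ...) {
  type <- match.arg(type)
  if (type == "systematic") plot_systematic(object) else
    plot_sporadic(object)
}
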