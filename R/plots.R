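# ggplot2 visualisations for harmonized data and fitted estimates.

#' Scatter of per-SNP associations with fitted causal slopes
#'
#' Exposure betas against outcome betas with +/- 1 SE bars and, when
#' estimates are supplied, the fitted causal slope(s) through the origin.
#'
#' @param object an `mr_harmonized` object.
#' @param estimates optional list of `mr_estimate` objects whose slopes
#'   are drawn.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mr_harmonized <- function(object, estimates = NULL, ...) {
  d <- object$snps
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_exposure,
                                       y = .data$beta_outcome)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$beta_outcome - .data$se_outcome,
      ymax = .data$beta_outcome + .data$se_outcome
    ), width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$beta_exposure - .data$se_exposure,
      xmax = .data$beta_exposure + .data$se_exposure
    ), height = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SNP effect on exposure (SD units)",
                  y = "SNP effect on outcome (log-odds)")
  if (!is.null(estimates)) {
    slopes <- dplyr::bind_rows(lapply(estimates, tidy.mr_estimate))
    p <- p + ggplot2::geom_abline(
      data = slopes,
      ggplot2::aes(slope = .data$theta, intercept = 0,
                   colour = .data$method)
    ) +
      ggplot2::labs(colour = "method")
  }
  p
}

#' Forest plot of a concordance report
#'
#' Odds ratios per dose increment with 95% CIs, one row per outcome and
#' method, with any externally supplied trial estimates alongside.
#'
#' @param object a `concordance_report` from [run_analysis()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.concordance_report <- function(object, ...) {
  d <- dplyr::transmute(object$results,
    outcome = .data$outcome, source = paste0("MR (", .data$method, ")"),
    estimate = .data$or, ci_low = .data$or_ci_low, ci_high = .data$or_ci_high
  )
  te <- object$trial_estimates
  if (!is.null(te)) {
    d <- dplyr::bind_rows(d, dplyr::transmute(te,
      outcome = .data$outcome, source = .data$label,
      estimate = .data$estimate, ci_low = .data$ci_low,
      ci_high = .data$ci_high
    ))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$source)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::facet_wrap(~outcome, ncol = 1, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio per dose increment (log scale)", y = NULL)
}
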