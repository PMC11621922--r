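#' Plot scar-score composition per sample
#'
#' Stacked bars of the LOH, LST and TAI components of each sample's HRDsum
#' score, ordered by total score.
#'
#' @param scores Output of [score_scars()].
#' @param cutoff Optional HRDsum cutoff drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_scar_scores <- function(scores, cutoff = NULL) {
  long <- scores %>%
    tidyr::pivot_longer(c("loh", "lst", "tai"), names_to = "metric",
                        values_to = "count") %>%
    mutate(sample = stats::reorder(.data$sample, .data$hrdsum))
  p <- ggplot(long, aes(x = .data$sample, y = .data$count,
                        fill = .data$metric)) +
    geom_col() +
    labs(x = NULL, y = "scar count", fill = NULL,
         title = "HRDsum composition") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
  if (!is.null(cutoff))
    p <- p + geom_hline(yintercept = cutoff, linetype = "dashed")
  p
}

#' Plot raw versus harmonized HRDsum scores
#'
#' One panel per dataset showing raw scores against the harmonized summary
#' score, with the identity line for reference.
#'
#' @param scores Long score tibble `sample, dataset, hrdsum`.
#' @param summary Output of [harmonize_scores()].
#' @return A ggplot object.
#' @export
plot_harmonization <- function(scores, summary) {
  dat <- inner_join(scores, summary, by = "sample")
  ggplot(dat, aes(x = .data$hrdsum, y = .data$summary_hrdsum)) +
    geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    geom_point(alpha = 0.5, size = 0.8) +
    facet_wrap(~dataset) +
    labs(x = "raw HRDsum", y = "summary HRDsum") +
    theme_minimal()
}

#' @describeIn fit_dose_response autoplot method: observed points and the
#'   fitted curve on a log10 concentration axis, with the IC50 marked.
#' @param object A `dr_fit`.
#' @param ... Unused.
#' @export
autoplot.dr_fit <- function(object, ...) {
  pts <- object$points
  grid <- tibble(x = seq(min(pts$x), max(pts$x), length.out = 200))
  grid$y <- if (object$model == "fallback")
    dr_fallback(grid$x, object$a, object$b)
  else dr_primary(grid$x, object$a, object$b)
  ggplot(pts, aes(x = .data$x, y = .data$y)) +
    geom_line(data = grid, colour = "steelblue") +
    geom_point() +
    geom_vline(xintercept = object$a, linetype = "dashed",
               colour = "grey50") +
    labs(x = "log10 concentration (nmol/L)", y = "response",
         title = paste0("IC50 = ", signif(object$ic50_nmolL, 3),
                        " nmol/L (", object$model, " model)")) +
    theme_minimal()
}
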