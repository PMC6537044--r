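#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_errorbar scale_x_log10 labs theme_minimal facet_wrap
#'   scale_fill_gradient2 geom_text
#' @export
ggplot2::autoplot

#' Plate heatmap of raw or normalized well values
#'
#' @param scores Plate or score tibble.
#' @param value Column to display (default `"bscore"`; use `"log_signal"` or
#'   `"signal"` for raw views).
#' @param plates Optional subset of plate ids.
#' @param replicate Replicate shown (default 1).
#' @return A ggplot faceted by plate and arm.
#' @export
plot_plate <- function(scores, value = "bscore", plates = NULL,
                       replicate = 1L) {
  df <- filter(scores, .data$replicate == !!replicate)
  if (!is.null(plates)) df <- filter(df, .data$plate_id %in% plates)
  ggplot(df, aes(x = .data$col, y = .data$row,
                 fill = .data[[value]])) +
    geom_tile() +
    ggplot2::scale_y_reverse(breaks = NULL) +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    facet_wrap(~ .data$plate_id + .data$arm) +
    labs(x = "column", y = "row", fill = value,
         title = sprintf("replicate %d", replicate)) +
    theme_minimal()
}

#' @describeIn fit_4pl Dose-response curve with data and fitted line.
#' @param object A `fit_4pl`.
#' @param ... Unused.
#' @export
autoplot.fit_4pl <- function(object, ...) {
  dat <- object$data
  pos <- dat$dose[dat$dose > 0]
  grid <- tibble(dose = exp(seq(log(min(pos) / 3), log(max(pos) * 3),
                                length.out = 200)))
  grid$viability <- predict(object, grid)
  ggplot(dat, aes(x = .data$dose, y = .data$viability)) +
    geom_point() +
    geom_line(data = grid) +
    scale_x_log10() +
    labs(x = "dose (µmol/L)", y = "relative viability",
         title = if (!is.na(object$compound_id)) object$compound_id else NULL,
         subtitle = if (object$converged) {
           sprintf("IC50 = %.3g µmol/L, hill = %.2f",
                   object$ic50, object$hill)
         } else "not converged") +
    theme_minimal()
}

#' @describeIn dose_matrix Heatmap of percent viability inhibition.
#' @param object A `dose_matrix`.
#' @param ... Unused.
#' @export
autoplot.dose_matrix <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(inhibition = (1 - .data$viability) * 100)
  ggplot(df, aes(x = factor(.data$dose_b), y = factor(.data$dose_a),
                 fill = .data$inhibition)) +
    geom_tile() +
    geom_text(aes(label = round(.data$inhibition)), size = 3) +
    scale_fill_gradient2(low = "white", high = "#b2182b", limits = c(0, 100)) +
    labs(x = sprintf("%s (µmol/L)", object$drug_b),
         y = sprintf("%s (µmol/L)", object$drug_a),
         fill = "% inhibition") +
    theme_minimal()
}

#' @describeIn synergy_analysis Side-by-side Loewe-excess and CI heatmaps.
#' @param object A `synergy_result`.
#' @param which `"loewe"` (default) or `"ci"`.
#' @param ... Unused.
#' @export
autoplot.synergy_result <- function(object, which = c("loewe", "ci"), ...) {
  which <- match.arg(which)
  m <- object$matrix
  df <- as_tibble(m) |>
    mutate(loewe_excess = as.vector(t(object$loewe_excess)),
           ci = as.vector(t(object$ci)))
  if (which == "loewe") {
    ggplot(df, aes(x = factor(.data$dose_b), y = factor(.data$dose_a),
                   fill = .data$loewe_excess)) +
      geom_tile() +
      geom_text(aes(label = round(.data$loewe_excess)), size = 3) +
      scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
      labs(x = sprintf("%s (µmol/L)", m$drug_b),
           y = sprintf("%s (µmol/L)", m$drug_a),
           fill = "Loewe excess (pp)") +
      theme_minimal()
  } else {
    ggplot(df, aes(x = factor(.data$dose_b), y = factor(.data$dose_a),
                   fill = .data$ci)) +
      geom_tile() +
      geom_text(aes(label = ifelse(is.na(.data$ci), "", round(.data$ci, 2))),
                size = 3) +
      scale_fill_gradient2(low = "#1a9850", mid = "white", high = "#d73027",
                           midpoint = 1) +
      labs(x = sprintf("%s (µmol/L)", m$drug_b),
           y = sprintf("%s (µmol/L)", m$drug_a),
           fill = "CI") +
      theme_minimal()
  }
}

#' Mean relative-tumor-volume growth curves
#'
#' @param summary Output of [compute_rtv()] (or a growth tibble).
#' @return A ggplot of group mean RTV vs day with SEM error bars.
#' @export
plot_growth <- function(summary) {
  if (is.data.frame(summary)) summary <- compute_rtv(summary)
  ggplot(summary$groups,
         aes(x = .data$day, y = .data$mean_rtv, color = .data$group)) +
    geom_line() +
    geom_point() +
    geom_errorbar(aes(ymin = .data$mean_rtv - .data$sem,
                      ymax = .data$mean_rtv + .data$sem), width = 0.5) +
    labs(x = "day", y = "relative tumor volume (mean ± SEM)") +
    theme_minimal()
}
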