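#' Four-parameter logistic viability model
#'
#' `hill4(d, top, bottom, ic50, hill)` evaluates
#' `bottom + (top - bottom) / (1 + (d/ic50)^hill)`: a sigmoid falling from
#' `top` (no drug) to `bottom` (saturating dose) for `hill > 0`, with
#' inflection at `ic50`. Zero dose is handled by the closed-form limit.
#'
#' @param d Dose vector (micromolar).
#' @param top,bottom Upper/lower viability asymptotes (fractions).
#' @param ic50 Inflection dose, > 0.
#' @param hill Slope; sign free.
#' @return Viability fractions.
#' @export
hill4 <- function(d, top, bottom, ic50, hill) {
  ratio <- ifelse(d == 0, if (hill > 0) 0 else Inf, (d / ic50)^hill)
  bottom + (top - bottom) / (1 + ratio)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of viability against dose using Levenberg-Marquardt
#' (via \pkg{minpack.lm}) with a deterministic multi-start: `ic50` starts at
#' quantiles of the positive doses, `hill` at several slopes, asymptotes at
#' the data extremes. The best converged start (lowest residual sum of
#' squares) is kept; if no start converges, `converged` is `FALSE` and no
#' sensitivity class can be assigned.
#'
#' @param dose Dose vector (micromolar), >= 4 distinct values; may include 0.
#' @param viability Viability fractions in \[0, 1.5\] (noise above 1
#'   tolerated); same length as `dose`.
#' @param weights Optional nonnegative case weights.
#' @param normalize If `TRUE`, viability is divided by the mean of the
#'   zero-dose (vehicle) observations before fitting.
#' @param compound_id,cell_line_id Optional identifiers carried in the result.
#' @return A `fit_4pl` object: coefficients `top`, `bottom`, `ic50`, `hill`,
#'   plus `rss`, `converged`, and the fitting data. Use [ic50()],
#'   [classify_sensitivity()], [generics::tidy()], [ggplot2::autoplot()].
#' @examples
#' d <- c(0, 0.1, 0.3, 1, 3, 10)
#' f <- fit_4pl(d, hill4(d, 1, 0, 1, 1))
#' ic50(f)
#' @export
fit_4pl <- function(dose, viability, weights = NULL, normalize = FALSE,
                    compound_id = NA_character_, cell_line_id = NA_character_) {
  stopifnot(length(dose) == length(viability))
  ok <- is.finite(dose) & is.finite(viability)
  dose <- dose[ok]; viability <- viability[ok]
  if (!is.null(weights)) weights <- weights[ok]
  if (length(unique(dose)) < 4L) abort("fit_4pl needs >= 4 distinct doses")
  if (any(dose < 0)) abort("doses must be nonnegative")
  if (any(viability < 0 | viability > 1.5)) {
    abort("viability must lie in [0, 1.5]")
  }
  if (normalize) {
    v0 <- mean(viability[dose == 0])
    if (!is.finite(v0) || v0 <= 0) abort("cannot normalize: no vehicle wells")
    viability <- viability / v0
  }
  dose_means <- tapply(viability, dose, mean)
  if (diff(range(dose_means)) < 1e-8) {
    abort("no dose effect detectable: viability is flat across doses")
  }

  pos <- sort(unique(dose[dose > 0]))
  top0 <- max(dose_means); bot0 <- min(dose_means)
  w <- if (is.null(weights)) rep(1, length(dose)) else weights
  resid_fn <- function(p) {
    (viability - hill4(dose, p[1], p[2], exp(p[3]), p[4])) * sqrt(w)
  }
  starts <- tidyr::expand_grid(
    lic = log(stats::quantile(pos, c(0.25, 0.5, 0.75), names = FALSE)),
    h = c(0.5, 1, 2)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(top = top0, bottom = bot0,
                lic50 = starts$lic[i], hill = starts$h[i]),
        fn = resid_fn,
        lower = c(-0.5, -0.5, log(1e-8), -20),
        upper = c(2, 2, log(1e8), 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && fit$info %in% 1:4) {
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) {
    return(structure(
      list(compound_id = compound_id, cell_line_id = cell_line_id,
           top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
           hill = NA_real_, rss = NA_real_, converged = FALSE,
           data = tibble(dose = dose, viability = viability)),
      class = "fit_4pl"))
  }
  cf <- best$fit$par
  top <- unname(cf["top"]); bottom <- unname(cf["bottom"])
  ic <- exp(unname(cf["lic50"])); hl <- unname(cf["hill"])
  # canonicalize so top is the zero-dose asymptote (hill > 0 orientation)
  if (hl < 0) {
    hl <- -hl
    tmp <- top; top <- bottom; bottom <- tmp
  }
  structure(
    list(compound_id = compound_id, cell_line_id = cell_line_id,
         top = top, bottom = bottom, ic50 = ic, hill = hl,
         rss = best$rss, converged = TRUE,
         data = tibble(dose = dose, viability = viability)),
    class = "fit_4pl")
}

#' @export
print.fit_4pl <- function(x, ...) {
  cat("<fit_4pl>",
      if (!is.na(x$compound_id)) paste0(" ", x$compound_id) else "", "\n",
      sep = "")
  if (x$converged) {
    cat(sprintf("  top %.3f  bottom %.3f  ic50 %.4g uM  hill %.3f  rss %.3g\n",
                x$top, x$bottom, x$ic50, x$hill, x$rss))
  } else {
    cat("  did not converge\n")
  }
  invisible(x)
}

#' Predicted viability from a 4PL fit
#'
#' @param object A `fit_4pl`.
#' @param newdata Optional data frame with a `dose` column; defaults to the
#'   fitting data.
#' @param ... Unused.
#' @return Numeric vector of predicted viability fractions.
#' @export
predict.fit_4pl <- function(object, newdata = NULL, ...) {
  if (!object$converged) abort("cannot predict from a non-converged fit")
  d <- if (is.null(newdata)) object$data$dose else newdata$dose
  hill4(d, object$top, object$bottom, object$ic50, object$hill)
}

#' Extract the IC50 from a 4PL fit
#'
#' The relative IC50 (default) is the inflection dose of the fitted sigmoid.
#' The absolute IC50 is the dose at which predicted viability crosses 0.5
#' (50% of control), which may not exist if the curve does not span 0.5.
#'
#' @param fit A `fit_4pl`.
#' @param type `"relative"` (default) or `"absolute"`.
#' @return IC50 in micromolar (`NA` if absolute IC50 is unattainable).
#' @export
ic50 <- function(fit, type = c("relative", "absolute")) {
  type <- match.arg(type)
  if (!fit$converged) return(NA_real_)
  if (type == "relative") return(fit$ic50)
  if (fit$top <= 0.5 || fit$bottom >= 0.5) return(NA_real_)
  fit$ic50 * ((fit$top - 0.5) / (0.5 - fit$bottom))^(1 / fit$hill)
}

#' Classify compound sensitivity from the IC50
#'
#' Two-band rule: IC50 below `sensitive_below` is "sensitive", above
#' `resistant_above` is "resistant", in between "intermediate". Defaults
#' follow the 4 and 30 micromolar bands used for the PRMT5-inhibitor panel.
#'
#' @param fit A `fit_4pl` object, or a numeric IC50 (micromolar).
#' @param sensitive_below Upper IC50 bound of the sensitive band (default 4).
#' @param resistant_above Lower IC50 bound of the resistant band (default 30).
#' @return Character class, `NA` for non-converged fits.
#' @examples
#' classify_sensitivity(2.2)  # "sensitive"
#' classify_sensitivity(35)   # "resistant"
#' @export
classify_sensitivity <- function(fit, sensitive_below = 4,
                                 resistant_above = 30) {
  x <- if (inherits(fit, "fit_4pl")) {
    if (!fit$converged) return(NA_character_)
    fit$ic50
  } else {
    as.numeric(fit)
  }
  dplyr::case_when(
    is.na(x) ~ NA_character_,
    x < sensitive_below ~ "sensitive",
    x > resistant_above ~ "resistant",
    TRUE ~ "intermediate"
  )
}

#' Fit dose-response curves for every compound/cell-line series in a table
#'
#' Tidy wrapper over [fit_4pl()]: one fit per group, returned one row per fit
#' with the sensitivity class attached.
#'
#' @param data Tibble with `dose` and `viability` columns.
#' @param ... Grouping columns (tidy-select), e.g. `compound_id, cell_line_id`.
#' @param sensitive_below,resistant_above Passed to [classify_sensitivity()].
#' @param normalize Passed to [fit_4pl()].
#' @return Tibble with group columns, `top`, `bottom`, `ic50`, `hill`, `rss`,
#'   `converged`, `sensitivity_class`, and a list-column `fit`.
#' @export
fit_dose_response <- function(data, ..., sensitive_below = 4,
                              resistant_above = 30, normalize = FALSE) {
  data |>
    group_by(...) |>
    dplyr::group_modify(function(df, key) {
      f <- fit_4pl(df$dose, df$viability, normalize = normalize)
      tibble(top = f$top, bottom = f$bottom, ic50 = f$ic50, hill = f$hill,
             rss = f$rss, converged = f$converged,
             sensitivity_class = classify_sensitivity(
               f, sensitive_below, resistant_above),
             fit = list(f))
    }) |>
    ungroup()
}
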