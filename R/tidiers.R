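#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a 4PL dose-response fit
#'
#' @param x A `fit_4pl`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.fit_4pl <- function(x, ...) {
  tibble(term = c("top", "bottom", "ic50", "hill"),
         estimate = c(x$top, x$bottom, x$ic50, x$hill))
}

#' One-row summary of a 4PL fit
#'
#' @param x A `fit_4pl`.
#' @param ... Unused.
#' @return Tibble with `ic50`, `hill`, `rss`, `converged`, `nobs`.
#' @export
glance.fit_4pl <- function(x, ...) {
  tibble(ic50 = x$ic50, hill = x$hill, rss = x$rss,
         converged = x$converged, nobs = nrow(x$data))
}

#' Tidy a median-effect fit
#'
#' @param x A `median_effect_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`dm`, `m`).
#' @export
tidy.median_effect_fit <- function(x, ...) {
  tibble(term = c("dm", "m"), estimate = c(x$dm, x$m))
}

#' One-row summary of a median-effect fit
#'
#' @param x A `median_effect_fit`.
#' @param ... Unused.
#' @return Tibble with `dm`, `m`, `r`, `n_points`.
#' @export
glance.median_effect_fit <- function(x, ...) {
  tibble(dm = x$dm, m = x$m, r = x$r, n_points = x$n_points)
}

#' One-row summary of a synergy analysis
#'
#' @param x A `synergy_result`.
#' @param ... Unused.
#' @return The matrix-level summary tibble.
#' @export
glance.synergy_result <- function(x, ...) x$summary
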