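#' Fit the median-effect model to single-agent dose-effect data
#'
#' Linear regression of `log(fa/(1-fa))` on `log(dose)` (the log-linearized
#' median-effect equation `fa/fu = (d/Dm)^m`), yielding the median-effect
#' dose `Dm` (dose at 50% effect) and slope `m`. Only points with fraction
#' affected strictly inside `fa_range` enter the regression; zero doses are
#' excluded.
#'
#' @param dose Dose vector (micromolar).
#' @param fa Fractions affected (inhibition, `1 - viability`) in \[0, 1\].
#' @param fa_range Inclusion window for the regression (default
#'   `c(0.01, 0.99)`).
#' @param drug_id Optional identifier.
#' @return A `median_effect_fit`: `dm`, `m`, `r` (correlation of the
#'   log-linear fit), `n_points`.
#' @examples
#' d <- c(0.25, 0.5, 1, 2, 4)
#' fit_median_effect(d, d / (d + 1))  # dm = 1, m = 1
#' @export
fit_median_effect <- function(dose, fa, fa_range = c(0.01, 0.99),
                              drug_id = NA_character_) {
  stopifnot(length(dose) == length(fa))
  keep <- is.finite(dose) & is.finite(fa) & dose > 0 &
    fa > fa_range[1] & fa < fa_range[2]
  if (sum(keep) < 2L) {
    abort("median-effect fit infeasible: < 2 points with 0 < fa < 1 in range")
  }
  x <- log(dose[keep])
  y <- log(fa[keep] / (1 - fa[keep]))
  fit <- stats::lm(y ~ x)
  m <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  if (!is.finite(m) || m == 0) {
    abort("median-effect fit infeasible: zero slope")
  }
  r <- if (length(x) > 2L) {
    suppressWarnings(stats::cor(x, y))
  } else {
    1
  }
  structure(
    list(drug_id = drug_id, dm = exp(-b / m), m = m, r = r,
         n_points = sum(keep)),
    class = "median_effect_fit")
}

#' @export
print.median_effect_fit <- function(x, ...) {
  cat(sprintf("<median_effect_fit>%s  Dm %.4g uM  m %.3f  r %.3f  (%d points)\n",
              if (!is.na(x$drug_id)) paste0(" ", x$drug_id) else "",
              x$dm, x$m, x$r, x$n_points))
  invisible(x)
}

#' Dose producing a given effect under the median-effect model
#'
#' `Dx = Dm * (fa/(1-fa))^(1/m)`.
#'
#' @param fit A `median_effect_fit`.
#' @param fa Fraction(s) affected, strictly inside (0, 1).
#' @return Dose(s) in micromolar; `NA` where `fa` is at the bounds.
#' @export
effect_dose <- function(fit, fa) {
  out <- rep(NA_real_, length(fa))
  ok <- is.finite(fa) & fa > 0 & fa < 1
  out[ok] <- fit$dm * (fa[ok] / (1 - fa[ok]))^(1 / fit$m)
  out
}

# fraction affected predicted by a 4PL viability fit
.fa_4pl <- function(fit, d) 1 - hill4(d, fit$top, fit$bottom, fit$ic50, fit$hill)

# invert a 4PL viability fit on the inhibition scale: dose producing effect E
.dose_at_fa_4pl <- function(fit, E) {
  v <- 1 - E
  if (v >= fit$top) return(0)
  if (v <= fit$bottom) return(Inf)
  fit$ic50 * ((fit$top - v) / (v - fit$bottom))^(1 / fit$hill)
}

#' Loewe-additive predicted inhibition surface
#'
#' For each cell `(d_a, d_b)` of a dose matrix, the Loewe-additive effect `E`
#' solves `d_a / D_A(E) + d_b / D_B(E) = 1`, where `D_X(E)` inverts drug X's
#' fitted single-agent curve on the inhibition scale. Solved by bisection
#' over the overlap of the two curves' attainable effect ranges; margin cells
#' take the corresponding single-agent fitted effect, and cells whose
#' additive effect falls outside the invertible range are clamped to the
#' nearest attainable bound and flagged.
#'
#' @param fit_a,fit_b Converged `fit_4pl` objects for the two drugs.
#' @param matrix A [dose_matrix()] (only its dose ladders are used).
#' @param tol Bisection tolerance on the effect (default 1e-6).
#' @return List with `predicted` (grid of predicted inhibition fractions,
#'   same shape as the viability grid) and `clamped` (logical grid).
#' @export
loewe_surface <- function(fit_a, fit_b, matrix, tol = 1e-6) {
  for (f in list(fit_a, fit_b)) {
    if (!inherits(f, "fit_4pl") || !f$converged) {
      abort("loewe_surface needs converged fit_4pl objects for both drugs")
    }
    if (f$top - f$bottom < 1e-6 || f$hill <= 0) {
      abort("non-invertible (flat) single-agent curve")
    }
  }
  da <- matrix$doses_a; db <- matrix$doses_b
  lo <- max(1 - fit_a$top, 1 - fit_b$top)
  hi <- min(1 - fit_a$bottom, 1 - fit_b$bottom)
  if (hi <= lo) abort("single-agent effect ranges do not overlap")
  eps <- tol * 1e-3
  pred <- matrix(NA_real_, length(da), length(db),
                 dimnames = dimnames(matrix$viability))
  clamped <- matrix(FALSE, length(da), length(db))
  g <- function(E, a, b) {
    a / .dose_at_fa_4pl(fit_a, E) + b / .dose_at_fa_4pl(fit_b, E) - 1
  }
  for (i in seq_along(da)) {
    for (j in seq_along(db)) {
      a <- da[i]; b <- db[j]
      if (a == 0 && b == 0) {
        pred[i, j] <- max(0, min(1 - fit_a$top, 1))
      } else if (b == 0) {
        pred[i, j] <- .fa_4pl(fit_a, a)
      } else if (a == 0) {
        pred[i, j] <- .fa_4pl(fit_b, b)
      } else {
        elo <- lo + eps; ehi <- hi - eps
        if (g(elo, a, b) <= 0) {
          pred[i, j] <- lo; clamped[i, j] <- TRUE
        } else if (g(ehi, a, b) >= 0) {
          pred[i, j] <- hi; clamped[i, j] <- TRUE
        } else {
          # g is strictly decreasing in E on (lo, hi)
          while (ehi - elo > tol) {
            mid <- (elo + ehi) / 2
            if (g(mid, a, b) > 0) elo <- mid else ehi <- mid
          }
          pred[i, j] <- (elo + ehi) / 2
        }
      }
    }
  }
  list(predicted = pred, clamped = clamped)
}

#' Loewe excess of an observed dose matrix over the additive prediction
#'
#' `excess = observed inhibition - Loewe-predicted inhibition`, in percentage
#' points; positive values mean more inhibition than additivity predicts.
#'
#' @param matrix A [dose_matrix()] (observed viability).
#' @param predicted Predicted-inhibition grid from [loewe_surface()] (the
#'   list or its `predicted` element).
#' @return Grid of excess values (percentage points).
#' @export
loewe_excess <- function(matrix, predicted) {
  if (is.list(predicted)) predicted <- predicted$predicted
  if (!all(dim(predicted) == dim(matrix$viability))) {
    abort("predicted grid shape does not match the dose matrix")
  }
  obs_inhib <- 1 - matrix$viability
  (obs_inhib - predicted) * 100
}

#' Chou-Talalay combination index
#'
#' For a combination `(d_a, d_b)` with observed fraction affected `fa`, the
#' mutually exclusive (two-term) combination index is
#' `CI = d_a / Dx_a + d_b / Dx_b`, where `Dx_x = Dm_x (fa/(1-fa))^(1/m_x)` is
#' the single-agent dose of drug x producing `fa`. CI < 1 leans synergistic,
#' CI about 1 additive, CI > 1 antagonistic. The nonexclusive (three-term)
#' variant adds the cross term `(d_a d_b)/(Dx_a Dx_b)`.
#'
#' @param fit_a,fit_b `median_effect_fit` objects for the two drugs.
#' @param d_a,d_b Combination doses (micromolar); vectorized.
#' @param fa_observed Observed fraction(s) affected, strictly in (0, 1);
#'   values at the bounds return `NA` (undefined, not fabricated).
#' @param exclusive If `TRUE` (default), the two-term form.
#' @return CI value(s); `NA` where undefined.
#' @export
chou_talalay_ci <- function(fit_a, fit_b, d_a, d_b, fa_observed,
                            exclusive = TRUE) {
  dxa <- effect_dose(fit_a, fa_observed)
  dxb <- effect_dose(fit_b, fa_observed)
  ci <- d_a / dxa + d_b / dxb
  if (!exclusive) ci <- ci + (d_a * d_b) / (dxa * dxb)
  ci
}

#' Full synergy analysis of a two-drug dose matrix
#'
#' Fits single-agent 4PL curves and median-effect lines from the matrix
#' margins (unless supplied), computes the Loewe-excess surface and the
#' per-cell Chou-Talalay CI, and classifies cells. CI is flagged undefined
#' (`NA`) at cells with fraction affected at the bounds and at cells whose
#' observed effect exceeds both single agents' maximal observed effects (the
#' grey-quadrant convention used when the combination outperforms either
#' agent's attainable range).
#'
#' @param matrix A [dose_matrix()].
#' @param fit_a,fit_b Optional `fit_4pl` objects; fitted from the margins if
#'   `NULL`.
#' @param me_a,me_b Optional `median_effect_fit` objects; fitted from the
#'   margins if `NULL`.
#' @param loewe_thresh Excess (percentage points) above which a cell is
#'   called synergy-leaning (default 10).
#' @param ci_thresh CI below which a cell is called synergy-leaning
#'   (default 1).
#' @param exclusive CI form, see [chou_talalay_ci()].
#' @param tol Loewe bisection tolerance.
#' @return A `synergy_result`: grids `loewe_excess`, `ci`, `calls`, the fits,
#'   and a one-row `summary` tibble (fraction of interior cells called, max
#'   excess, min CI, verdict).
#' @export
synergy_analysis <- function(matrix, fit_a = NULL, fit_b = NULL,
                             me_a = NULL, me_b = NULL,
                             loewe_thresh = 10, ci_thresh = 1,
                             exclusive = TRUE, tol = 1e-6) {
  v <- matrix$viability
  da <- matrix$doses_a; db <- matrix$doses_b
  fa_a_margin <- 1 - v[, 1]   # drug A alone (column of zero dose_b)
  fa_b_margin <- 1 - v[1, ]   # drug B alone
  if (is.null(fit_a)) fit_a <- fit_4pl(da, v[, 1], compound_id = matrix$drug_a)
  if (is.null(fit_b)) fit_b <- fit_4pl(db, v[1, ], compound_id = matrix$drug_b)
  if (is.null(me_a)) fit_me_a <- fit_median_effect(da, fa_a_margin,
                                                   drug_id = matrix$drug_a)
  else fit_me_a <- me_a
  if (is.null(me_b)) fit_me_b <- fit_median_effect(db, fa_b_margin,
                                                   drug_id = matrix$drug_b)
  else fit_me_b <- me_b

  surf <- loewe_surface(fit_a, fit_b, matrix, tol = tol)
  excess <- loewe_excess(matrix, surf)

  fa_obs <- 1 - v
  ci <- matrix(NA_real_, length(da), length(db), dimnames = dimnames(v))
  grey <- matrix(FALSE, length(da), length(db))
  max_single <- c(max(fa_a_margin), max(fa_b_margin))
  for (i in seq_along(da)) {
    for (j in seq_along(db)) {
      if (i == 1L || j == 1L) next  # margins and anchor: no combination
      fa_ij <- fa_obs[i, j]
      if (fa_ij > max_single[1] && fa_ij > max_single[2]) {
        grey[i, j] <- TRUE
        next
      }
      if (fa_ij <= 0 || fa_ij >= 1) next
      ci[i, j] <- chou_talalay_ci(fit_me_a, fit_me_b, da[i], db[j], fa_ij,
                                  exclusive = exclusive)
    }
  }

  calls <- matrix("undefined", length(da), length(db),
                  dimnames = dimnames(v))
  interior <- outer(seq_along(da) > 1L, seq_along(db) > 1L, `&`)
  syn <- interior & (excess > loewe_thresh |
                       (!is.na(ci) & ci < ci_thresh))
  ant <- interior & !syn & excess < -loewe_thresh
  calls[interior] <- "additive"
  calls[syn] <- "synergy-leaning"
  calls[ant] <- "antagonistic"

  frac_called <- mean(calls[interior] == "synergy-leaning")
  med_excess <- stats::median(excess[interior])
  med_ci <- if (all(is.na(ci))) NA_real_ else stats::median(ci, na.rm = TRUE)
  # matrix verdict uses medians: the per-cell CI rule is a knife edge at
  # CI = 1, where an exactly additive matrix falls by construction
  potentiated <- med_excess > loewe_thresh ||
    (!is.na(med_ci) && med_ci < ci_thresh - 0.1)
  summary <- tibble(
    drug_a = matrix$drug_a, drug_b = matrix$drug_b,
    n_interior = sum(interior),
    frac_synergy_leaning = frac_called,
    max_excess = max(excess[interior]),
    median_excess = med_excess,
    min_ci = if (all(is.na(ci))) NA_real_ else min(ci, na.rm = TRUE),
    median_ci = med_ci,
    verdict = if (potentiated) "potentiation" else "no potentiation"
  )
  structure(
    list(matrix = matrix, loewe_excess = excess, ci = ci, calls = calls,
         clamped = surf$clamped, grey = grey,
         fit_a = fit_a, fit_b = fit_b, me_a = fit_me_a, me_b = fit_me_b,
         loewe_thresh = loewe_thresh, ci_thresh = ci_thresh,
         summary = summary),
    class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("<synergy_result> %s x %s: %s\n", x$matrix$drug_a,
              x$matrix$drug_b, x$summary$verdict))
  cat(sprintf("  %.0f%% of interior cells synergy-leaning; max Loewe excess %.1f pp; min CI %s\n",
              100 * x$summary$frac_synergy_leaning, x$summary$max_excess,
              if (is.na(x$summary$min_ci)) "undefined" else
                sprintf("%.2f", x$summary$min_ci)))
  invisible(x)
}

#' Per-cell combination calls as a tibble
#'
#' @param result A `synergy_result`.
#' @param loewe_thresh,ci_thresh Optional re-thresholding (defaults: those
#'   stored in the result).
#' @return Long tibble with `dose_a`, `dose_b`, `viability`, `loewe_excess`,
#'   `ci`, `call`.
#' @export
classify_combination <- function(result, loewe_thresh = NULL,
                                 ci_thresh = NULL) {
  if (!is.null(loewe_thresh) || !is.null(ci_thresh)) {
    result <- synergy_analysis(
      result$matrix, fit_a = result$fit_a, fit_b = result$fit_b,
      me_a = result$me_a, me_b = result$me_b,
      loewe_thresh = loewe_thresh %||% result$loewe_thresh,
      ci_thresh = ci_thresh %||% result$ci_thresh)
  }
  as_tibble(result$matrix) |>
    select("dose_a", "dose_b", "viability") |>
    mutate(loewe_excess = as.vector(t(result$loewe_excess)),
           ci = as.vector(t(result$ci)),
           call = as.vector(t(result$calls)))
}
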