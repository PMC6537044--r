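#' Log-transform raw plate signals
#'
#' First step of the scoring chain: natural log of the raw readout. Natural
#' log is used so the percent-proliferation back-transform is a plain `exp()`.
#'
#' @param plates Canonical plate tibble (see [read_plate_table()]).
#' @param zero_policy How to treat nonpositive signals: `"error"` (default)
#'   or `"floor"`, which replaces them with half the smallest positive signal
#'   on the same plate/replicate.
#' @return The tibble with a `log_signal` column added; ordering of finite
#'   signals is preserved.
#' @export
log_transform <- function(plates, zero_policy = c("error", "floor")) {
  zero_policy <- match.arg(zero_policy)
  if (any(plates$signal <= 0)) {
    if (zero_policy == "error") {
      abort("nonpositive signal encountered; set zero_policy = 'floor' to floor them")
    }
    plates <- plates |>
      group_by(.data$plate_id, .data$replicate) |>
      mutate(signal = if_else(
        .data$signal <= 0,
        min(.data$signal[.data$signal > 0]) * 0.5,
        .data$signal)) |>
      ungroup()
  }
  mutate(plates, log_signal = log(.data$signal))
}

#' Two-way median polish
#'
#' Iteratively sweeps row medians then column medians out of a matrix until
#' the absolute sum of residuals changes by less than `tol`, the decomposition
#' underlying the B-score. Exact on additive row+column models; `NA` cells are
#' tolerated and excluded from medians.
#'
#' @param mat Numeric matrix (may contain `NA`).
#' @param max_iter Maximum sweep iterations (default 100).
#' @param tol Convergence tolerance on the change in `sum(|residual|)`
#'   (default 1e-9).
#' @return List with `overall`, `row` and `col` effects, `residuals` matrix,
#'   and `iterations`.
#' @export
median_polish <- function(mat, max_iter = 100L, tol = 1e-9) {
  stopifnot(is.matrix(mat))
  r <- mat
  t_all <- 0
  row_eff <- numeric(nrow(mat))
  col_eff <- numeric(ncol(mat))
  old_sum <- 0
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    rm_ <- apply(r, 1L, stats::median, na.rm = TRUE)
    rm_[is.na(rm_)] <- 0
    r <- sweep(r, 1L, rm_)
    row_eff <- row_eff + rm_
    cm_of_row <- stats::median(col_eff)
    t_all <- t_all + cm_of_row
    col_eff <- col_eff - cm_of_row

    cm_ <- apply(r, 2L, stats::median, na.rm = TRUE)
    cm_[is.na(cm_)] <- 0
    r <- sweep(r, 2L, cm_)
    col_eff <- col_eff + cm_
    rm_of_col <- stats::median(row_eff)
    t_all <- t_all + rm_of_col
    row_eff <- row_eff - rm_of_col

    new_sum <- sum(abs(r), na.rm = TRUE)
    converged <- new_sum == 0 || abs(new_sum - old_sum) < tol
    old_sum <- new_sum
    if (converged) break
  }
  list(overall = t_all, row = row_eff, col = col_eff,
       residuals = r, iterations = iter)
}

#' B-score positional normalization
#'
#' Applies a two-way median polish to the log-signal matrix of each
#' (plate, replicate, arm) separately — removing plate, row and column
#' effects — and scales the residuals by 1.4826 times their median absolute
#' deviation. Only compound wells enter the polish and the MAD; control wells
#' receive `NA` B-scores.
#'
#' @param scores Plate tibble with a `log_signal` column (see
#'   [log_transform()]).
#' @param max_iter,tol Passed to [median_polish()].
#' @param include_controls If `TRUE`, control wells enter the polish as well.
#' @return The tibble with a `bscore` column added.
#' @export
bscore <- function(scores, max_iter = 100L, tol = 1e-9,
                   include_controls = FALSE) {
  if (!"log_signal" %in% names(scores)) {
    abort("run log_transform() before bscore()")
  }
  scores |>
    group_by(.data$plate_id, .data$replicate, .data$arm) |>
    dplyr::group_modify(~ .bscore_one(.x, max_iter, tol, include_controls)) |>
    ungroup()
}

.bscore_one <- function(df, max_iter, tol, include_controls) {
  use <- if (include_controls) rep(TRUE, nrow(df)) else df$role == "compound"
  rows <- sort(unique(df$row[use]))
  cols <- sort(unique(df$col[use]))
  if (length(rows) < 2L || length(cols) < 2L) {
    abort("median polish undefined: need >= 2 distinct rows and columns of compound wells")
  }
  m <- matrix(NA_real_, length(rows), length(cols))
  ri <- match(df$row[use], rows)
  ci <- match(df$col[use], cols)
  m[cbind(ri, ci)] <- df$log_signal[use]
  mp <- median_polish(m, max_iter = max_iter, tol = tol)
  resid <- mp$residuals[cbind(ri, ci)]
  smad <- stats::mad(resid, constant = 1.4826, na.rm = TRUE)
  if (smad == 0) {
    # degenerate constant plate: residuals are all zero, keep bscore 0
    b <- ifelse(resid == 0, 0, NA_real_)
  } else {
    b <- resid / smad
  }
  df$bscore <- NA_real_
  df$bscore[use] <- b
  df
}

#' Robust Z-scores
#'
#' Centers by the median and scales by 1.4826 times the median absolute
#' deviation of a reference population:
#' `rz = (value - median_ref) / (1.4826 * mad_ref)`, the robust analogue of
#' the Z-score used for hit calling. `mad_ref` here is the raw MAD (the
#' consistency factor is applied explicitly).
#'
#' @param values Numeric vector to score.
#' @param reference Numeric vector defining `median_ref` and `mad_ref`;
#'   defaults to `values` itself.
#' @param consistency Consistency factor (default 1.4826, Gaussian).
#' @return List with `rz`, `median_ref`, `mad_ref` (raw MAD).
#' @examples
#' robust_zscore(100, reference = c(1, 2, 3, 4, 100))$rz  # 97/1.4826
#' @export
robust_zscore <- function(values, reference = values, consistency = 1.4826) {
  med <- stats::median(reference, na.rm = TRUE)
  mad_raw <- stats::mad(reference, constant = 1, na.rm = TRUE)
  if (!is.finite(mad_raw) || mad_raw == 0) {
    abort("degenerate reference population: MAD is zero")
  }
  list(rz = (values - med) / (consistency * mad_raw),
       median_ref = med, mad_ref = mad_raw)
}

#' Score a plate set: log transform, B-score, robust Z
#'
#' Runs the full per-well scoring chain. Robust Z-scores are computed on the
#' B-scores, per replicate, against a reference population of compound wells
#' in the same arm — per plate by default (matching the per-plate scope of the
#' positional correction) or globally across plates.
#'
#' @param plates Canonical plate tibble.
#' @param scope `"plate"` (default) or `"global"`: scope of the robust-Z
#'   reference population.
#' @param zero_policy Passed to [log_transform()].
#' @param max_iter,tol Passed to [bscore()].
#' @param consistency MAD consistency factor (default 1.4826).
#' @param pooled_mad If `TRUE` and `scope = "global"`, uses the median of
#'   per-plate MADs rather than one pooled MAD.
#' @return A score tibble: the input plus `log_signal`, `bscore`, `rz_score`,
#'   `median_ref`, `mad_ref` columns (`NA` for control wells).
#' @export
score_plates <- function(plates, scope = c("plate", "global"),
                         zero_policy = c("error", "floor"),
                         max_iter = 100L, tol = 1e-9,
                         consistency = 1.4826, pooled_mad = FALSE) {
  scope <- match.arg(scope)
  scored <- plates |>
    log_transform(zero_policy = zero_policy) |>
    bscore(max_iter = max_iter, tol = tol)

  grouping <- if (scope == "plate") {
    c("plate_id", "replicate", "arm")
  } else {
    c("replicate", "arm")
  }
  ref_stats <- scored |>
    filter(.data$role == "compound") |>
    group_by(across(dplyr::all_of(grouping)))
  if (scope == "global" && pooled_mad) {
    ref_stats <- ref_stats |>
      group_by(.data$plate_id, .add = TRUE) |>
      summarise(med_p = stats::median(.data$bscore, na.rm = TRUE),
                mad_p = stats::mad(.data$bscore, constant = 1, na.rm = TRUE),
                .groups = "drop_last") |>
      summarise(median_ref = stats::median(.data$med_p),
                mad_ref = stats::median(.data$mad_p), .groups = "drop")
  } else {
    ref_stats <- ref_stats |>
      summarise(median_ref = stats::median(.data$bscore, na.rm = TRUE),
                mad_ref = stats::mad(.data$bscore, constant = 1, na.rm = TRUE),
                .groups = "drop")
  }
  if (any(ref_stats$mad_ref == 0)) {
    abort("degenerate reference population: MAD is zero on at least one plate/arm")
  }
  scored |>
    left_join(ref_stats, by = grouping) |>
    mutate(rz_score = if_else(
      .data$role == "compound",
      (.data$bscore - .data$median_ref) / (consistency * .data$mad_ref),
      NA_real_))
}
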