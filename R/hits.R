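#' Call screening hits with a replicate-concordance rule
#'
#' A compound is a hit when its robust Z-score falls below the threshold in
#' every replicate of the selected arm (strictly below by default; two
#' replicates in the anchored-screen design). Compounds scored in fewer than
#' `min_replicates` replicates are excluded and reported with a warning, not
#' silently dropped.
#'
#' @param scores Score tibble from [score_plates()].
#' @param threshold RZ threshold (default -2).
#' @param arm Arm the rule is applied to (default `"combo_with_anchor"`).
#' @param min_replicates Minimum replicates required (default 2).
#' @param strict If `TRUE` (default) the rule is `rz < threshold`; if `FALSE`,
#'   `rz <= threshold`.
#' @return A tibble with one row per compound: per-replicate RZ columns
#'   (`rz_rep1`, `rz_rep2`, ...), `rz_mean`, `is_hit`, and the arm's
#'   `median_ref`/`mad_ref` means (for the proliferation back-transform).
#' @export
call_hits <- function(scores, threshold = -2, arm = "combo_with_anchor",
                      min_replicates = 2L, strict = TRUE) {
  sel <- scores |>
    filter(.data$role == "compound", .data$arm == !!arm,
           !is.na(.data$rz_score))
  if (nrow(sel) == 0) abort(sprintf("no scored compound wells in arm '%s'", arm))
  per <- sel |>
    group_by(.data$compound_id) |>
    summarise(
      n_rep = dplyr::n_distinct(.data$replicate),
      rz_mean = mean(.data$rz_score),
      all_below = if (strict) all(.data$rz_score < threshold) else
        all(.data$rz_score <= threshold),
      median_ref = mean(.data$median_ref),
      mad_ref = mean(.data$mad_ref),
      .groups = "drop"
    )
  short <- per |> filter(.data$n_rep < min_replicates)
  if (nrow(short) > 0) {
    warn(sprintf(
      "%d compound(s) scored in < %d replicates excluded from hit calling: %s",
      nrow(short), min_replicates,
      paste(utils::head(short$compound_id, 5L), collapse = ", ")))
  }
  wide <- sel |>
    group_by(.data$compound_id, .data$replicate) |>
    summarise(rz = mean(.data$rz_score), .groups = "drop") |>
    mutate(replicate = paste0("rz_rep", .data$replicate)) |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "rz")
  per |>
    filter(.data$n_rep >= min_replicates) |>
    mutate(is_hit = .data$all_below) |>
    select(-"all_below") |>
    left_join(wide, by = "compound_id") |>
    arrange(.data$rz_mean)
}

#' Delta-RZ potentiation score
#'
#' For each compound scored in both arms, the difference between its mean
#' combination-arm RZ and its mean single-agent RZ:
#' `delta_rz = RZ(compound + anchor) - RZ(compound alone)`. More negative
#' values indicate stronger potentiation by the anchor compound.
#' Per-replicate differences are also emitted where replicates pair up.
#'
#' @param scores Score tibble from [score_plates()].
#' @param threshold,strict Hit rule applied to the combination arm (see
#'   [call_hits()]); `delta_rz` is reported for every compound, with `is_hit`
#'   flagging those passing the rule.
#' @param single_arm,combo_arm Arm labels.
#' @return Tibble with `compound_id`, `rz_single`, `rz_combo` (replicate
#'   means), `delta_rz`, per-replicate `delta_rz_rep*`, `is_hit`, ordered by
#'   ascending `delta_rz`.
#' @export
delta_rz <- function(scores, threshold = -2, strict = TRUE,
                     single_arm = "single", combo_arm = "combo_with_anchor") {
  arm_means <- scores |>
    filter(.data$role == "compound", !is.na(.data$rz_score),
           .data$arm %in% c(single_arm, combo_arm)) |>
    group_by(.data$compound_id, .data$arm) |>
    summarise(rz = mean(.data$rz_score), .groups = "drop") |>
    mutate(arm = if_else(.data$arm == single_arm, "rz_single", "rz_combo")) |>
    tidyr::pivot_wider(names_from = "arm", values_from = "rz")
  if (!all(c("rz_single", "rz_combo") %in% names(arm_means))) {
    abort("delta_rz needs compounds scored in both arms")
  }
  missing_arm <- arm_means |>
    filter(is.na(.data$rz_single) | is.na(.data$rz_combo))
  if (nrow(missing_arm) > 0) {
    warn(sprintf("%d compound(s) missing one arm excluded from delta-RZ",
                 nrow(missing_arm)))
  }
  per_rep <- scores |>
    filter(.data$role == "compound", !is.na(.data$rz_score),
           .data$arm %in% c(single_arm, combo_arm)) |>
    mutate(arm = if_else(.data$arm == single_arm, "s", "c")) |>
    group_by(.data$compound_id, .data$replicate, .data$arm) |>
    summarise(rz = mean(.data$rz_score), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "arm", values_from = "rz") |>
    mutate(d = .data$c - .data$s,
           replicate = paste0("delta_rz_rep", .data$replicate)) |>
    select("compound_id", "replicate", "d") |>
    tidyr::pivot_wider(names_from = "replicate", values_from = "d")
  hits <- call_hits(scores, threshold = threshold, arm = combo_arm,
                    strict = strict) |>
    select("compound_id", "is_hit")
  arm_means |>
    filter(!is.na(.data$rz_single), !is.na(.data$rz_combo)) |>
    mutate(delta_rz = .data$rz_combo - .data$rz_single) |>
    left_join(per_rep, by = "compound_id") |>
    left_join(hits, by = "compound_id") |>
    mutate(is_hit = if_else(is.na(.data$is_hit), FALSE, .data$is_hit)) |>
    arrange(.data$delta_rz)
}

#' Rank potentiation hits
#'
#' Orders hit compounds by ascending delta-RZ (most potentiated first), ties
#' broken by the combination-arm RZ, and returns the top `n`.
#'
#' @param deltas Output of [delta_rz()].
#' @param n Number of compounds to return (default 25).
#' @param hits_only If `TRUE` (default), only compounds passing the hit rule
#'   are ranked.
#' @return Tibble of the top `n` rows with a `rank` column.
#' @export
rank_hits <- function(deltas, n = 25L, hits_only = TRUE) {
  ranked <- deltas
  if (hits_only) ranked <- filter(ranked, .data$is_hit)
  ranked |>
    arrange(.data$delta_rz, .data$rz_combo) |>
    utils::head(n) |>
    mutate(rank = dplyr::row_number())
}

#' Back-transform robust Z-scores to percent proliferation
#'
#' Inverts the log-scale scoring chain:
#' `%proliferation = exp(rz * 1.4826 * mad_ref + median_ref) / exp(median_ref) * 100`,
#' which simplifies to `exp(rz * 1.4826 * mad_ref) * 100`. An RZ of 0 (a well
#' at the treated-population median) therefore maps to 100% for any reference.
#'
#' @param rz Robust Z-score(s).
#' @param mad_ref Raw MAD of the reference population (log scale).
#' @param median_ref Reference median; cancels algebraically, accepted for
#'   interface completeness.
#' @param consistency MAD consistency factor (default 1.4826).
#' @return Percent proliferation, strictly increasing in `rz`.
#' @examples
#' rz_to_proliferation(0, mad_ref = 0.2)    # 100
#' rz_to_proliferation(-2, mad_ref = 0.1)   # ~74.34
#' @export
rz_to_proliferation <- function(rz, mad_ref, median_ref = 0,
                                consistency = 1.4826) {
  if (any(mad_ref < 0)) abort("mad_ref must be nonnegative")
  x <- rz * consistency * mad_ref
  # overflow guard: cap the exponent at log(.Machine$double.xmax)
  x <- pmin(x, log(.Machine$double.xmax) - 1)
  exp(x) * 100
}
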