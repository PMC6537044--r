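#' Relative tumor volumes and group growth summaries
#'
#' Computes, per animal, `RTV(t) = volume(t) / volume(baseline day)` (day 1 =
#' randomization), and per group per day the mean RTV and its standard error
#' — the quantities plotted on mean +/- SEM growth curves.
#'
#' @param growth Validated growth tibble (see [read_growth_table()]).
#' @param baseline_day Baseline day (default 1).
#' @return List with `animals` (per animal-day tibble incl. `rtv`) and
#'   `groups` (per group-day `mean_rtv`, `sem`, `n`).
#' @export
compute_rtv <- function(growth, baseline_day = 1L) {
  growth <- validate_growth_table(growth, baseline_day = baseline_day)
  animals <- growth |>
    group_by(.data$animal_id) |>
    mutate(rtv = .data$volume /
             .data$volume[.data$day == baseline_day][1]) |>
    ungroup()
  groups <- animals |>
    group_by(.data$group, .data$day) |>
    summarise(mean_rtv = mean(.data$rtv),
              sem = stats::sd(.data$rtv) / sqrt(n()),
              n = n(), .groups = "drop")
  list(animals = animals, groups = groups)
}

#' Tumor growth inhibition at a stated day
#'
#' `TGI = (1 - mean RTV(treated) / mean RTV(control)) x 100` at the stated
#' day. 100 means complete suppression of net growth relative to control;
#' negative values (treated growing faster) are reported as-is.
#'
#' @param summary Output of [compute_rtv()] (or a growth tibble, which is
#'   summarized first).
#' @param day Assessment day; must be measured in both groups.
#' @param treated,control Group labels (defaults `"treated"`, `"control"`).
#' @return TGI in percent.
#' @export
tgi <- function(summary, day, treated = "treated", control = "control") {
  if (is.data.frame(summary)) summary <- compute_rtv(summary)
  g <- summary$groups |> filter(.data$day == !!day)
  mt <- g$mean_rtv[g$group == treated]
  mc <- g$mean_rtv[g$group == control]
  if (length(mt) != 1L || length(mc) != 1L) {
    abort(sprintf("day %d not measured in both groups", day))
  }
  (1 - mt / mc) * 100
}

#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Wrapper over [stats::wilcox.test()] fixing the conventions used for
#' endpoint RTV comparisons: exact null distribution when both groups have at
#' most `exact_max` observations and no ties; normal approximation with
#' continuity and tie correction otherwise. Fully tied samples return p = 1
#' with a warning rather than an error.
#'
#' @param x,y Numeric samples (>= 3 observations each).
#' @param exact_max Largest per-group n for the exact branch (default 8).
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return One-row tibble: `statistic` (rank-sum U), `p_value`, `method`
#'   (`"exact"` or `"normal_approx"`), `n_x`, `n_y`, `significant`.
#' @export
mann_whitney_two_tailed <- function(x, y, exact_max = 8L, alpha = 0.05) {
  if (length(x) < 3L || length(y) < 3L) {
    abort("both samples need >= 3 observations")
  }
  ties <- any(duplicated(c(x, y)))
  if (length(unique(c(x, y))) == 1L) {
    warn("all observations tied; p = 1")
    return(tibble(statistic = length(x) * length(y) / 2, p_value = 1,
                  method = "degenerate", n_x = length(x), n_y = length(y),
                  significant = FALSE))
  }
  use_exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
  res <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = use_exact, correct = TRUE))
  tibble(statistic = unname(res$statistic), p_value = res$p.value,
         method = if (use_exact) "exact" else "normal_approx",
         n_x = length(x), n_y = length(y),
         significant = res$p.value < alpha)
}

#' Per-phase Fisher-exact comparison of cell-cycle counts with BH adjustment
#'
#' For each phase (G1, S, G2/M by default), builds the 2x2 table
#' (phase vs not-phase) x (condition A vs B) from cell counts, runs a
#' two-sided Fisher exact test, and adjusts the family of phase p-values with
#' Benjamini-Hochberg.
#'
#' @param counts Tibble with columns `condition`, `phase`, `count`; exactly
#'   two conditions. Phases not in `phases` (e.g. subG1) still contribute to
#'   the totals.
#' @param phases Phases tested (default `c("G1", "S", "G2M")`).
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return Tibble with one row per phase: the 2x2 table margins, `p_value`,
#'   `p_adjusted`, `significant`.
#' @export
cellcycle_fisher_bh <- function(counts, phases = c("G1", "S", "G2M"),
                                alpha = 0.05) {
  conds <- unique(counts$condition)
  if (length(conds) != 2L) abort("exactly two conditions required")
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    abort("counts must be nonnegative integers")
  }
  totals <- counts |>
    group_by(.data$condition) |>
    summarise(total = sum(.data$count), .groups = "drop")
  if (any(totals$total == 0)) abort("zero total count in a condition")
  res <- purrr::map(phases, function(ph) {
    in_ph <- counts |>
      filter(.data$phase == ph) |>
      group_by(.data$condition) |>
      summarise(k = sum(.data$count), .groups = "drop")
    k <- in_ph$k[match(conds, in_ph$condition)]
    k[is.na(k)] <- 0L
    tot <- totals$total[match(conds, totals$condition)]
    tab <- matrix(c(k[1], tot[1] - k[1], k[2], tot[2] - k[2]), nrow = 2)
    tibble(phase = ph,
           count_1 = k[1], total_1 = tot[1],
           count_2 = k[2], total_2 = tot[2],
           p_value = stats::fisher.test(tab)$p.value)
  }) |>
    purrr::list_rbind() |>
    mutate(p_adjusted = stats::p.adjust(.data$p_value, method = "BH"),
           significant = .data$p_adjusted < alpha)
  res
}

#' Viability-normalized caspase activity fold change
#'
#' Apoptosis readouts scale with cell number, so caspase luminescence is
#' divided by a concomitant viability readout; fold change is the treated
#' ratio over the vehicle ratio. The result is invariant to any common
#' luminescence gain.
#'
#' @param caspase_lum,viability_lum Treated-condition signals (vectorized).
#' @param vehicle_caspase,vehicle_viability Vehicle-condition signals.
#' @return Fold change(s) of the caspase/viability ratio vs vehicle.
#' @examples
#' normalize_caspase(200, 50, 100, 100)  # caspase x2, viability x0.5 -> 4
#' @export
normalize_caspase <- function(caspase_lum, viability_lum,
                              vehicle_caspase, vehicle_viability) {
  if (any(viability_lum <= 0) || any(vehicle_viability <= 0)) {
    abort("viability signal must be positive")
  }
  if (any(vehicle_caspase <= 0)) abort("vehicle caspase signal must be positive")
  (caspase_lum / viability_lum) / (vehicle_caspase / vehicle_viability)
}
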