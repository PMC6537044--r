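#' Pipeline configuration
#'
#' Bundles every tunable of the screen-to-report pipeline. Defaults are the
#' published analysis settings: hit threshold RZ < -2 in all replicates,
#' Loewe-excess threshold 10 percentage points, CI threshold 1, sensitivity
#' bands 4 / 30 micromolar, per-plate robust-Z scoping, top-25 ranking.
#'
#' @param plates_path,matrix_path,growth_path Input CSVs; any left `NULL` is
#'   simulated from `seed` when `simulate = TRUE`.
#' @param simulate Generate synthetic inputs for missing paths (default TRUE).
#' @param out_dir Output directory.
#' @param hit_threshold RZ hit threshold (default -2).
#' @param min_replicates Replicates required for hit calling (default 2).
#' @param scope Robust-Z reference scope, `"plate"` or `"global"`.
#' @param top_n Size of the potentiation ranking (default 25).
#' @param loewe_thresh,ci_thresh Combination-call thresholds (10, 1).
#' @param sensitive_below,resistant_above IC50 class bands (4, 30).
#' @param endpoint_day In-vivo assessment day (default 29).
#' @param stages Character vector of enabled stages, a subset of
#'   `c("normalize", "hits", "dose_response", "synergy", "invivo")`.
#' @param seed Seed for all simulated inputs (default 1).
#' @return A `screen_config` list.
#' @export
screen_config <- function(plates_path = NULL, matrix_path = NULL,
                          growth_path = NULL, simulate = TRUE,
                          out_dir = "screen_out",
                          hit_threshold = -2, min_replicates = 2L,
                          scope = "plate", top_n = 25L,
                          loewe_thresh = 10, ci_thresh = 1,
                          sensitive_below = 4, resistant_above = 30,
                          endpoint_day = 29L,
                          stages = c("normalize", "hits", "dose_response",
                                     "synergy", "invivo"),
                          seed = 1L) {
  structure(as.list(environment()), class = "screen_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' Configurations round-trip exactly through serialization, so a stored file
#' reproduces a run.
#'
#' @param config A [screen_config()].
#' @param path YAML file path.
#' @return `path` (write) or the `screen_config` (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(screen_config, raw)
}

.log_line <- function(con, stage, msg) {
  cat(sprintf("[%s] %s\n", stage, msg), file = con, append = TRUE)
}

#' Run the full screen analysis pipeline
#'
#' Executes the enabled stages in order — load (or simulate) inputs,
#' normalize and score plates, call and rank hits, fit single-agent
#' dose-response curves, score the two-drug combination, and analyze the
#' in-vivo study — writing per-stage CSV/JSON outputs plus a `report.json`
#' summary into `config$out_dir`. Every random input derives from
#' `config$seed`, so a rerun under the same configuration yields identical
#' data outputs (`pipeline.log`, which records wall-clock timings, is the
#' one diagnostic exception).
#'
#' @param config A [screen_config()].
#' @return Invisibly, a list with the in-memory stage results and the vector
#'   of files written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  cat("", file = log_path)
  .log_line(log_path, "config", paste0("hash ", rlang::hash(unclass(config))))
  t0 <- Sys.time()
  files <- character()
  res <- list()
  report <- list(config_hash = rlang::hash(unclass(config)))

  # ---- load / simulate --------------------------------------------------
  truth <- NULL
  if (!is.null(config$plates_path)) {
    plates <- read_plate_table(config$plates_path)
  } else if (config$simulate) {
    sim <- simulate_screen(screen_sim_spec(seed = config$seed))
    plates <- sim$plates
    truth <- sim$truth
  } else {
    plates <- NULL
  }
  dm <- if (!is.null(config$matrix_path)) {
    read_dose_matrix(config$matrix_path)
  } else if (config$simulate) {
    simulate_matrix(matrix_sim_spec(regime = "synergy",
                                    seed = config$seed + 1L))
  } else NULL
  growth <- if (!is.null(config$growth_path)) {
    read_growth_table(config$growth_path)
  } else if (config$simulate) {
    simulate_growth(growth_sim_spec(seed = config$seed + 2L))
  } else NULL
  .log_line(log_path, "load", sprintf(
    "plates=%s matrix=%s growth=%s",
    !is.null(plates), !is.null(dm), !is.null(growth)))

  wjson <- function(x, name) {
    p <- file.path(config$out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, p)
  }
  wcsv <- function(x, name) {
    p <- file.path(config$out_dir, name)
    readr::write_csv(x, p)
    files <<- c(files, p)
  }

  # ---- normalize --------------------------------------------------------
  if ("normalize" %in% config$stages) {
    if (is.null(plates)) abort("normalize stage needs plate data")
    res$scores <- score_plates(plates, scope = config$scope)
    wcsv(res$scores, "scores.csv")
    .log_line(log_path, "normalize", sprintf("%d wells scored",
                                             nrow(res$scores)))
  }

  # ---- hits -------------------------------------------------------------
  if ("hits" %in% config$stages) {
    if (is.null(res$scores)) abort("hits stage needs the normalize stage")
    res$hits <- call_hits(res$scores, threshold = config$hit_threshold,
                          min_replicates = config$min_replicates)
    res$deltas <- delta_rz(res$scores, threshold = config$hit_threshold)
    res$top <- rank_hits(res$deltas, n = config$top_n)
    wcsv(res$hits, "hits.csv")
    wcsv(res$deltas, "delta_rz.csv")
    wcsv(res$top, "top_hits.csv")
    report$n_hits <- sum(res$hits$is_hit)
    report$top_hits <- res$top$compound_id
    .log_line(log_path, "hits", sprintf("%d hits", report$n_hits))
  }

  # ---- dose response ----------------------------------------------------
  if ("dose_response" %in% config$stages) {
    if (is.null(dm)) abort("dose_response stage needs a dose matrix")
    fits <- tibble(
      drug = c(dm$drug_a, dm$drug_b),
      fit = list(
        fit_4pl(dm$doses_a, dm$viability[, 1], compound_id = dm$drug_a),
        fit_4pl(dm$doses_b, dm$viability[1, ], compound_id = dm$drug_b))
    ) |>
      mutate(ic50 = purrr::map_dbl(.data$fit, ic50),
             hill = purrr::map_dbl(.data$fit, "hill"),
             converged = purrr::map_lgl(.data$fit, "converged"),
             sensitivity_class = purrr::map_chr(
               .data$fit, classify_sensitivity,
               sensitive_below = config$sensitive_below,
               resistant_above = config$resistant_above))
    res$dose_response <- fits
    wcsv(select(fits, -"fit"), "dose_response.csv")
    report$ic50 <- stats::setNames(fits$ic50, fits$drug)
    .log_line(log_path, "dose_response",
              paste(sprintf("%s ic50=%.3g (%s)", fits$drug, fits$ic50,
                            fits$sensitivity_class), collapse = "; "))
  }

  # ---- synergy ----------------------------------------------------------
  if ("synergy" %in% config$stages) {
    if (is.null(dm)) abort("synergy stage needs a dose matrix")
    fa <- if (!is.null(res$dose_response)) res$dose_response$fit[[1]] else NULL
    fb <- if (!is.null(res$dose_response)) res$dose_response$fit[[2]] else NULL
    res$synergy <- synergy_analysis(dm, fit_a = fa, fit_b = fb,
                                    loewe_thresh = config$loewe_thresh,
                                    ci_thresh = config$ci_thresh)
    wcsv(classify_combination(res$synergy), "synergy_cells.csv")
    wjson(as.list(res$synergy$summary), "synergy_summary.json")
    report$synergy_verdict <- res$synergy$summary$verdict
    .log_line(log_path, "synergy", res$synergy$summary$verdict)
  }

  # ---- in vivo ----------------------------------------------------------
  if ("invivo" %in% config$stages) {
    if (is.null(growth)) abort("invivo stage needs a growth table")
    res$rtv <- compute_rtv(growth)
    endpoint <- config$endpoint_day
    tgi_pct <- tgi(res$rtv, day = endpoint)
    final <- res$rtv$animals |> filter(.data$day == endpoint)
    mw <- mann_whitney_two_tailed(
      final$rtv[final$group == "treated"],
      final$rtv[final$group == "control"])
    res$invivo <- list(tgi_percent = tgi_pct, mann_whitney = mw)
    wcsv(res$rtv$groups, "rtv_groups.csv")
    wjson(list(endpoint_day = endpoint, tgi_percent = tgi_pct,
               mw_p = mw$p_value, mw_method = mw$method),
          "invivo_summary.json")
    report$tgi_percent <- tgi_pct
    report$mw_p <- mw$p_value
    .log_line(log_path, "invivo", sprintf("TGI %.1f%%, p=%.4g",
                                          tgi_pct, mw$p_value))
  }

  wjson(report, "report.json")
  .log_line(log_path, "done", sprintf(
    "%.2f s elapsed", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res$truth <- truth
  res$files <- files
  invisible(res)
}
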