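# run expr with a local RNG state so generators are pure functions of (spec, seed)
.with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic anchored screen
#'
#' Describes a multiwell anchored screen with planted truth: a fraction of
#' compounds are actives (log-scale viability effect), a fraction of actives
#' is additionally potentiated by the anchor in the combination arm, and
#' plates carry additive positional artifacts (row/column gradients, plate
#' offsets) plus log-normal measurement noise. Defaults emulate a
#' 1,200-compound duplicate 384-well screen with vehicle controls in column 1
#' and anchor-alone controls in column 24.
#'
#' @param n_compounds Number of library compounds (default 1200).
#' @param geometry Plate shape `c(n_rows, n_cols)` (default 384-well, 16x24).
#' @param n_replicates Replicates per arm (default 2).
#' @param active_fraction Fraction of compounds with a real effect
#'   (default 0.05).
#' @param active_effect `list(location, scale)` of the Gaussian log-scale
#'   viability shift of actives (default location -0.6, scale 0.05; about -6
#'   robust-Z units at the default noise).
#' @param anchor_potentiation_fraction Fraction of actives additionally
#'   potentiated by the anchor (default 0.5).
#' @param potentiation_effect `list(location, scale)` of the extra log-scale
#'   shift in the combination arm (default -0.5, 0.25).
#' @param anchor_effect Constant log-scale shift applied to all
#'   combination-arm compound wells and anchor-control wells (default -0.1).
#' @param row_gradient,col_gradient Additive log-scale artifact per row /
#'   column step (defaults 0.02, 0.015).
#' @param plate_offset SD of the per-plate additive log-scale offset
#'   (default 0.05).
#' @param noise_sd Log-scale Gaussian noise SD (default 0.1, about 10% CV).
#' @param contamination_fraction Fraction of wells given 5x noise SD (heavy
#'   tail stress option; default 0).
#' @param base_log Baseline log-signal (default `log(2e5)` luminescence
#'   counts).
#' @param compound_concentration_um Screening concentration (default 10).
#' @param seed RNG seed (required for reproducibility; default 1).
#' @return A `screen_sim_spec` list.
#' @export
screen_sim_spec <- function(n_compounds = 1200L, geometry = c(16L, 24L),
                            n_replicates = 2L,
                            active_fraction = 0.05,
                            active_effect = list(location = -0.6, scale = 0.05),
                            anchor_potentiation_fraction = 0.5,
                            potentiation_effect = list(location = -0.5,
                                                       scale = 0.25),
                            anchor_effect = -0.1,
                            row_gradient = 0.02, col_gradient = 0.015,
                            plate_offset = 0.05, noise_sd = 0.1,
                            contamination_fraction = 0,
                            base_log = log(2e5),
                            compound_concentration_um = 10,
                            seed = 1L) {
  stopifnot(active_fraction >= 0, active_fraction <= 1,
            anchor_potentiation_fraction >= 0,
            anchor_potentiation_fraction <= 1,
            noise_sd >= 0, n_replicates >= 1)
  structure(as.list(environment()), class = "screen_sim_spec")
}

#' Simulate an anchored screen with planted truth
#'
#' Log-signals are built additively — plate offset + row gradient + column
#' gradient + compound effect (+ potentiation in the combination arm, for
#' potentiated actives) + Gaussian noise — then exponentiated to raw
#' luminescence. Compounds fill columns 2 to (n_cols - 1); column 1 holds
#' vehicle controls, the last column anchor-alone controls. Both arms are
#' laid out identically and replicated.
#'
#' @param spec A [screen_sim_spec()].
#' @return List with `plates` (canonical plate tibble) and `truth` (one row
#'   per compound: `is_active`, `effect`, `is_potentiated`, `potentiation`).
#' @export
simulate_screen <- function(spec) {
  stopifnot(inherits(spec, "screen_sim_spec"))
  .with_local_seed(spec$seed, {
    nr <- spec$geometry[1]; nc <- spec$geometry[2]
    cmp_cols <- 2:(nc - 1)
    per_plate <- nr * length(cmp_cols)
    n_plates <- ceiling(spec$n_compounds / per_plate)

    ids <- sprintf("CMP%04d", seq_len(spec$n_compounds))
    is_active <- stats::runif(spec$n_compounds) < spec$active_fraction
    effect <- ifelse(is_active,
                     stats::rnorm(spec$n_compounds,
                                  spec$active_effect$location,
                                  spec$active_effect$scale), 0)
    is_pot <- is_active &
      (stats::runif(spec$n_compounds) < spec$anchor_potentiation_fraction)
    potentiation <- ifelse(is_pot,
                           stats::rnorm(spec$n_compounds,
                                        spec$potentiation_effect$location,
                                        spec$potentiation_effect$scale), 0)
    truth <- tibble(compound_id = ids, is_active = is_active, effect = effect,
                    is_potentiated = is_pot, potentiation = potentiation)

    # fixed compound placement, shared by every arm and replicate
    slot <- tidyr::expand_grid(plate = seq_len(n_plates), col = cmp_cols,
                               row = seq_len(nr))[seq_len(spec$n_compounds), ]
    layout <- bind_rows(
      tibble(plate = slot$plate, row = slot$row, col = slot$col,
             compound_id = ids, role = "compound"),
      tidyr::expand_grid(plate = seq_len(n_plates), row = seq_len(nr)) |>
        mutate(col = 1L, compound_id = NA_character_,
               role = "vehicle_control"),
      tidyr::expand_grid(plate = seq_len(n_plates), row = seq_len(nr)) |>
        mutate(col = nc, compound_id = NA_character_,
               role = "anchor_control")
    )

    arms <- .arms[seq_len(2L)]
    out <- vector("list", 2L * spec$n_replicates)
    k <- 0L
    for (arm in arms) {
      for (rep_i in seq_len(spec$n_replicates)) {
        df <- layout
        df$arm <- arm
        df$replicate <- rep_i
        df$plate_id <- sprintf("%s%02d",
                               if (arm == "single") "S" else "C", df$plate)
        offs <- stats::rnorm(n_plates, 0, spec$plate_offset)
        eff <- ifelse(df$role == "compound",
                      effect[match(df$compound_id, ids)], 0)
        pot <- if (arm == "combo_with_anchor") {
          ifelse(df$role == "compound",
                 potentiation[match(df$compound_id, ids)], 0)
        } else 0
        anchor <- ifelse(
          df$role == "anchor_control" |
            (df$role == "compound" & arm == "combo_with_anchor"),
          spec$anchor_effect, 0)
        sdvec <- rep(spec$noise_sd, nrow(df))
        if (spec$contamination_fraction > 0) {
          heavy <- stats::runif(nrow(df)) < spec$contamination_fraction
          sdvec[heavy] <- sdvec[heavy] * 5
        }
        logsig <- spec$base_log + offs[df$plate] +
          spec$row_gradient * (df$row - 1L) +
          spec$col_gradient * (df$col - 1L) +
          eff + pot + anchor + stats::rnorm(nrow(df), 0, sdvec)
        df$signal <- exp(logsig)
        k <- k + 1L
        out[[k]] <- df
      }
    }
    plates <- bind_rows(out) |>
      mutate(
        well = rowcol_to_well(.data$row, .data$col),
        concentration_um = if_else(.data$role == "compound",
                                   spec$compound_concentration_um, NA_real_)
      ) |>
      select("plate_id", "row", "col", "well", "compound_id", "role", "arm",
             "concentration_um", "replicate", "signal")
    list(plates = plates, truth = truth)
  })
}

#' Specification of a synthetic two-drug dose matrix
#'
#' Single agents follow four-parameter Hill curves; combination cells are
#' built under a chosen interaction regime: Loewe-additive (by an
#' implementation-independent fine-grid inversion of the Loewe equation),
#' Bliss-independent (survival product), or synergy/antagonism (additive
#' inhibition shifted by +/- `interaction_strength` at combination cells).
#'
#' @param hill_a,hill_b `list(top, bottom, ic50, hill)` of the two drugs'
#'   true viability curves.
#' @param regime One of `"loewe_additive"`, `"bliss_independent"`,
#'   `"synergy"`, `"antagonism"`.
#' @param interaction_strength Inhibition-fraction shift applied at
#'   combination cells in the synergy/antagonism regimes (default 0.2).
#' @param doses_a,doses_b Dose ladders including 0 (default two-fold ladder
#'   0 to 10 micromolar).
#' @param noise_cv Multiplicative (log-normal) noise CV on viability
#'   (default 0.05).
#' @param drug_a,drug_b Identifiers.
#' @param replicate_id Replicate label.
#' @param seed RNG seed (default 1).
#' @return A `matrix_sim_spec` list.
#' @export
matrix_sim_spec <- function(hill_a = list(top = 1, bottom = 0, ic50 = 1,
                                          hill = 1),
                            hill_b = list(top = 1, bottom = 0, ic50 = 2,
                                          hill = 1.5),
                            regime = c("loewe_additive", "bliss_independent",
                                       "synergy", "antagonism"),
                            interaction_strength = 0.2,
                            doses_a = c(0, 0.625, 1.25, 2.5, 5, 10),
                            doses_b = c(0, 0.625, 1.25, 2.5, 5, 10),
                            noise_cv = 0.05,
                            drug_a = "drug_a", drug_b = "drug_b",
                            replicate_id = 1L, seed = 1L) {
  regime <- match.arg(regime)
  structure(as.list(environment()), class = "matrix_sim_spec")
}

# fine-grid Loewe inversion on true Hill curves; deliberately independent of
# the bisection solver in loewe_surface() so it can serve as its oracle
.loewe_grid_effect <- function(hill_a, hill_b, d_a, d_b, n_grid = 200001L) {
  fa_at <- function(h, d) 1 - hill4(d, h$top, h$bottom, h$ic50, h$hill)
  dose_at <- function(h, E) {
    v <- 1 - E
    h$ic50 * ((h$top - v) / (v - h$bottom))^(1 / h$hill)
  }
  if (d_b == 0) return(fa_at(hill_a, d_a))
  if (d_a == 0) return(fa_at(hill_b, d_b))
  lo <- max(1 - hill_a$top, 1 - hill_b$top)
  hi <- min(1 - hill_a$bottom, 1 - hill_b$bottom)
  pad <- (hi - lo) * 1e-9
  E <- seq(lo + pad, hi - pad, length.out = n_grid)
  gv <- d_a / dose_at(hill_a, E) + d_b / dose_at(hill_b, E) - 1
  idx <- which(diff(sign(gv)) != 0)
  if (length(idx) == 0) return(if (gv[1] < 0) lo else hi)
  i <- idx[1]
  # linear interpolation across the sign change
  E[i] + (E[i + 1] - E[i]) * gv[i] / (gv[i] - gv[i + 1])
}

#' Simulate a two-drug dose matrix
#'
#' @param spec A [matrix_sim_spec()].
#' @return A [dose_matrix()]; the (0, 0) anchor is exactly 1 and margins
#'   follow the true single-agent curves (before noise).
#' @export
simulate_matrix <- function(spec) {
  stopifnot(inherits(spec, "matrix_sim_spec"))
  .with_local_seed(spec$seed, {
    da <- spec$doses_a; db <- spec$doses_b
    ha <- spec$hill_a; hb <- spec$hill_b
    sa <- hill4(da, ha$top, ha$bottom, ha$ic50, ha$hill)
    sb <- hill4(db, hb$top, hb$bottom, hb$ic50, hb$hill)
    v <- matrix(NA_real_, length(da), length(db))
    for (i in seq_along(da)) {
      for (j in seq_along(db)) {
        if (spec$regime == "bliss_independent") {
          v[i, j] <- sa[i] * sb[j]
        } else {
          fa_add <- .loewe_grid_effect(ha, hb, da[i], db[j])
          fa <- fa_add
          if (da[i] > 0 && db[j] > 0) {
            if (spec$regime == "synergy") {
              fa <- min(fa_add + spec$interaction_strength, 0.999)
            } else if (spec$regime == "antagonism") {
              fa <- max(fa_add - spec$interaction_strength, 0.001)
            }
          }
          v[i, j] <- 1 - fa
        }
      }
    }
    if (spec$noise_cv > 0) {
      sdlog <- sqrt(log(1 + spec$noise_cv^2))
      v <- v * exp(matrix(stats::rnorm(length(v), 0, sdlog), nrow(v)))
      v <- pmin(pmax(v, 0), 1.5)
    }
    v[1, 1] <- 1  # double-vehicle normalization anchor
    dose_matrix(v, da, db, drug_a = spec$drug_a, drug_b = spec$drug_b,
                replicate_id = spec$replicate_id)
  })
}

#' Specification of a synthetic tumor-growth study
#'
#' Exponential tumor growth with a treatment effect: control volumes follow
#' `V0 exp(r t)`; the treated growth rate is chosen so the expected
#' endpoint tumor growth inhibition equals `inhibition`. Baselines are drawn
#' uniformly from `baseline_range` at day 1 (randomization); measurements
#' carry log-normal noise.
#'
#' @param n_per_group Animals per group (default 7).
#' @param baseline_range Day-1 volume range in mm^3 (default `c(60, 100)`).
#' @param growth_rate Control exponential growth rate per day (default 0.08).
#' @param inhibition Target endpoint TGI as a fraction (default 0.39).
#' @param measurement_cv Log-normal measurement CV (default 0.1).
#' @param days Measurement schedule; day 1 is baseline (default twice weekly
#'   for four weeks).
#' @param seed RNG seed (default 1).
#' @return A `growth_sim_spec` list.
#' @export
growth_sim_spec <- function(n_per_group = 7L, baseline_range = c(60, 100),
                            growth_rate = 0.08, inhibition = 0.39,
                            measurement_cv = 0.1,
                            days = c(1L, 4L, 8L, 11L, 15L, 18L, 22L, 25L, 29L),
                            seed = 1L) {
  stopifnot(inhibition < 1, n_per_group >= 1, measurement_cv >= 0)
  structure(as.list(environment()), class = "growth_sim_spec")
}

#' Simulate a two-group tumor-growth study
#'
#' @param spec A [growth_sim_spec()].
#' @return A growth tibble (`animal_id`, `group`, `day`, `volume`); with zero
#'   measurement noise, [tgi()] at the last day returns
#'   `100 * spec$inhibition` exactly.
#' @export
simulate_growth <- function(spec) {
  stopifnot(inherits(spec, "growth_sim_spec"))
  .with_local_seed(spec$seed, {
    t_end <- max(spec$days) - min(spec$days)
    r_c <- spec$growth_rate
    r_t <- r_c + log(1 - spec$inhibition) / t_end
    sdlog <- if (spec$measurement_cv > 0) {
      sqrt(log(1 + spec$measurement_cv^2))
    } else 0
    rows <- list()
    for (grp in c("control", "treated")) {
      r <- if (grp == "control") r_c else r_t
      for (i in seq_len(spec$n_per_group)) {
        v0 <- stats::runif(1, spec$baseline_range[1], spec$baseline_range[2])
        v_true <- v0 * exp(r * (spec$days - min(spec$days)))
        noise <- if (sdlog > 0) {
          exp(stats::rnorm(length(spec$days), 0, sdlog))
        } else 1
        rows[[length(rows) + 1L]] <- tibble(
          animal_id = sprintf("%s_%02d", substr(grp, 1, 1), i),
          group = grp, day = as.integer(spec$days),
          volume = v_true * noise)
      }
    }
    validate_growth_table(bind_rows(rows), baseline_day = min(spec$days))
  })
}
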