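#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   across left_join bind_rows distinct n rename count pull if_else first
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map2 pmap imap compact
NULL

# canonical roles and arms used throughout the package
.roles <- c("compound", "vehicle_control", "anchor_control")
.arms <- c("single", "combo_with_anchor")

#' Convert well names to 1-based (row, col) coordinates
#'
#' Accepts alphanumeric plate-reader well labels (`"A1"`, `"A01"`, `"P24"`,
#' lower case tolerated) and returns 1-based row/column indices, so `"A01"`
#' maps to row 1, column 1.
#'
#' @param well Character vector of well labels.
#' @return A tibble with columns `row` and `col` (integers).
#' @examples
#' well_to_rowcol(c("A01", "B12", "P24"))
#' @export
well_to_rowcol <- function(well) {
  well <- toupper(trimws(as.character(well)))
  ok <- grepl("^[A-Z][0-9]{1,2}$", well)
  if (!all(ok)) {
    abort(paste0("unparseable well label(s): ",
                 paste(utils::head(well[!ok], 5L), collapse = ", ")))
  }
  tibble(
    row = match(substr(well, 1L, 1L), LETTERS),
    col = as.integer(sub("^[A-Z]", "", well))
  )
}

#' Convert (row, col) coordinates to well names
#'
#' @param row,col 1-based integer vectors; rows up to 26 are supported.
#' @return Character vector of zero-padded labels (`"A01"` style).
#' @export
rowcol_to_well <- function(row, col) {
  stopifnot(all(row >= 1L), all(row <= 26L), all(col >= 1L))
  sprintf("%s%02d", LETTERS[row], as.integer(col))
}

#' Validate a long-format plate table
#'
#' Checks the invariants a screen plate table must satisfy before scoring:
#' unique well addresses within each (plate, replicate), nonnegative signals,
#' vehicle-control wells free of compound annotations, and a minimum number of
#' vehicle wells per plate.
#'
#' @param plates A tibble as returned by [read_plate_table()].
#' @param min_vehicle_wells Minimum vehicle-control wells required per
#'   (plate, replicate); default 8.
#' @return The validated tibble, invisibly usable in a pipe.
#' @export
validate_plate_table <- function(plates, min_vehicle_wells = 8L) {
  req <- c("plate_id", "row", "col", "compound_id", "role", "arm",
           "concentration_um", "replicate", "signal")
  missing_cols <- setdiff(req, names(plates))
  if (length(missing_cols) > 0) {
    abort(paste0("plate table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(plates$role %in% .roles)) {
    abort(paste0("role must be one of: ", paste(.roles, collapse = ", ")))
  }
  if (!all(plates$arm %in% .arms)) {
    abort(paste0("arm must be one of: ", paste(.arms, collapse = ", ")))
  }
  if (any(!is.finite(plates$signal)) || any(plates$signal < 0)) {
    abort("signal must be finite and nonnegative")
  }
  dup <- plates |>
    count(.data$plate_id, .data$replicate, .data$row, .data$col) |>
    filter(n > 1L)
  if (nrow(dup) > 0) {
    abort(sprintf(
      "duplicated well address(es), e.g. plate %s replicate %d well %s",
      dup$plate_id[1], dup$replicate[1], rowcol_to_well(dup$row[1], dup$col[1])
    ))
  }
  veh <- plates$role == "vehicle_control"
  if (any(!is.na(plates$compound_id[veh])) ||
      any(!is.na(plates$concentration_um[veh]))) {
    abort("vehicle_control wells must not carry compound_id or concentration")
  }
  nveh <- plates |>
    group_by(.data$plate_id, .data$replicate) |>
    summarise(n_veh = sum(.data$role == "vehicle_control"), .groups = "drop")
  if (any(nveh$n_veh < min_vehicle_wells)) {
    bad <- nveh |> filter(.data$n_veh < min_vehicle_wells)
    abort(sprintf(
      "plate %s replicate %d has %d vehicle wells (< %d required)",
      bad$plate_id[1], bad$replicate[1], bad$n_veh[1], min_vehicle_wells
    ))
  }
  plates
}

#' Read a long-format plate table
#'
#' Reads delimited text holding one row per well (plate id, well address,
#' compound, role, arm, concentration, replicate, raw signal) and returns a
#' validated tibble in the package's canonical column layout. Well addresses
#' may be given either as an alphanumeric `well` column (`A01` style) or as
#' numeric `row`/`col` columns; both conventions yield identical tables.
#'
#' @param path Path to a CSV/TSV file (delimiter sniffed by extension).
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(signal = "lum")`.
#' @param min_vehicle_wells Passed to [validate_plate_table()].
#' @return A tibble with columns `plate_id`, `row`, `col`, `well`,
#'   `compound_id`, `role`, `arm`, `concentration_um`, `replicate`, `signal`.
#' @seealso [write_plate_table()] for the inverse.
#' @export
read_plate_table <- function(path, schema = NULL, min_vehicle_wells = 8L) {
  raw <- .read_delim(path)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(raw)) {
        abort(sprintf("schema maps '%s' to missing column '%s'",
                      canon, schema[[canon]]))
      }
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  if (!"row" %in% names(raw) && "well" %in% names(raw)) {
    rc <- well_to_rowcol(raw$well)
    raw$row <- rc$row
    raw$col <- rc$col
  }
  for (col in c("plate_id", "row", "col", "role", "arm", "replicate", "signal")) {
    if (!col %in% names(raw)) abort(paste0("plate table missing column: ", col))
  }
  bad_sig <- which(is.na(suppressWarnings(as.numeric(raw$signal))) &
                     !is.na(raw$signal))
  if (length(bad_sig) > 0) {
    abort(sprintf("non-numeric signal at data line %d: '%s'",
                  bad_sig[1], as.character(raw$signal[bad_sig[1]])))
  }
  out <- tibble(
    plate_id = as.character(raw$plate_id),
    row = as.integer(raw$row),
    col = as.integer(raw$col),
    compound_id = if ("compound_id" %in% names(raw)) {
      cid <- as.character(raw$compound_id)
      cid[!is.na(cid) & cid %in% c("", "NA", "CONTROL")] <- NA_character_
      cid
    } else NA_character_,
    role = as.character(raw$role),
    arm = as.character(raw$arm),
    concentration_um = if ("concentration_um" %in% names(raw)) {
      suppressWarnings(as.numeric(raw$concentration_um))
    } else NA_real_,
    replicate = as.integer(raw$replicate),
    signal = as.numeric(raw$signal)
  )
  out$well <- rowcol_to_well(out$row, out$col)
  out <- out[, c("plate_id", "row", "col", "well", "compound_id", "role",
                 "arm", "concentration_um", "replicate", "signal")]
  validate_plate_table(out, min_vehicle_wells = min_vehicle_wells)
}

#' Write a plate table to CSV
#'
#' @param plates Canonical plate tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(plates, path) {
  readr::write_csv(plates, path)
  invisible(path)
}

.read_delim <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

# ---- dose matrices ----------------------------------------------------------

#' Construct a two-drug dose matrix
#'
#' A dose matrix holds relative viability (fractions of the double-vehicle
#' cell) on a grid of dose combinations; ladders are ascending and include 0,
#' and the (0, 0) cell is the normalization anchor (viability 1).
#'
#' @param viability Numeric matrix, rows indexed by `doses_a`, columns by
#'   `doses_b`, values in \[0, 1.5\] (small >1 noise tolerated).
#' @param doses_a,doses_b Ascending dose ladders (micromolar) including 0.
#' @param drug_a,drug_b Drug identifiers.
#' @param replicate_id Integer replicate label.
#' @return An object of class `dose_matrix`.
#' @export
dose_matrix <- function(viability, doses_a, doses_b,
                        drug_a = "drug_a", drug_b = "drug_b",
                        replicate_id = 1L) {
  viability <- as.matrix(viability)
  if (nrow(viability) != length(doses_a) || ncol(viability) != length(doses_b)) {
    abort("viability grid dimensions must match dose ladder lengths")
  }
  if (is.unsorted(doses_a, strictly = TRUE) ||
      is.unsorted(doses_b, strictly = TRUE)) {
    abort("dose ladders must be strictly ascending")
  }
  if (doses_a[1] != 0 || doses_b[1] != 0) {
    abort("dose ladders must include 0 as the first (anchor) dose")
  }
  if (any(!is.finite(viability)) || any(viability < 0) ||
      any(viability > 1.5)) {
    abort("viability must be finite fractions in [0, 1.5]")
  }
  dimnames(viability) <- list(doses_a, doses_b)
  structure(
    list(drug_a = drug_a, drug_b = drug_b,
         doses_a = as.numeric(doses_a), doses_b = as.numeric(doses_b),
         viability = viability, replicate_id = as.integer(replicate_id)),
    class = "dose_matrix"
  )
}

#' @export
print.dose_matrix <- function(x, ...) {
  cat(sprintf("<dose_matrix> %s (rows) x %s (cols), %d x %d doses, replicate %d\n",
              x$drug_a, x$drug_b, length(x$doses_a), length(x$doses_b),
              x$replicate_id))
  print(round(x$viability, 3))
  invisible(x)
}

#' @export
as_tibble.dose_matrix <- function(x, ...) {
  tidyr::expand_grid(dose_a = x$doses_a, dose_b = x$doses_b) |>
    mutate(viability = as.vector(t(x$viability)),
           drug_a = x$drug_a, drug_b = x$drug_b,
           replicate_id = x$replicate_id)
}

#' Read a two-drug dose matrix from CSV
#'
#' Two encodings are accepted: a grid with dose headers on both axes (first
#' column = doses of drug A, remaining column names = doses of drug B), or a
#' long table with `dose_a`, `dose_b`, `viability` columns. Both readers
#' return identical objects for the same data.
#'
#' @param path CSV path.
#' @param format `"auto"` (default), `"grid"` or `"long"`.
#' @param percent If `TRUE`, values are percentages and are divided by 100 at
#'   the boundary; the internal canonical unit is always a fraction.
#' @param drug_a,drug_b,replicate_id Metadata overrides (used for grid input;
#'   long input may carry its own columns).
#' @return A [dose_matrix()].
#' @export
read_dose_matrix <- function(path, format = c("auto", "grid", "long"),
                             percent = FALSE,
                             drug_a = "drug_a", drug_b = "drug_b",
                             replicate_id = 1L) {
  format <- match.arg(format)
  raw <- .read_delim(path)
  if (format == "auto") {
    format <- if (all(c("dose_a", "dose_b", "viability") %in% names(raw))) {
      "long"
    } else "grid"
  }
  if (format == "long") {
    if ("drug_a" %in% names(raw)) drug_a <- raw$drug_a[1]
    if ("drug_b" %in% names(raw)) drug_b <- raw$drug_b[1]
    if ("replicate_id" %in% names(raw)) replicate_id <- raw$replicate_id[1]
    da <- sort(unique(raw$dose_a))
    db <- sort(unique(raw$dose_b))
    full <- tidyr::expand_grid(dose_a = da, dose_b = db)
    joined <- left_join(full, raw, by = c("dose_a", "dose_b"))
    if (any(is.na(joined$viability))) abort("ragged dose grid: missing cells")
    v <- matrix(joined$viability, nrow = length(da), ncol = length(db),
                byrow = TRUE)
  } else {
    da <- suppressWarnings(as.numeric(raw[[1]]))
    db <- suppressWarnings(as.numeric(names(raw)[-1]))
    if (any(is.na(da)) || any(is.na(db))) {
      abort("grid format requires numeric dose headers on both axes")
    }
    v <- as.matrix(raw[, -1, drop = FALSE])
    if (any(is.na(v))) abort("ragged dose grid: missing cells")
    ord_a <- order(da); ord_b <- order(db)
    da <- da[ord_a]; db <- db[ord_b]
    v <- v[ord_a, ord_b, drop = FALSE]
  }
  if (percent) v <- v / 100
  if (da[1] != 0 || db[1] != 0) {
    abort("dose matrix must include the (0, 0) vehicle anchor")
  }
  dose_matrix(v, da, db, drug_a = drug_a, drug_b = drug_b,
              replicate_id = replicate_id)
}

#' Write a dose matrix to CSV (grid layout)
#'
#' @param x A [dose_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dose_matrix <- function(x, path) {
  df <- as.data.frame(x$viability)
  names(df) <- as.character(x$doses_b)
  df <- cbind(dose_a = x$doses_a, df)
  readr::write_csv(as_tibble(df), path)
  invisible(path)
}

# ---- tumor growth tables ----------------------------------------------------

#' Read a longitudinal tumor-growth table
#'
#' One row per (animal, day) with positive volumes; every animal must carry a
#' day-1 baseline (day 1 = randomization), the denominator of the relative
#' tumor volume.
#'
#' @param path CSV/TSV path with columns `animal_id`, `group`, `day`, `volume`.
#' @param baseline_day Day used as baseline; default 1.
#' @return A validated tibble.
#' @export
read_growth_table <- function(path, baseline_day = 1L) {
  raw <- .read_delim(path)
  validate_growth_table(raw, baseline_day = baseline_day)
}

#' Validate a tumor-growth table
#'
#' @param growth Tibble with `animal_id`, `group`, `day`, `volume`.
#' @param baseline_day Required baseline day (default 1).
#' @return The validated tibble with canonical column types.
#' @export
validate_growth_table <- function(growth, baseline_day = 1L) {
  req <- c("animal_id", "group", "day", "volume")
  missing_cols <- setdiff(req, names(growth))
  if (length(missing_cols) > 0) {
    abort(paste0("growth table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble(
    animal_id = as.character(growth$animal_id),
    group = as.character(growth$group),
    day = as.integer(growth$day),
    volume = as.numeric(growth$volume)
  )
  if (any(!is.finite(out$volume)) || any(out$volume <= 0)) {
    abort("volumes must be positive")
  }
  if (length(unique(out$group)) < 2L) {
    abort("growth table needs at least two groups")
  }
  has_base <- out |>
    group_by(.data$animal_id) |>
    summarise(base = any(.data$day == baseline_day), .groups = "drop")
  if (any(!has_base$base)) {
    abort(sprintf("animal %s has no day-%d baseline",
                  has_base$animal_id[!has_base$base][1], baseline_day))
  }
  arrange(out, .data$group, .data$animal_id, .data$day)
}

#' Write a growth table to CSV
#'
#' @param growth Growth tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_growth_table <- function(growth, path) {
  readr::write_csv(growth, path)
  invisible(path)
}
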