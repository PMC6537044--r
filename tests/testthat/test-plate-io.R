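test_that("well labels and numeric coordinates are interchangeable", {
  expect_equal(well_to_rowcol("A01"), tibble::tibble(row = 1L, col = 1L))
  expect_equal(well_to_rowcol(c("a1", "P24"))$row, c(1L, 16L))
  expect_equal(rowcol_to_well(c(1L, 16L), c(1L, 24L)), c("A01", "P24"))
  # round trip over a whole 384-well plate
  grid <- expand.grid(row = 1:16, col = 1:24)
  rc <- well_to_rowcol(rowcol_to_well(grid$row, grid$col))
  expect_equal(rc$row, grid$row)
  expect_equal(rc$col, grid$col)
  expect_error(well_to_rowcol("1A"), "unparseable")
})

test_that("plate tables survive a write/read round trip and conserve counts", {
  plates <- simulate_screen(screen_sim_spec(n_compounds = 100L, seed = 7L))$plates
  path <- withr::local_tempfile(fileext = ".csv")
  write_plate_table(plates, path)
  back <- read_plate_table(path)
  expect_equal(nrow(back), nrow(plates))
  expect_equal(as.data.frame(back), as.data.frame(plates), tolerance = 1e-12)
  # a 384-well file with 2 replicates gives 768 rows per arm
  one_arm <- dplyr::filter(plates, arm == "single")
  expect_equal(nrow(one_arm), 2L * dplyr::n_distinct(
    paste(one_arm$plate_id, one_arm$row, one_arm$col)))
})

test_that("well-label and row/col input conventions load identically", {
  plates <- make_toy_plates()
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(plates, -well), p1)
  readr::write_csv(dplyr::select(plates, -row, -col), p2)
  t1 <- read_plate_table(p1, min_vehicle_wells = 4L)
  t2 <- read_plate_table(p2, min_vehicle_wells = 4L)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
})

test_that("invalid plate tables are rejected with informative errors", {
  plates <- make_toy_plates()
  dup <- dplyr::bind_rows(plates, plates[1, ])
  expect_error(validate_plate_table(dup, min_vehicle_wells = 4L),
               "duplicated well")
  bad_veh <- plates
  bad_veh$compound_id[bad_veh$role == "vehicle_control"][1] <- "X"
  expect_error(validate_plate_table(bad_veh, min_vehicle_wells = 4L),
               "vehicle_control")
  expect_error(validate_plate_table(plates, min_vehicle_wells = 8L),
               "vehicle wells")
  neg <- plates; neg$signal[3] <- -1
  expect_error(validate_plate_table(neg, min_vehicle_wells = 4L),
               "nonnegative")
  path <- withr::local_tempfile(fileext = ".csv")
  broken <- plates; broken$signal <- as.character(broken$signal)
  broken$signal[5] <- "oops"
  readr::write_csv(broken, path)
  expect_error(read_plate_table(path, min_vehicle_wells = 4L), "non-numeric")
})

test_that("schema mapping renames columns and names missing ones", {
  plates <- make_toy_plates() |> dplyr::rename(lum = signal)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(plates, path)
  t <- read_plate_table(path, schema = c(signal = "lum"),
                        min_vehicle_wells = 4L)
  expect_true("signal" %in% names(t))
  expect_error(read_plate_table(path, schema = c(signal = "nope"),
                                min_vehicle_wells = 4L), "nope")
})

test_that("dose matrices read identically from grid and long encodings", {
  m <- simulate_matrix(matrix_sim_spec(seed = 21L))
  pg <- withr::local_tempfile(fileext = ".csv")
  pl <- withr::local_tempfile(fileext = ".csv")
  write_dose_matrix(m, pg)
  readr::write_csv(tibble::as_tibble(m), pl)
  mg <- read_dose_matrix(pg)
  ml <- read_dose_matrix(pl)
  expect_equal(mg$viability, ml$viability, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(mg$doses_a, ml$doses_a)
  # 6x6 ladder conservation
  expect_length(mg$doses_a, 6L)
  expect_length(mg$doses_b, 6L)
})

test_that("dose-matrix validation enforces the anchor, shape, and units", {
  v <- matrix(1, 3, 3)
  expect_silent(dose_matrix(v, c(0, 1, 2), c(0, 1, 2)))        # inert matrix
  expect_error(dose_matrix(v, c(1, 2, 3), c(0, 1, 2)), "anchor|include 0")
  expect_error(dose_matrix(v[, 1:2], c(0, 1, 2), c(0, 1, 2)), "dimensions")
  expect_error(dose_matrix(v, c(0, 2, 1), c(0, 1, 2)), "ascending")
  # percent inputs are converted to fractions at the boundary
  p <- withr::local_tempfile(fileext = ".csv")
  m <- dose_matrix(matrix(c(1, .8, .6, .4), 2, 2), c(0, 1), c(0, 1))
  df <- tibble::tibble(dose_a = c(0, 0, 1, 1), dose_b = c(0, 1, 0, 1),
                       viability = c(100, 60, 80, 40))
  readr::write_csv(df, p)
  mp <- read_dose_matrix(p, percent = TRUE)
  expect_equal(mp$viability, m$viability, ignore_attr = TRUE)
})

test_that("growth tables validate baselines and round trip", {
  g <- simulate_growth(growth_sim_spec(seed = 31L))
  expect_equal(nrow(g), 14L * 9L)   # 14 animals x 9 timepoints
  path <- withr::local_tempfile(fileext = ".csv")
  write_growth_table(g, path)
  expect_equal(as.data.frame(read_growth_table(path)), as.data.frame(g),
               tolerance = 1e-12)
  no_base <- dplyr::filter(g, !(animal_id == "c_01" & day == 1L))
  expect_error(validate_growth_table(no_base), "baseline")
  neg <- g; neg$volume[5] <- 0
  expect_error(validate_growth_table(neg), "positive")
})
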