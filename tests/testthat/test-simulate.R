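test_that("generators are pure functions of their spec", {
  s1 <- simulate_screen(screen_sim_spec(n_compounds = 200L, seed = 12L))
  s2 <- simulate_screen(screen_sim_spec(n_compounds = 200L, seed = 12L))
  expect_identical(s1, s2)
  s3 <- simulate_screen(screen_sim_spec(n_compounds = 200L, seed = 13L))
  expect_false(identical(s1$plates$signal, s3$plates$signal))

  m1 <- simulate_matrix(matrix_sim_spec(seed = 12L))
  m2 <- simulate_matrix(matrix_sim_spec(seed = 12L))
  expect_identical(m1, m2)

  g1 <- simulate_growth(growth_sim_spec(seed = 12L))
  expect_identical(g1, simulate_growth(growth_sim_spec(seed = 12L)))
  # the global RNG stream is left untouched
  set.seed(99); before <- .Random.seed
  invisible(simulate_screen(screen_sim_spec(n_compounds = 50L, seed = 1L)))
  expect_identical(.Random.seed, before)
})

test_that("screen generator plants what it says it plants", {
  spec0 <- screen_sim_spec(n_compounds = 100L, active_fraction = 0, seed = 3L)
  sim0 <- simulate_screen(spec0)
  expect_equal(sum(sim0$truth$is_active), 0L)
  expect_equal(sum(sim0$truth$is_potentiated), 0L)

  # no gradients, no noise: every non-active single-arm well sits at the
  # plate offset exactly
  spec <- screen_sim_spec(n_compounds = 100L, active_fraction = 0,
                          row_gradient = 0, col_gradient = 0,
                          plate_offset = 0, noise_sd = 0, anchor_effect = 0,
                          base_log = 2, seed = 4L)
  sim <- simulate_screen(spec)
  expect_equal(unique(sim$plates$signal), exp(2))

  # geometry: controls in the first and last columns, compounds between
  full <- simulate_screen(screen_sim_spec(seed = 5L))
  expect_true(all(full$plates$col[full$plates$role == "vehicle_control"] == 1L))
  expect_true(all(full$plates$col[full$plates$role == "anchor_control"] == 24L))
  expect_true(all(dplyr::between(
    full$plates$col[full$plates$role == "compound"], 2L, 23L)))
  expect_equal(dplyr::n_distinct(full$plates$compound_id, na.rm = TRUE), 1200L)
})

test_that("matrix generator margins and regimes follow their construction", {
  ha <- list(top = 1, bottom = 0.05, ic50 = 0.8, hill = 1.4)
  hb <- list(top = 1, bottom = 0, ic50 = 2.5, hill = 0.9)
  for (reg in c("loewe_additive", "bliss_independent", "synergy",
                "antagonism")) {
    m <- simulate_matrix(matrix_sim_spec(hill_a = ha, hill_b = hb,
                                         regime = reg, noise_cv = 0,
                                         seed = 8L))
    expect_equal(m$viability[, 1],
                 hill4(m$doses_a, ha$top, ha$bottom, ha$ic50, ha$hill),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(m$viability[1, ],
                 hill4(m$doses_b, hb$top, hb$bottom, hb$ic50, hb$hill),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(m$viability[1, 1], 1)
  }
  # bliss: cell survival is exactly the product of margins
  mb <- simulate_matrix(matrix_sim_spec(hill_a = ha, hill_b = hb,
                                        regime = "bliss_independent",
                                        noise_cv = 0, seed = 8L))
  expect_equal(mb$viability, outer(mb$viability[, 1], mb$viability[1, ]),
               tolerance = 1e-9, ignore_attr = TRUE)
  # synergy at zero interaction strength degenerates to additivity
  msyn0 <- simulate_matrix(matrix_sim_spec(hill_a = ha, hill_b = hb,
                                           regime = "synergy",
                                           interaction_strength = 0,
                                           noise_cv = 0, seed = 8L))
  madd <- simulate_matrix(matrix_sim_spec(hill_a = ha, hill_b = hb,
                                          regime = "loewe_additive",
                                          noise_cv = 0, seed = 8L))
  expect_equal(msyn0$viability, madd$viability, tolerance = 1e-12)
})

test_that("growth generator hits its target inhibition exactly without noise", {
  g <- simulate_growth(growth_sim_spec(inhibition = 0.39, measurement_cv = 0,
                                       seed = 14L))
  expect_equal(tgi(compute_rtv(g), day = 29L), 39, tolerance = 1e-9)
  g2 <- simulate_growth(growth_sim_spec(inhibition = 0, measurement_cv = 0,
                                        seed = 14L))
  expect_equal(tgi(compute_rtv(g2), day = 29L), 0, tolerance = 1e-9)
})

test_that("heavy-tailed contamination barely moves robust scores", {
  clean <- simulate_screen(screen_sim_spec(n_compounds = 352L, seed = 15L))
  dirty <- simulate_screen(screen_sim_spec(n_compounds = 352L,
                                           contamination_fraction = 0.02,
                                           seed = 15L))
  sc_c <- score_plates(clean$plates)
  sc_d <- score_plates(dirty$plates)
  ref_c <- dplyr::distinct(dplyr::filter(sc_c, role == "compound"),
                           plate_id, replicate, arm, mad_ref)
  ref_d <- dplyr::distinct(dplyr::filter(sc_d, role == "compound"),
                           plate_id, replicate, arm, mad_ref)
  m <- dplyr::inner_join(ref_c, ref_d,
                         by = c("plate_id", "replicate", "arm"))
  expect_lt(max(abs(m$mad_ref.y / m$mad_ref.x - 1)), 0.25)
})
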