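hill_fa <- function(d, dm, m) (d / dm)^m / (1 + (d / dm)^m)

test_that("median-effect fits recover exact and noisy parameters", {
  d <- c(0.25, 0.5, 1, 2, 4)
  f <- fit_median_effect(d, hill_fa(d, 1, 1))
  expect_equal(f$dm, 1, tolerance = 1e-9)
  expect_equal(f$m, 1, tolerance = 1e-9)
  # fa = 0.5 at dose 2 pins Dm = 2 by definition
  f2 <- fit_median_effect(c(2, 4), hill_fa(c(2, 4), 2, 1.5))
  expect_equal(f2$dm, 2, tolerance = 1e-9)
  # binomial counting noise, n = 1000 cells per dose
  set.seed(19)
  d6 <- c(0.125, 0.25, 0.5, 1, 2, 4, 8)
  fa_noisy <- rbinom(length(d6), 1000, hill_fa(d6, 1.3, 1.8)) / 1000
  f3 <- fit_median_effect(d6, fa_noisy)
  expect_lt(abs(f3$dm / 1.3 - 1), 0.10)
  expect_error(fit_median_effect(d, rep(1, 5)), "infeasible")
  expect_equal(effect_dose(f, 0.5), f$dm)
  expect_true(is.na(effect_dose(f, 1)))
})

test_that("the Loewe prediction restricted to either axis is the single-agent curve", {
  m <- simulate_matrix(matrix_sim_spec(noise_cv = 0, seed = 41L))
  fa <- fit_4pl(m$doses_a, m$viability[, 1])
  fb <- fit_4pl(m$doses_b, m$viability[1, ])
  surf <- loewe_surface(fa, fb, m, tol = 1e-8)
  expect_equal(surf$predicted[, 1], 1 - predict(fa, data.frame(dose = m$doses_a)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(surf$predicted[1, ], 1 - predict(fb, data.frame(dose = m$doses_b)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("bisection agrees with an independent fine-grid inversion", {
  set.seed(43)
  for (i in 1:10) {
    fa <- structure(list(top = 1, bottom = runif(1, 0, 0.15),
                         ic50 = exp(runif(1, -1, 1.5)),
                         hill = runif(1, 0.7, 2.5), converged = TRUE),
                    class = "fit_4pl")
    fb <- structure(list(top = 1, bottom = runif(1, 0, 0.15),
                         ic50 = exp(runif(1, -1, 1.5)),
                         hill = runif(1, 0.7, 2.5), converged = TRUE),
                    class = "fit_4pl")
    d_a <- exp(runif(1, -1, 1.5)); d_b <- exp(runif(1, -1, 1.5))
    m <- dose_matrix(matrix(1, 2, 2), c(0, d_a), c(0, d_b))
    surf <- loewe_surface(fa, fb, m, tol = 1e-8)
    oracle <- oracle_loewe_effect(fa, fb, d_a, d_b)
    expect_equal(surf$predicted[2, 2], oracle, tolerance = 1e-4)
  }
})

test_that("a drug combined with itself is exactly additive (sham combination)", {
  h <- list(top = 1, bottom = 0, ic50 = 1.2, hill = 1.6)
  m <- simulate_matrix(matrix_sim_spec(hill_a = h, hill_b = h,
                                       regime = "loewe_additive",
                                       noise_cv = 0, seed = 47L))
  res <- synergy_analysis(m)
  interior <- outer(seq_along(m$doses_a) > 1, seq_along(m$doses_b) > 1, `&`)
  expect_lt(max(abs(res$loewe_excess[interior])), 2)  # percentage points
  # CI on the diagonal split (d/2, d/2) at the true combined effect is 1
  me <- fit_median_effect(m$doses_a, 1 - m$viability[, 1])
  for (d in c(0.5, 1, 2, 5)) {
    fa_d <- hill_fa(d, 1.2, 1.6)
    expect_equal(chou_talalay_ci(me, me, d / 2, d / 2, fa_d), 1,
                 tolerance = 1e-6)
  }
})

test_that("equal-slope Loewe-additive combinations have CI = 1 analytically", {
  me_a <- fit_median_effect(c(0.5, 1, 2, 4), hill_fa(c(0.5, 1, 2, 4), 1, 2))
  me_b <- fit_median_effect(c(0.5, 1, 2, 4), hill_fa(c(0.5, 1, 2, 4), 3, 2))
  # with equal slopes the Loewe surface is linear in dose fractions:
  # fa at (d_a, d_b) solves d_a/Dx_a(fa) + d_b/Dx_b(fa) = 1
  for (frac in c(0.25, 0.5, 0.75)) {
    fa_target <- 0.6
    dxa <- effect_dose(me_a, fa_target); dxb <- effect_dose(me_b, fa_target)
    ci <- chou_talalay_ci(me_a, me_b, frac * dxa, (1 - frac) * dxb, fa_target)
    expect_equal(ci, 1, tolerance = 1e-6)
  }
})

test_that("CI is monotone decreasing in the observed effect", {
  me_a <- fit_median_effect(c(0.5, 1, 2, 4), hill_fa(c(0.5, 1, 2, 4), 1, 1.5))
  me_b <- fit_median_effect(c(0.5, 1, 2, 4), hill_fa(c(0.5, 1, 2, 4), 2, 1.2))
  fa_seq <- seq(0.1, 0.9, by = 0.1)
  ci_seq <- chou_talalay_ci(me_a, me_b, 1, 1, fa_seq)
  expect_true(all(diff(ci_seq) < 0))
})

test_that("Loewe excess is zero when observed equals predicted and flags >10%", {
  m <- simulate_matrix(matrix_sim_spec(noise_cv = 0, seed = 53L))
  fa <- fit_4pl(m$doses_a, m$viability[, 1])
  fb <- fit_4pl(m$doses_b, m$viability[1, ])
  surf <- loewe_surface(fa, fb, m)
  self <- m
  self$viability <- 1 - surf$predicted     # observed == predicted
  expect_equal(max(abs(loewe_excess(self, surf))), 0, tolerance = 1e-12)
  expect_error(loewe_excess(m, surf$predicted[1:3, 1:3]), "shape")
  # a cell with 12 points of excess is called at the 10-point threshold
  res <- synergy_analysis(m, loewe_thresh = 10)
  bumped <- m
  bumped$viability[4, 4] <- max(0, 1 - (surf$predicted[4, 4] + 0.12))
  res2 <- synergy_analysis(bumped, loewe_thresh = 10)
  expect_equal(res2$calls[4, 4], "synergy-leaning")
})

test_that("planted synergy and antagonism are detected; Bliss differs from Loewe", {
  syn <- synergy_analysis(simulate_matrix(matrix_sim_spec(
    regime = "synergy", interaction_strength = 0.2, seed = 59L)))
  interior <- outer(seq_along(syn$matrix$doses_a) > 1,
                    seq_along(syn$matrix$doses_b) > 1, `&`)
  defined <- !is.na(syn$ci)
  expect_true(all(syn$ci[defined] < 1))
  expect_equal(syn$summary$verdict, "potentiation")

  add <- synergy_analysis(simulate_matrix(matrix_sim_spec(
    regime = "loewe_additive", seed = 61L)))
  expect_equal(add$summary$verdict, "no potentiation")

  ant <- synergy_analysis(simulate_matrix(matrix_sim_spec(
    regime = "antagonism", interaction_strength = 0.2, seed = 67L)))
  expect_equal(ant$summary$verdict, "no potentiation")
  expect_lt(ant$summary$median_excess, -10)

  # equal-slope Bliss surface shows systematic nonzero Loewe excess
  h <- list(top = 1, bottom = 0, ic50 = 1, hill = 1)
  bliss <- synergy_analysis(simulate_matrix(matrix_sim_spec(
    hill_a = h, hill_b = h, regime = "bliss_independent",
    noise_cv = 0, seed = 71L)))
  inner <- bliss$loewe_excess[interior]
  expect_gt(mean(inner), 1)          # consistent positive sign
  expect_gt(mean(inner > 0), 0.9)
})

test_that("cells where the combination beats both single agents are left undefined", {
  m <- simulate_matrix(matrix_sim_spec(noise_cv = 0, seed = 73L))
  strong <- m
  strong$viability[5:6, 5:6] <- 0.001   # beyond either margin's best effect
  res <- synergy_analysis(strong)
  expect_true(all(is.na(res$ci[5:6, 5:6])))
  expect_true(all(res$grey[5:6, 5:6]))
})
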