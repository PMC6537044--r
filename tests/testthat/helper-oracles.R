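# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# two-sided Fisher exact p by direct hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b      # row 1 total
  n <- c + d      # row 2 total
  k <- a + c      # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-tailed rank-sum p by exhaustive enumeration of group assignments
oracle_ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(nx + ny, nx)
  ws <- apply(combos, 2L, function(idx) sum(r[idx]))
  mu <- nx * (nx + ny + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# coarse-lattice grid search of the 4PL least-squares problem
oracle_4pl_grid_rss <- function(dose, viability, ic50_grid, hill_grid) {
  best <- Inf
  for (ic in ic50_grid) {
    for (h in hill_grid) {
      # profile out top/bottom by linear least squares given (ic50, hill)
      f <- 1 / (1 + (dose / ic)^h)
      f[dose == 0] <- 1
      X <- cbind(1 - f, f)   # v = bottom*(1-f) + top*f
      fit <- stats::lm.fit(X, viability)
      best <- min(best, sum(fit$residuals^2))
    }
  }
  best
}

# fine-grid Loewe inversion on fitted 4PL curves (independent of the
# bisection in loewe_surface and of the generator's true-curve version)
oracle_loewe_effect <- function(fit_a, fit_b, d_a, d_b, n = 400001L) {
  inv <- function(f, E) {
    v <- 1 - E
    f$ic50 * ((f$top - v) / (v - f$bottom))^(1 / f$hill)
  }
  lo <- max(1 - fit_a$top, 1 - fit_b$top)
  hi <- min(1 - fit_a$bottom, 1 - fit_b$bottom)
  E <- seq(lo + (hi - lo) * 1e-9, hi - (hi - lo) * 1e-9, length.out = n)
  g <- d_a / inv(fit_a, E) + d_b / inv(fit_b, E) - 1
  i <- which(diff(sign(g)) != 0)[1]
  if (is.na(i)) return(if (g[1] < 0) lo else hi)
  E[i] + (E[i + 1] - E[i]) * g[i] / (g[i] - g[i + 1])
}

# small deterministic plate tibble: one plate, two replicates, one arm
make_toy_plates <- function(n_rows = 4L, n_cols = 6L, seed = 100L,
                            arm = "single") {
  withr::with_seed(seed, {
    grid <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
    purrr::map(1:2, function(rep_i) {
      tibble::tibble(
        plate_id = "P1",
        row = grid$row, col = grid$col,
        well = rowcol_to_well(grid$row, grid$col),
        compound_id = ifelse(grid$col == 1L, NA_character_,
                             sprintf("C%02d", seq_len(nrow(grid)))),
        role = ifelse(grid$col == 1L, "vehicle_control", "compound"),
        arm = arm,
        concentration_um = ifelse(grid$col == 1L, NA_real_, 10),
        replicate = rep_i,
        signal = exp(rnorm(nrow(grid), 12, 0.2))
      )
    }) |> purrr::list_rbind()
  })
}
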