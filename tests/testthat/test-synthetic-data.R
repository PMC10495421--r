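# Synthetic-data generator: seeded determinism, structural expansion,
# stationarity control, and fixed-point behaviour of the simulator.

test_that("dimension scores are reproducible, well shaped, non-degenerate", {
  cfg <- sim_config(seed = 11)
  d1 <- sim_dimension_scores(cfg)
  d2 <- sim_dimension_scores(cfg)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 24)
  expect_equal(emodyn:::dim_names(d1), c("dim_1", "dim_2", "dim_3"))
  expect_length(d1$dict_size, 24)
  expect_true(all(d1$dict_size >= 1 & d1$dict_size == round(d1$dict_size)))

  for (s in 1:100) {
    d <- sim_dimension_scores(sim_config(n_emotions = 5, seed = s))
    expect_true(all(vapply(d[c("dim_1", "dim_2", "dim_3")], var, numeric(1)) > 0))
  }
  expect_error(sim_config(n_emotions = 1), class = "emodyn_config_error")
  expect_error(sim_config(target_spectral_radius = 1.2), class = "emodyn_config_error")
  expect_error(sim_config(exog_break_fractions = c(0.9, 0.5)), class = "emodyn_config_error")
})

test_that("structural truth expands exactly per the defining equations", {
  sim <- make_sim(seed = 21, n_emotions = 8, n_days = 50)
  sh <- sim$truth$truth$shared_list
  dimsc <- center_scores(sim$dims)
  DIM <- as.matrix(dimsc[c("dim_1", "dim_2", "dim_3")])
  S <- dimsc$dict_size
  g <- sim$truth$coeffs$gamma

  # diagonal: carryover equation
  expect_equal(unname(diag(g)),
               sh$lambda_0 + drop(DIM %*% sh$lambda) + sh$lambda_S * S,
               tolerance = 1e-12)
  # off-diagonal: transition equation with asymmetric distances
  dist <- asymmetric_distances(dimsc)
  for (pair in list(c(1, 2), c(3, 7), c(8, 4))) {
    i <- pair[1]; j <- pair[2]
    dd <- dplyr::filter(dist, destination == dimsc$emotion[i],
                        source == dimsc$emotion[j])
    expect_equal(unname(g[i, j]),
                 sh$tau_0 + sum(sh$tau_up * dd$dist_up) +
                   sum(sh$tau_down * dd$dist_down) + sh$tau_S * S[i],
                 tolerance = 1e-12)
  }
  # intercepts: base-level equation
  expect_equal(unname(sim$truth$coeffs$alpha),
               sh$mu_0 + drop(DIM %*% sh$mu) + sh$mu_S * S,
               tolerance = 1e-12)

  # structural consistency: re-expanding the (rescaled) truth reproduces
  # the matrices used for simulation, exactly
  co2 <- expand_truth(sh, sim$dims, sim$truth$coeffs$beta, sim$truth$coeffs$sigma)
  expect_identical(co2$gamma, sim$truth$coeffs$gamma)
  expect_identical(co2$alpha, sim$truth$coeffs$alpha)
})

test_that("rescaling keeps the spectral radius at or below target", {
  for (s in 1:100) {
    cfg <- sim_config(n_emotions = 8, seed = s, target_spectral_radius = 0.9)
    tr <- sim_structured_params(sim_dimension_scores(cfg), cfg)
    expect_lte(emodyn:::spectral_radius(tr$coeffs$gamma), 0.9 + 1e-10)
  }
})

test_that("noise-free simulation follows the deterministic recursion", {
  cfg <- sim_config(n_emotions = 5, n_days = 60, n_exog = 0,
                    exog_break_fractions = numeric(0), burn_in = 0, seed = 31)
  tr <- sim_structured_params(sim_dimension_scores(cfg), cfg)
  co <- tr$coeffs
  co$sigma[] <- 0
  n <- 5

  # started at the fixed point, the path is constant
  fp <- solve(diag(n) - co$gamma, co$alpha)
  panel <- simulate_panel(co, cfg)
  E <- emodyn:::panel_matrix(panel)
  expect_lt(max(abs(sweep(E, 2, fp))), 1e-10)

  # from an arbitrary start, it matches direct iteration and converges
  # geometrically to the fixed point
  init <- fp + c(0.3, -0.2, 0.1, 0.05, -0.1)
  panel2 <- simulate_panel(co, cfg, init = init)
  E2 <- emodyn:::panel_matrix(panel2)
  oracle <- iterate_var(co$alpha, co$gamma, co$beta,
                        matrix(0, 60, 0), init, 60)
  expect_lt(max(abs(E2 - oracle)), 1e-12)
  dev <- sqrt(rowSums(sweep(E2, 2, fp)^2))
  rho <- emodyn:::spectral_radius(co$gamma)
  expect_lt(dev[60], dev[1] * (rho + 0.05)^40)

  # non-stationary systems are refused
  co_bad <- co
  co_bad$gamma <- diag(1.01, n)
  expect_error(simulate_panel(co_bad, cfg), class = "emodyn_simulation_error")
})

test_that("long-run sample mean matches the analytic stationary mean", {
  cfg <- sim_config(n_emotions = 4, n_days = 20000, n_exog = 0,
                    exog_break_fractions = numeric(0), seed = 41)
  tr <- sim_structured_params(sim_dimension_scores(cfg), cfg)
  panel <- simulate_panel(tr$coeffs, cfg)
  E <- emodyn:::panel_matrix(panel)
  mu <- solve(diag(4) - tr$coeffs$gamma, tr$coeffs$alpha)
  expect_lt(max(abs(colMeans(E) - mu)), 2e-3)
})

test_that("step dummies switch on at the configured break fractions", {
  sim <- make_sim(seed = 51, n_emotions = 4, n_days = 200)
  X <- emodyn:::panel_exog(sim$panel)
  expect_equal(colnames(X), c("X_1", "X_2"))
  expect_equal(unname(colSums(X == 0)), floor(c(0.75, 0.87) * 200))
  expect_true(all(apply(X, 2, function(x) all(diff(x) >= 0))))
})
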