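# Restricted design construction and FGLS estimation.

test_that("the stacked design has the documented shared-column structure", {
  # N = 2, K = 1, M = 0: 4K + 6 = 10 shared columns in documented order
  cfg <- sim_config(n_emotions = 2, n_dims = 1, n_days = 30, n_exog = 0,
                    exog_break_fractions = numeric(0), seed = 1)
  dims <- sim_dimension_scores(cfg)
  tr <- sim_structured_params(dims, cfg)
  panel <- simulate_panel(tr$coeffs, cfg)
  des <- build_design(panel, dims)
  expect_equal(des$p_shared, 10L)
  expect_equal(des$terms,
               c("mu_0", "mu_dim_1", "mu_dict_size",
                 "lambda_0", "lambda_dim_1", "lambda_dict_size",
                 "tau_0", "tau_up_dim_1", "tau_down_dim_1", "tau_dict_size"))
  # the carryover-intercept regressor is the own lag, exactly
  E <- emodyn:::panel_matrix(panel)
  for (i in 1:2) {
    expect_identical(unname(des$X[, "lambda_0", i]), unname(E[1:29, i]))
  }
})

test_that("the design with truth parameters reproduces the VAR recursion", {
  sim <- make_sim(seed = 61, n_emotions = 6, n_days = 120)
  des <- build_design(sim$panel, sim$dims)
  theta <- c(sim$truth$truth$shared[des$terms[1:des$p_shared]],
             as.vector(t(sim$truth$coeffs$beta)))
  fitted <- emodyn:::fitted_matrix(des$X, unname(theta))
  E <- emodyn:::panel_matrix(sim$panel)
  X <- emodyn:::panel_exog(sim$panel)
  tt <- nrow(E)
  direct <- sweep(E[1:(tt - 1), ] %*% t(sim$truth$coeffs$gamma), 2,
                  -sim$truth$coeffs$alpha) +
    X[2:tt, ] %*% t(sim$truth$coeffs$beta)
  expect_lt(max(abs(fitted - direct)), 1e-10)
})

test_that("GLS with spherical weights equals pooled OLS", {
  sim <- make_sim(seed = 71, n_emotions = 6, n_days = 150)
  des <- build_design(sim$panel, sim$dims)
  n <- length(des$emotions)
  f_ols <- estimate_fgls(des, sigma = diag(1, n))
  f_sph <- estimate_fgls(des, sigma = diag(3.7, n))
  expect_lt(max(abs(f_ols$estimates - f_sph$estimates)), 1e-8)
})

test_that("noiseless data yield exact recovery of all shared parameters", {
  sim <- make_sim(seed = 81, n_emotions = 8, n_days = 300, sigma_zero = TRUE)
  fit <- fit_emotion_var(sim$panel, sim$dims)
  tru <- sim$truth$truth$shared
  expect_lt(max(abs(fit$params$shared[names(tru)] - tru)), 1e-8)
  expect_lt(max(abs(fit$params$beta - sim$truth$coeffs$beta)), 1e-8)
  # expansion round-trips the truth matrices
  expect_lt(max(abs(fit$coeffs$gamma - sim$truth$coeffs$gamma)), 1e-8)
  expect_lt(max(abs(fit$coeffs$alpha - sim$truth$coeffs$alpha)), 1e-8)
})

test_that("parameter RMSE shrinks as the panel lengthens", {
  rmse_at <- function(tt) {
    errs <- vapply(1:3, function(r) {
      sim <- make_sim(seed = 900 + r, n_emotions = 8, n_days = tt)
      fit <- fit_emotion_var(sim$panel, sim$dims)
      tru <- sim$truth$truth$shared
      sqrt(mean((fit$params$shared[names(tru)] - tru)^2))
    }, numeric(1))
    mean(errs)
  }
  expect_lt(rmse_at(3000), rmse_at(200))
})

test_that("sigma_hat is consistent with the final residual covariance", {
  sim <- make_sim(seed = 91, n_emotions = 6, n_days = 400)
  fit <- fit_emotion_var(sim$panel, sim$dims)
  res_cov <- crossprod(fit$params$residuals) / fit$params$n_obs
  rel <- norm(res_cov - fit$params$sigma_hat, "F") / norm(fit$params$sigma_hat, "F")
  expect_lt(rel, 0.05)
  # and iterating to convergence closes the gap further
  des <- build_design(sim$panel, sim$dims)
  fit_it <- estimate_fgls(des, iterate = TRUE)
  res_cov2 <- crossprod(fit_it$residuals) / fit_it$n_obs
  rel2 <- norm(res_cov2 - fit_it$sigma_hat, "F") / norm(fit_it$sigma_hat, "F")
  expect_lte(rel2, rel + 1e-12)
})

test_that("a collinear design is refused with the offending columns named", {
  sim <- make_sim(seed = 95, n_emotions = 6, n_days = 100)
  dims_bad <- sim$dims
  dims_bad$dim_2 <- 2 * dims_bad$dim_1   # duplicated appraisal direction
  expect_error(fit_emotion_var(sim$panel, dims_bad),
               class = "emodyn_estimation_error")
})

test_that("expanded coefficient asymmetry follows the tau contrasts", {
  sim <- make_sim(seed = 97, n_emotions = 7, n_days = 60)
  g <- sim$truth$coeffs$gamma
  sh <- sim$truth$truth$shared_list
  dimsc <- center_scores(sim$dims)
  da <- emodyn:::dist_arrays(asymmetric_distances(dimsc), dimsc$emotion,
                             emodyn:::dim_names(dimsc))
  S <- dimsc$dict_size
  for (i in 1:7) for (j in seq_len(7)[-i]) {
    lhs <- g[i, j] - g[j, i] - (sh$tau_S * (S[i] - S[j]))
    rhs <- sum((sh$tau_up - sh$tau_down) * (da$up[i, j, ] - da$down[i, j, ]))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  # all tau zero makes the matrix diagonal
  sh0 <- sh
  sh0$tau_0 <- 0; sh0$tau_up[] <- 0; sh0$tau_down[] <- 0; sh0$tau_S <- 0
  co0 <- expand_truth(sh0, sim$dims, sim$truth$coeffs$beta, sim$truth$coeffs$sigma)
  expect_true(all(co0$gamma[row(co0$gamma) != col(co0$gamma)] == 0))
})

test_that("the symmetry Wald statistic is zero at the null point", {
  sim <- make_sim(seed = 99, n_emotions = 6, n_days = 200)
  fit <- fit_emotion_var(sim$panel, sim$dims)
  fit$params$shared[["tau_up_dim_1"]] <- 0.002
  fit$params$shared[["tau_down_dim_1"]] <- 0.002
  w <- wald_symmetry(fit, "dim_1")
  expect_equal(w$statistic, 0, tolerance = 1e-12)
  expect_equal(w$p.value, 1)
  expect_error(wald_symmetry(fit, "no_such_dim"))
})
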