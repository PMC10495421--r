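# Duration intervals, shock vectors, IRF/CIRF propagation and the
# pair-level distance regressions.

test_that("duration intervals follow the cumulative-effect formula", {
  # baseline carryover of an average emotion: about two weeks
  expect_equal(round(duration_interval(0.855983, 90), 1), 13.8)
  # oracle: smallest continuous x with 1 - lambda^(x + 1) = P/100
  oracle <- function(lambda, p) log1p(-p / 100) / log(lambda) - 1
  for (lam in c(0.2, 0.5, 0.9, 0.99)) {
    for (p in c(10, 50, 90, 99)) {
      expect_equal(duration_interval(lam, p), oracle(lam, p), tolerance = 1e-12)
    }
  }
  expect_equal(duration_interval(0.5, 90), 2.321928, tolerance = 1e-6)
  # P -> 0+ limit is -1
  expect_equal(duration_interval(0.7, 1e-8), -1, tolerance = 1e-6)
  # strictly increasing in lambda and in P
  lams <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(duration_interval(lams, 90)) > 0))
  ps <- seq(5, 95, by = 5)
  expect_true(all(diff(vapply(ps, function(p) duration_interval(0.8, p), numeric(1))) > 0))
  expect_error(duration_interval(1.2, 90), class = "emodyn_domain_error")
  expect_error(duration_interval(0, 90), class = "emodyn_domain_error")
  expect_error(duration_interval(0.5, 100), class = "emodyn_domain_error")
})

test_that("profile durations evaluate the +/- 1 SD carryovers", {
  lam0 <- 0.86
  lamk <- c(valence = 0.05, arousal = 0.01, dominance = -0.16)
  sds <- c(valence = 1.5, arousal = 1.2, dominance = 0.3)
  prof <- duration_profiles(lam0, lamk, sds, p = 90)
  expect_equal(prof$lambda_high, unname(lam0 + lamk * sds), tolerance = 1e-12)
  expect_equal(prof$duration_high,
               log(0.1) / log(unname(lam0 + lamk * sds)) - 1, tolerance = 1e-12)
  expect_equal(prof$duration_low,
               log(0.1) / log(unname(lam0 - lamk * sds)) - 1, tolerance = 1e-12)
  # higher carryover slope on a dimension means longer high-profile duration
  expect_gt(prof$duration_high[1], prof$duration_low[1])
  expect_lt(prof$duration_high[3], prof$duration_low[3])
})

test_that("shock vectors equal the conditional-normal expectation", {
  sig <- matrix(c(4, 2, 2, 3), 2)
  expect_equal(unname(shock_vector(sig, 1, 1)), c(1, 0.5))
  # diagonal covariance: no co-movement
  expect_equal(unname(shock_vector(diag(c(2, 5, 1)), 2, 0.3)), c(0, 0.3, 0))
  # homogeneity in delta
  set.seed(55)
  s <- crossprod(matrix(rnorm(16), 4))
  expect_equal(shock_vector(s, 3, 2 * 0.7), 2 * shock_vector(s, 3, 0.7))
  expect_error(shock_vector(diag(c(1, 0)), 2, 1), class = "emodyn_domain_error")

  # Monte-Carlo oracle: regression slope of eps_j on eps_i
  set.seed(56)
  draws <- MASS::mvrnorm(40000, mu = c(0, 0), Sigma = sig)
  fitl <- lm(draws[, 2] ~ draws[, 1])
  slope <- coef(fitl)[2]
  se <- summary(fitl)$coefficients[2, 2]
  expect_lt(abs(shock_vector(sig, 1, 1)[2] - slope), 3 * se)
})

test_that("IRFs match the shocked-minus-unshocked simulation oracle", {
  co0 <- var_coefficients(c(0.1, 0.2), matrix(0, 2, 2))
  irf0 <- compute_irf(co0, c(1, 0.5), horizon = 10)
  expect_true(all(irf0$responses[2:10, ] == 0))

  co <- var_coefficients(c(0.1, 0.1), matrix(c(0.5, 0, 0.2, 0.4), 2, byrow = TRUE))
  irf <- compute_irf(co, c(1, 0.5), horizon = 30)
  expect_equal(unname(irf$responses[2, ]), c(0.5, 0.4))
  expect_equal(unname(irf$responses[3, ]), c(0.25, 0.26))
  expect_equal(unname(irf$ce), c(1, 0.5))

  set.seed(61)
  for (r in 1:10) {
    n <- sample(2:6, 1)
    co <- random_stationary_coeffs(n)
    shock <- rnorm(n, 0, 0.1)
    h <- sample(10:60, 1)
    irf <- compute_irf(co, shock, horizon = h)
    # oracle: difference of deterministic shocked and unshocked paths
    X <- matrix(rbinom(h, 1, 0.5), h, 1)
    e0 <- solve(diag(n) - co$gamma, co$alpha)
    shocked <- rbind((e0 + shock), matrix(0, h - 1, n))
    for (t in 2:h) {
      shocked[t, ] <- co$alpha + drop(co$gamma %*% shocked[t - 1, ]) +
        drop(co$beta %*% X[t, ])
    }
    base2 <- rbind(e0, matrix(0, h - 1, n))
    for (t in 2:h) {
      base2[t, ] <- co$alpha + drop(co$gamma %*% base2[t - 1, ]) +
        drop(co$beta %*% X[t, ])
    }
    expect_lt(max(abs((shocked - base2) - irf$responses)), 1e-10)
  }
})

test_that("cumulative responses sum the stated day window", {
  co <- var_coefficients(c(0.1, 0.1), matrix(c(0.5, 0, 0.2, 0.4), 2, byrow = TRUE))
  irf <- compute_irf(co, c(1, 0.5), horizon = 35)
  expect_equal(cumulative_irf(irf, 1, 1), irf$responses[2, ])
  expect_equal(unname(cumulative_irf(irf)),
               unname(colSums(irf$responses[2:30, ])))
  expect_equal(unname(irf$cirf), unname(colSums(irf$responses[2:30, ])))
  expect_error(cumulative_irf(compute_irf(co, c(1, 0), horizon = 10)))

  # scalar system: infinite-horizon cumulative response is the geometric
  # series lambda / (1 - lambda), the duration formula's total effect
  lam <- 0.6
  co1 <- var_coefficients(0.1, matrix(lam, 1, 1))
  irf1 <- compute_irf(co1, 1, horizon = 400)
  expect_equal(sum(irf1$responses[-1, ]), lam / (1 - lam), tolerance = 1e-8)

  # zero-persistence system has zero CIRF
  expect_true(all(compute_irf(var_coefficients(c(0, 0), matrix(0, 2, 2)),
                              c(1, 1), horizon = 30)$cirf == 0))
})

test_that("the all-shock sweep has the right shape, scale and symmetry", {
  sim <- make_sim(seed = 71, n_emotions = 6, n_days = 300)
  fit <- fit_emotion_var(sim$panel, sim$dims)
  sh <- run_all_shocks(fit, horizon = 30)
  n <- 6
  expect_equal(dim(sh$ce), c(n, n))
  expect_equal(dim(sh$cirf), c(n, n))
  expect_length(sh$irfs, n)
  expect_equal(unname(diag(sh$ce)), unname(sh$delta))
  eff <- tidy(sh)
  expect_equal(sum(eff$source != eff$destination), n * (n - 1))

  # doubling the shock fraction doubles every effect
  sh2 <- run_all_shocks(fit, shock_fraction = 0.20, horizon = 30)
  expect_equal(sh2$ce, 2 * sh$ce, tolerance = 1e-12)
  expect_equal(sh2$cirf, 2 * sh$cirf, tolerance = 1e-12)

  # symmetric sigma and gamma with equal deltas give a symmetric CE matrix
  g <- matrix(0.02, 4, 4); diag(g) <- 0.5
  s <- matrix(0.3, 4, 4); diag(s) <- 1
  co <- var_coefficients(rep(0.1, 4), g, sigma = s * 1e-4)
  sh3 <- run_all_shocks(co, horizon = 30)
  expect_equal(sh3$ce, t(sh3$ce), tolerance = 1e-10)
})

test_that("distance regressions recover exact and noisy planted coefficients", {
  sim <- make_sim(seed = 81, n_emotions = 8, n_days = 50)
  dimsc <- center_scores(sim$dims)
  dist <- asymmetric_distances(dimsc)
  wide <- tidyr::pivot_wider(dist, names_from = "dimension",
                             values_from = c("dist_up", "dist_down"))
  wide <- dplyr::filter(wide, source != destination)
  truth_b <- c(0.013, -0.003, -0.0025, -0.002, -0.001, -0.0012, -0.0059)
  xmat <- as.matrix(wide[c("dist_up_dim_1", "dist_up_dim_2", "dist_up_dim_3",
                           "dist_down_dim_1", "dist_down_dim_2", "dist_down_dim_3")])
  sdest <- dimsc$dict_size[match(wide$destination, dimsc$emotion)]
  eff <- tibble::tibble(
    source = wide$source, destination = wide$destination,
    cirf = truth_b[1] + drop(xmat %*% truth_b[-1]) + 2e-5 * sdest
  )
  reg <- distance_regression(eff, dist, sim$dims, effect = "cirf")
  est <- suppressWarnings(tidy(reg))   # lm flags the (intentional) perfect fit
  expect_lt(max(abs(est$estimate -
                      c(truth_b, 2e-5)[match(est$term,
                        c("(Intercept)", "dist_up_dim_1", "dist_up_dim_2",
                          "dist_up_dim_3", "dist_down_dim_1", "dist_down_dim_2",
                          "dist_down_dim_3", "dict_size_dest"))])), 1e-10)

  # permutation invariance
  eff_perm <- eff[sample(nrow(eff)), ]
  reg2 <- distance_regression(eff_perm, dist, sim$dims, effect = "cirf")
  expect_equal(suppressWarnings(tidy(reg2))$estimate, est$estimate,
               tolerance = 1e-10)

  # unbiasedness under i.i.d. noise
  set.seed(82)
  slopes <- replicate(50, {
    eff_n <- eff
    eff_n$cirf <- eff_n$cirf + rnorm(nrow(eff_n), 0, 0.005)
    r <- distance_regression(eff_n, dist, sim$dims, effect = "cirf")
    tidy(r)$estimate[tidy(r)$term == "dist_up_dim_1"]
  })
  expect_lt(abs(mean(slopes) - truth_b[2]), 3 * sd(slopes) / sqrt(50))
})

test_that("estimated CIRF distance patterns track the truth-implied ones", {
  # qualitative sign recovery of the distance-regression slopes across
  # replicated end-to-end runs
  match_frac <- vapply(1:10, function(r) {
    sim <- make_sim(seed = 700 + r, n_emotions = 12, n_days = 790)
    fit <- fit_emotion_var(sim$panel, sim$dims)
    xb <- fit$xbar
    truth_shocks <- run_all_shocks(sim$truth$coeffs, xbar = xb, horizon = 30)
    est_shocks <- run_all_shocks(fit, horizon = 30)
    dist <- fit$dist
    t_reg <- tidy(distance_regression(tidy(truth_shocks), dist, sim$dims))
    e_reg <- tidy(distance_regression(tidy(est_shocks), dist, sim$dims))
    slope_terms <- grep("^dist_", t_reg$term, value = TRUE)
    keep <- slope_terms[abs(t_reg$statistic[match(slope_terms, t_reg$term)]) > 2]
    if (length(keep) == 0) return(1)
    mean(sign(t_reg$estimate[match(keep, t_reg$term)]) ==
           sign(e_reg$estimate[match(keep, e_reg$term)]))
  }, numeric(1))
  expect_gte(mean(match_frac >= 0.8), 0.9)
})
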