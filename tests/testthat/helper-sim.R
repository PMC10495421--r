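# Shared fixtures, built in code.

# Small end-to-end simulation: scores, structural truth, panel.
make_sim <- function(seed, n_emotions = 8, n_days = 400, n_exog = 2,
                     noise_scale = 0.004, sigma_zero = FALSE, ...) {
  cfg <- sim_config(n_emotions = n_emotions, n_days = n_days,
                    n_exog = n_exog,
                    exog_break_fractions = if (n_exog == 2) c(0.75, 0.87)
                                           else seq(0.5, 0.9, length.out = max(n_exog, 1))[seq_len(n_exog)],
                    seed = seed, noise_scale = noise_scale, ...)
  dims <- sim_dimension_scores(cfg)
  truth <- sim_structured_params(dims, cfg)
  if (sigma_zero) truth$coeffs$sigma[] <- 0
  panel <- simulate_panel(truth$coeffs, cfg)
  list(cfg = cfg, dims = dims, truth = truth, panel = panel)
}

# Rebuild VAR coefficients from a (possibly modified) shared-parameter
# list, keeping expansion exactly consistent with the estimation path.
expand_truth <- function(shared_list, dims, beta, sigma) {
  dimsc <- center_scores(dims)
  dn <- emodyn:::dim_names(dimsc)
  da <- emodyn:::dist_arrays(asymmetric_distances(dimsc), dimsc$emotion, dn)
  ex <- emodyn:::expand_shared(shared_list, as.matrix(dimsc[dn]),
                               dimsc$dict_size, da$up, da$down)
  var_coefficients(stats::setNames(ex$alpha, dims$emotion), ex$gamma, beta, sigma)
}

# Deterministic VARX(1) recursion, written independently of the package
# simulator, for use as an oracle.
iterate_var <- function(alpha, gamma, beta, X, e0, n_steps) {
  out <- matrix(0, n_steps, length(alpha))
  prev <- e0
  for (t in seq_len(n_steps)) {
    xt <- if (ncol(beta) > 0) drop(beta %*% X[t, ]) else 0
    prev <- alpha + drop(gamma %*% prev) + xt
    out[t, ] <- prev
  }
  out
}

# Random stationary VAR coefficient sets for IRF oracle checks.
random_stationary_coeffs <- function(n, radius_max = 0.95) {
  g <- matrix(rnorm(n * n, 0, 0.4), n, n)
  rho <- max(Mod(eigen(g, only.values = TRUE)$values))
  g <- g * runif(1, 0.2, radius_max) / rho
  s <- crossprod(matrix(rnorm(n * n), n))
  var_coefficients(rnorm(n, 0.05, 0.02), g,
                   matrix(rnorm(n, 0, 0.01), n, 1), s / max(diag(s)) * 1e-4)
}

# Orthogonal Procrustes alignment of an estimated loading matrix onto a
# target, followed by per-column Tucker congruence.
congruence_after_procrustes <- function(est, target) {
  sv <- svd(t(est) %*% target)
  aligned <- est %*% sv$u %*% t(sv$v)
  vapply(seq_len(ncol(target)), function(j) {
    sum(aligned[, j] * target[, j]) /
      sqrt(sum(aligned[, j]^2) * sum(target[, j]^2))
  }, numeric(1))
}

# Simulate an unrestricted VAR(2) panel (for lag-selection power checks).
sim_var2_panel <- function(seed, n = 4, tt = 500, a1 = 0.3, a2 = 0.45) {
  set.seed(seed)
  g1 <- diag(a1, n)
  g2 <- diag(a2, n)
  E <- matrix(0, tt + 100, n)
  for (t in 3:(tt + 100)) {
    E[t, ] <- g1 %*% E[t - 1, ] + g2 %*% E[t - 2, ] + rnorm(n, 0, 0.01)
  }
  E <- E[101:(tt + 100), ] + 0.05
  colnames(E) <- paste0("emotion_", seq_len(n))
  out <- tibble::as_tibble(E)
  out$date <- as.Date("2020-01-01") + seq_len(tt) - 1
  dplyr::relocate(out, "date")
}
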