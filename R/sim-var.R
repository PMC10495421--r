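# Structural truth generator and VARX(1) panel simulator.

# Expand shared structural parameters into the full intercept vector and
# autoregressive matrix.  `shared` is a named list/vector with elements
# mu_0, mu[K], mu_S, lambda_0, lambda[K], lambda_S, tau_0, tau_up[K],
# tau_down[K], tau_S.  DIM is the centered N x K score matrix, S the
# centered dictionary sizes, up/down the N x N x K distance arrays.
expand_shared <- function(shared, DIM, S, up, down) {
  n <- nrow(DIM)
  k <- ncol(DIM)
  alpha <- shared$mu_0 + drop(DIM %*% shared$mu) + shared$mu_S * S
  gamma <- matrix(shared$tau_0, n, n)
  for (kk in seq_len(k)) {
    gamma <- gamma + shared$tau_up[kk] * up[, , kk] + shared$tau_down[kk] * down[, , kk]
  }
  gamma <- gamma + matrix(shared$tau_S * S, n, n)  # destination's size, constant in j
  diag(gamma) <- shared$lambda_0 + drop(DIM %*% shared$lambda) + shared$lambda_S * S
  list(alpha = alpha, gamma = gamma)
}

shared_as_vector <- function(shared, dnames) {
  c(setNames(shared$mu_0, "mu_0"),
    setNames(shared$mu, paste0("mu_", dnames)),
    setNames(shared$mu_S, "mu_dict_size"),
    setNames(shared$lambda_0, "lambda_0"),
    setNames(shared$lambda, paste0("lambda_", dnames)),
    setNames(shared$lambda_S, "lambda_dict_size"),
    setNames(shared$tau_0, "tau_0"),
    setNames(shared$tau_up, paste0("tau_up_", dnames)),
    setNames(shared$tau_down, paste0("tau_down_", dnames)),
    setNames(shared$tau_S, "tau_dict_size"))
}

#' Draw structural truth parameters and expand them to VAR matrices
#'
#' Draws the shared coefficients that tie the VAR's intercepts, carryover
#' and cross-lagged transitions to the appraisal dimensions (baseline
#' carryover near 0.85, small cross-emotion suppression, magnitudes on the
#' relative-frequency scale of daily panels), expands them through the
#' structural equations into `(alpha, gamma, beta)`, rescales all
#' carryover/transition coefficients uniformly so the spectral radius of
#' `gamma` does not exceed `config$target_spectral_radius`, and draws a
#' full innovation covariance with off-diagonal structure.  The returned
#' truth is re-derived after rescaling so that expanding it reproduces the
#' simulated `gamma` exactly.
#'
#' @param dims Dimension-score tibble (centered or raw).
#' @param config A [sim_config()]; `n_dims` must match `dims`.
#' @return A list with `truth` (shared parameters: named vector `shared`,
#'   `beta` matrix, plus bookkeeping) and `coeffs`, a `var_coefficients`
#'   object (`alpha`, `gamma`, `beta`, `sigma`).
#' @export
sim_structured_params <- function(dims, config) {
  stopifnot(inherits(config, "sim_config"))
  check_dims(dims)
  dn <- dim_names(dims)
  k <- length(dn)
  if (k != config$n_dims) abort("dims has a different K than config$n_dims",
                                class = "emodyn_generation_error")
  n <- nrow(dims)
  m <- config$n_exog
  dimsc <- ensure_centered(dims)
  DIM <- as.matrix(dimsc[dn])
  S <- dimsc$dict_size

  set.seed(config$seed + 202L)
  shared <- list(
    mu_0 = rnorm(1, 0.02, 0.004),
    mu = rnorm(k, 0, 0.003),
    mu_S = rnorm(1, 0, 2e-5),
    lambda_0 = rnorm(1, 0.85, 0.03),
    lambda = rnorm(k, 0, 0.06),
    lambda_S = rnorm(1, 0, 5e-5),
    tau_0 = rnorm(1, -0.011, 0.003),
    tau_up = rnorm(k, 0, 0.002),
    tau_down = rnorm(k, 0, 0.002),
    tau_S = rnorm(1, 0, 5e-6)
  )
  beta <- matrix(rnorm(n * m, 0, 0.002), n, m)

  da <- dist_arrays(asymmetric_distances(dimsc), dimsc$emotion, dn)
  ex <- expand_shared(shared, DIM, S, da$up, da$down)
  rho <- spectral_radius(ex$gamma)
  if (!is.finite(rho)) abort("expansion produced a non-finite matrix",
                             class = "emodyn_generation_error")
  if (rho > config$target_spectral_radius) {
    c_scale <- config$target_spectral_radius / rho
    for (nm in c("lambda_0", "lambda", "lambda_S", "tau_0", "tau_up", "tau_down", "tau_S")) {
      shared[[nm]] <- shared[[nm]] * c_scale
    }
    ex <- expand_shared(shared, DIM, S, da$up, da$down)
  }
  if (spectral_radius(ex$gamma) > config$target_spectral_radius + 1e-8) {
    abort("failed to rescale the system to the target spectral radius",
          class = "emodyn_generation_error")
  }

  # full innovation covariance: two-factor correlation structure scaled to
  # per-emotion standard deviations around noise_scale
  f <- matrix(rnorm(n * 2, 0, 0.6), n, 2)
  r0 <- tcrossprod(f) + diag(runif(n, 0.5, 1.5))
  corr <- stats::cov2cor(r0)
  sds <- config$noise_scale * exp(rnorm(n, 0, 0.2))
  sigma <- diag(sds) %*% corr %*% diag(sds)
  sigma <- (sigma + t(sigma)) / 2
  dimnames(sigma) <- list(dimsc$emotion, dimsc$emotion)

  exog_names <- if (m > 0) paste0("X_", seq_len(m)) else character(0)
  dimnames(beta) <- list(dimsc$emotion, exog_names)
  names(ex$alpha) <- dimsc$emotion
  dimnames(ex$gamma) <- list(dimsc$emotion, dimsc$emotion)

  truth <- list(
    shared = shared_as_vector(shared, dn),
    shared_list = shared,
    beta = beta,
    emotions = dimsc$emotion,
    dim_names = dn
  )
  coeffs <- var_coefficients(ex$alpha, ex$gamma, beta, sigma)
  list(truth = truth, coeffs = coeffs)
}

#' Construct a VAR coefficient set
#'
#' @param alpha Intercept vector (length N).
#' @param gamma N x N autoregressive matrix.
#' @param beta N x M exogenous coefficient matrix (M may be 0).
#' @param sigma N x N innovation covariance (symmetric PSD).
#' @return A `var_coefficients` object.
#' @export
var_coefficients <- function(alpha, gamma, beta = NULL, sigma = NULL) {
  n <- length(alpha)
  stopifnot(is.matrix(gamma), nrow(gamma) == n, ncol(gamma) == n)
  if (is.null(beta)) beta <- matrix(0, n, 0)
  if (is.null(sigma)) sigma <- matrix(0, n, n)
  check_psd(sigma, "sigma")
  structure(list(alpha = alpha, gamma = gamma, beta = beta, sigma = sigma),
            class = "var_coefficients")
}

#' Simulate a daily emotion-frequency panel from a VARX(1)
#'
#' Iterates `E_t = alpha + gamma %*% E_{t-1} + beta %*% X_t + eps_t` with
#' jointly normal innovations `eps_t ~ N(0, sigma)`, starting at the
#' deterministic fixed point `(I - gamma)^{-1} alpha` (or `init`),
#' discarding `config$burn_in` steps, and switching each exogenous step
#' dummy on permanently at its configured break fraction of the sample.
#' Values are left on the unconstrained scale by default; with
#' `clip = TRUE` they are clipped to [0, 1] and the clip rate reported.
#'
#' @param coeffs A [var_coefficients()] with spectral radius below 1.
#' @param config A [sim_config()].
#' @param init Optional starting state (length N); defaults to the fixed
#'   point.
#' @param clip Clip frequencies to the unit interval (default `FALSE`).
#' @param start_date First date of the panel.
#' @return A tibble with `date`, one column per emotion, and step-dummy
#'   columns `X_1`, ..., `X_M`.
#' @export
simulate_panel <- function(coeffs, config, init = NULL, clip = FALSE,
                           start_date = as.Date("2016-06-15")) {
  stopifnot(inherits(coeffs, "var_coefficients"), inherits(config, "sim_config"))
  n <- length(coeffs$alpha)
  if (n != config$n_emotions) abort("coeffs and config disagree on the number of emotions")
  rho <- spectral_radius(coeffs$gamma)
  if (rho >= 1) {
    abort(sprintf("gamma is not stationary (spectral radius %.3f >= 1); refusing to simulate", rho),
          class = "emodyn_simulation_error")
  }
  check_psd(coeffs$sigma, "sigma")
  tt <- config$n_days
  burn <- config$burn_in
  m <- ncol(coeffs$beta)

  X <- matrix(0L, tt, m)
  if (m > 0) {
    breaks <- floor(config$exog_break_fractions * tt)
    for (j in seq_len(m)) X[(breaks[j] + 1):tt, j] <- 1L
  }

  set.seed(config$seed + 303L)
  total <- burn + tt
  if (all(coeffs$sigma == 0)) {
    eps <- matrix(0, total, n)
  } else {
    eps <- MASS::mvrnorm(total, mu = rep(0, n), Sigma = coeffs$sigma)
  }

  e0 <- if (is.null(init)) solve(diag(n) - coeffs$gamma, coeffs$alpha) else as.numeric(init)
  E <- matrix(0, total, n)
  prev <- e0
  for (t in seq_len(total)) {
    xt <- if (t > burn && m > 0) X[t - burn, ] else rep(0, m)
    prev <- coeffs$alpha + drop(coeffs$gamma %*% prev) +
      (if (m > 0) drop(coeffs$beta %*% xt) else 0) + eps[t, ]
    E[t, ] <- prev
  }
  E <- E[(burn + 1):total, , drop = FALSE]
  if (clip) {
    n_clip <- sum(E < 0 | E > 1)
    if (n_clip > 0) {
      inform(sprintf("clipped %d of %d values (%.2f%%) to [0, 1]",
                     n_clip, length(E), 100 * n_clip / length(E)))
    }
    E <- pmin(pmax(E, 0), 1)
  }
  emo <- names(coeffs$alpha) %||% sprintf("emotion_%02d", seq_len(n))
  colnames(E) <- emo
  out <- tibble::as_tibble(E)
  out$date <- start_date + seq_len(tt) - 1
  if (m > 0) {
    colnames(X) <- paste0("X_", seq_len(m))
    out <- dplyr::bind_cols(out, tibble::as_tibble(X))
  }
  dplyr::relocate(out, "date")
}
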