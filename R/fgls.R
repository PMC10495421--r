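# Feasible generalized least squares on the stacked restricted design,
# coefficient expansion back to full VAR matrices, and the user-facing
# fitting wrapper.

#' Estimate the structured VAR by feasible generalized least squares
#'
#' Two-step FGLS on the stacked design: (1) pooled OLS across all
#' destination equations; (2) cross-equation residual covariance
#' estimated from the OLS residuals (denominator T-1, the observations
#' per equation after lagging); (3) GLS reweighting with
#' `solve(sigma_hat) %x% I`.  Standard errors come from the GLS
#' covariance.  With `sigma` supplied the given covariance is used
#' directly (plain GLS); with `iterate = TRUE` steps 2-3 are repeated to
#' convergence.  A numerically perfect first-stage fit (noiseless data)
#' short-circuits to the exact OLS solution with a zero covariance.
#'
#' @param design An `evar_design` from [build_design()].
#' @param sigma Optional known innovation covariance (N x N).
#' @param iterate Iterate covariance estimation and GLS to convergence.
#' @param max_iter,tol Iteration controls.
#' @return An `evar_params` object: shared estimates with standard
#'   errors and joint covariance, free exogenous coefficients, the
#'   residual covariance `sigma_hat`, residuals and fit metadata.
#' @export
estimate_fgls <- function(design, sigma = NULL, iterate = FALSE,
                          max_iter = 25, tol = 1e-10) {
  stopifnot(inherits(design, "evar_design"))
  Y <- design$Y
  Xarr <- design$X
  tt1 <- nrow(Y)
  n <- ncol(Y)
  p <- dim(Xarr)[2]
  if (tt1 * n <= p) abort("not enough observations for the design size")

  Xstack <- stack_equations(Xarr)
  y <- as.vector(Y)
  qrX <- qr(Xstack)
  if (qrX$rank < p) {
    bad <- design$terms[qrX$pivot[(qrX$rank + 1):p]]
    abort(sprintf("design is rank deficient; collinear columns: %s",
                  paste(bad, collapse = ", ")),
          class = "emodyn_estimation_error")
  }
  theta <- qr.coef(qrX, y)
  res <- Y - fitted_matrix(Xarr, theta)

  sig_given <- !is.null(sigma)
  sig <- if (sig_given) sigma else crossprod(res) / tt1

  # noiseless data: OLS already interpolates exactly, and the residual
  # covariance is numerically zero; return the exact solution
  if (!sig_given && max(abs(res)) < 1e-9) {
    return(new_evar_params(theta, matrix(0, p, p), sig, res, design,
                           method = "ols-exact"))
  }
  check_sigma_ok(sig, res)

  for (it in seq_len(if (iterate && !sig_given) max_iter else 1L)) {
    U <- whitening_matrix(sig)
    Yt <- Y %*% t(U)
    Xt <- Xarr
    dim(Xt) <- c(tt1 * p, n)
    Xt <- Xt %*% t(U)
    dim(Xt) <- c(tt1, p, n)
    Xts <- stack_equations(Xt)
    xtwx <- crossprod(Xts)
    theta_new <- drop(chol2inv(chol(xtwx)) %*% crossprod(Xts, as.vector(Yt)))
    names(theta_new) <- design$terms
    conv <- max(abs(theta_new - theta))
    theta <- theta_new
    res <- Y - fitted_matrix(Xarr, theta)
    if (!iterate || sig_given || conv < tol) break
    sig <- crossprod(res) / tt1
    check_sigma_ok(sig, res)
  }
  vc <- chol2inv(chol(xtwx))
  dimnames(vc) <- list(design$terms, design$terms)
  new_evar_params(theta, vc, sig, res, design,
                  method = if (sig_given) "gls" else "fgls")
}

stack_equations <- function(Xarr) {
  d <- dim(Xarr)
  out <- aperm(Xarr, c(1, 3, 2))
  dim(out) <- c(d[1] * d[3], d[2])
  out
}

fitted_matrix <- function(Xarr, theta) {
  d <- dim(Xarr)
  fit <- matrix(0, d[1], d[3])
  for (i in seq_len(d[3])) fit[, i] <- Xarr[, , i] %*% theta
  fit
}

whitening_matrix <- function(sig) {
  Rc <- chol(sig)            # sig = Rc' Rc
  t(solve(Rc))               # U with U'U = solve(sig)
}

check_sigma_ok <- function(sig, res) {
  ev <- eigen((sig + t(sig)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    abort(paste("estimated residual covariance is singular;",
                "more days or fewer emotions are needed"),
          class = "emodyn_estimation_error")
  }
  invisible(sig)
}

new_evar_params <- function(theta, vcov, sigma_hat, residuals, design, method) {
  names(theta) <- design$terms
  se <- sqrt(pmax(diag(vcov), 0))
  names(se) <- design$terms
  ps <- design$p_shared
  m <- design$m
  n <- length(design$emotions)
  beta <- matrix(0, n, m, dimnames = list(design$emotions, design$exog_names))
  if (m > 0) {
    beta[] <- matrix(theta[(ps + 1):length(theta)], n, m, byrow = TRUE)
  }
  dimnames(sigma_hat) <- list(design$emotions, design$emotions)
  colnames(residuals) <- design$emotions
  structure(list(
    estimates = theta, se = se, vcov = vcov,
    shared = theta[seq_len(ps)], shared_se = se[seq_len(ps)],
    shared_vcov = vcov[seq_len(ps), seq_len(ps), drop = FALSE],
    beta = beta, sigma_hat = sigma_hat, residuals = residuals,
    terms = design$terms, p_shared = ps,
    emotions = design$emotions, dim_names = design$dim_names,
    k = design$k, m = m, n_obs = nrow(design$Y),
    dims = design$dims, dist = design$dist, xbar = design$xbar,
    method = method
  ), class = "evar_params")
}

#' @export
print.evar_params <- function(x, ...) {
  cat(sprintf("<evar_params> %s fit: %d emotions, %d days used, K = %d\n",
              x$method, length(x$emotions), x$n_obs, x$k))
  print(tidy(x), n = x$p_shared)
  invisible(x)
}

#' Tidy the shared structural coefficients
#'
#' @param x An `evar_params` or `evar_fit` object.
#' @param all Include the free per-equation exogenous coefficients.
#' @param ... Unused.
#' @return A tibble with `term`, `block`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy evar_params
#' @export
tidy.evar_params <- function(x, all = FALSE, ...) {
  idx <- if (all) seq_along(x$estimates) else seq_len(x$p_shared)
  est <- x$estimates[idx]
  se <- x$se[idx]
  z <- ifelse(se > 0, est / se, NA_real_)
  block <- dplyr::case_when(
    startsWith(names(est), "mu") ~ "base_level",
    startsWith(names(est), "lambda") ~ "carryover",
    startsWith(names(est), "tau") ~ "transition",
    TRUE ~ "exogenous"
  )
  tibble::tibble(
    term = names(est), block = block, estimate = unname(est),
    std.error = unname(se), statistic = unname(z),
    p.value = 2 * stats::pnorm(-abs(z))
  )
}

#' @method glance evar_params
#' @export
glance.evar_params <- function(x, ...) {
  tibble::tibble(
    n_emotions = length(x$emotions), n_obs = x$n_obs, k = x$k,
    n_shared = x$p_shared, n_free = length(x$estimates) - x$p_shared,
    method = x$method,
    sigma_logdet = determinant(x$sigma_hat, logarithm = TRUE)$modulus[[1]]
  )
}

#' Expand shared structural estimates to full VAR coefficient matrices
#'
#' Reconstructs the intercepts from the base-level equation, the diagonal
#' of the autoregressive matrix from the carryover equation, and the
#' off-diagonals from the transition equation with asymmetric distances;
#' the free exogenous coefficients and innovation covariance are copied
#' through.
#'
#' @param params An `evar_params` (or `evar_fit`).
#' @param dims Centered dimension scores (defaults to those stored in
#'   `params`).
#' @param dist Distance table (defaults to the stored one).
#' @return A [var_coefficients()] object.
#' @export
expand_coefficients <- function(params, dims = NULL, dist = NULL) {
  if (inherits(params, "evar_fit")) params <- params$params
  stopifnot(inherits(params, "evar_params"))
  dims <- dims %||% params$dims
  dist <- dist %||% params$dist
  dimsc <- ensure_centered(dims)
  dn <- dim_names(dimsc)
  dimsc <- dimsc[match(params$emotions, dimsc$emotion), ]
  da <- dist_arrays(dist, params$emotions, dn)
  sh <- params$shared
  shared <- list(
    mu_0 = sh[["mu_0"]], mu = unname(sh[paste0("mu_", dn)]),
    mu_S = sh[["mu_dict_size"]],
    lambda_0 = sh[["lambda_0"]], lambda = unname(sh[paste0("lambda_", dn)]),
    lambda_S = sh[["lambda_dict_size"]],
    tau_0 = sh[["tau_0"]], tau_up = unname(sh[paste0("tau_up_", dn)]),
    tau_down = unname(sh[paste0("tau_down_", dn)]),
    tau_S = sh[["tau_dict_size"]]
  )
  ex <- expand_shared(shared, as.matrix(dimsc[dn]), dimsc$dict_size, da$up, da$down)
  names(ex$alpha) <- params$emotions
  dimnames(ex$gamma) <- list(params$emotions, params$emotions)
  var_coefficients(ex$alpha, ex$gamma, params$beta, params$sigma_hat)
}

#' Fit the appraisal-structured VAR to an emotion panel
#'
#' Convenience wrapper: centers the dimension scores, builds the
#' asymmetric distances and the stacked restricted design, estimates the
#' shared coefficients by FGLS, and expands them back to full VAR
#' matrices.
#'
#' @inheritParams build_design
#' @inheritParams estimate_fgls
#' @return An `evar_fit` object with elements `params` (see
#'   [estimate_fgls()]) and `coeffs` (see [var_coefficients()]); supports
#'   [tidy()], [glance()] and the dynamics functions.
#' @export
#' @examples
#' cfg <- sim_config(n_emotions = 5, n_days = 150, seed = 3,
#'                   n_exog = 1, exog_break_fractions = 0.8)
#' dims <- sim_dimension_scores(cfg)
#' tr <- sim_structured_params(dims, cfg)
#' panel <- simulate_panel(tr$coeffs, cfg)
#' fit <- fit_emotion_var(panel, dims)
#' tidy(fit)
fit_emotion_var <- function(panel, dims, dist = NULL, sigma = NULL,
                            iterate = FALSE) {
  design <- build_design(panel, dims, dist)
  params <- estimate_fgls(design, sigma = sigma, iterate = iterate)
  coeffs <- expand_coefficients(params)
  structure(list(params = params, coeffs = coeffs,
                 emotions = params$emotions, dims = params$dims,
                 dist = params$dist, xbar = params$xbar),
            class = "evar_fit")
}

#' @export
print.evar_fit <- function(x, ...) {
  print(x$params)
  invisible(x)
}

#' @method tidy evar_fit
#' @export
tidy.evar_fit <- function(x, ...) tidy(x$params, ...)

#' @method glance evar_fit
#' @export
glance.evar_fit <- function(x, ...) glance(x$params, ...)
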