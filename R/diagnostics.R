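# Pre-estimation diagnostics: unit-root tests, lag-order selection,
# Granger causality, and the symmetry Wald test on transition slopes.

#' Augmented Dickey-Fuller unit-root test
#'
#' ADF regression with a constant: `diff(y)_t` on `[1, y_{t-1},
#' diff(y)_{t-1..p}]`, the augmentation order chosen by information
#' criterion over a common sample (maximum lag by Schwert's rule).  BIC
#' is the default selector: its parsimony preserves power against highly
#' persistent alternatives, where AIC's tendency to over-augment costs
#' rejections.  The 5% critical value uses the MacKinnon (2010) response
#' surface for the constant-only case; the unit root is rejected when
#' the test statistic falls below it.
#'
#' @param series Numeric series, length at least 25.
#' @param max_lag Maximum augmentation lag (default Schwert's rule).
#' @param ic `"bic"` (default) or `"aic"` for augmentation-order
#'   selection.
#' @return One-row tibble: `statistic`, `lag_order`, `critical_5pct`,
#'   `reject_unit_root`, `n`.
#' @export
adf_test <- function(series, max_lag = NULL, ic = c("bic", "aic")) {
  ic <- match.arg(ic)
  y <- as.numeric(series)
  tt <- length(y)
  if (tt < 25) abort("series must have at least 25 observations")
  if (sd(y) == 0) abort("constant series: unit-root test undefined",
                        class = "emodyn_diagnostic_error")
  if (is.null(max_lag)) max_lag <- floor(12 * (tt / 100)^0.25)
  max_lag <- min(max_lag, tt - 10)

  dy <- diff(y)
  # common estimation sample across candidate lags for IC comparability
  idx_common <- (max_lag + 1):length(dy)
  ics <- vapply(0:max_lag, function(p) {
    f <- adf_ols(y, dy, p, idx_common)
    n <- length(idx_common)
    pen <- if (ic == "aic") 2 else log(n)
    n * log(f$rss / n) + pen * f$df
  }, numeric(1))
  p_star <- (0:max_lag)[which.min(ics)]

  idx_full <- (p_star + 1):length(dy)
  f <- adf_ols(y, dy, p_star, idx_full)
  crit <- mackinnon_crit_5(f$n)
  tibble::tibble(statistic = f$tstat, lag_order = p_star,
                 critical_5pct = crit,
                 reject_unit_root = f$tstat < crit, n = f$n)
}

adf_ols <- function(y, dy, p, idx) {
  Z <- cbind(1, y[idx])
  if (p > 0) {
    lags <- sapply(seq_len(p), function(l) dy[idx - l])
    Z <- cbind(Z, lags)
  }
  yy <- dy[idx]
  xtx <- crossprod(Z)
  xtxinv <- chol2inv(chol(xtx))
  b <- drop(xtxinv %*% crossprod(Z, yy))
  r <- yy - Z %*% b
  rss <- sum(r^2)
  dfres <- length(yy) - ncol(Z)
  s2 <- rss / dfres
  tstat <- b[2] / sqrt(s2 * xtxinv[2, 2])
  list(tstat = unname(tstat), rss = rss, df = ncol(Z), n = length(yy))
}

# MacKinnon (2010) response-surface 5% critical value, constant, no trend.
mackinnon_crit_5 <- function(n) {
  -2.86154 - 2.8903 / n - 4.234 / n^2 - 40.04 / n^3
}

#' Select the VAR lag order by information criteria
#'
#' Fits unrestricted VAR(p) models for p = 1..`p_max` by equationwise OLS
#' over a common sample, reports multivariate AIC, BIC and HQC
#' (log-determinant of the residual covariance plus the usual penalties),
#' and selects the BIC minimizer.
#'
#' @param panel Emotion panel tibble; step dummies are included as
#'   exogenous regressors.
#' @param p_max Largest lag order considered.
#' @return List with `selected` (BIC argmin) and `criteria` (tibble with
#'   one row per candidate p).
#' @export
select_lag_order <- function(panel, p_max = 7) {
  check_panel(panel)
  if (p_max < 1) abort("p_max must be at least 1")
  E <- panel_matrix(panel)
  X <- panel_exog(panel)
  tt <- nrow(E)
  n <- ncol(E)
  if (tt - p_max <= n * p_max + ncol(X) + 1) {
    abort("not enough days for the requested maximum lag order")
  }
  idx <- (p_max + 1):tt
  n_eff <- length(idx)
  crit <- purrr::map_dfr(seq_len(p_max), function(p) {
    Z <- cbind(1, do.call(cbind, lapply(seq_len(p), function(l) E[idx - l, , drop = FALSE])))
    if (ncol(X) > 0) Z <- cbind(Z, X[idx, , drop = FALSE])
    B <- qr.coef(qr(Z), E[idx, , drop = FALSE])
    res <- E[idx, , drop = FALSE] - Z %*% B
    sig <- crossprod(res) / n_eff
    ld <- determinant(sig, logarithm = TRUE)$modulus[[1]]
    kpar <- n * ncol(Z)
    tibble::tibble(
      p = p,
      aic = ld + 2 * kpar / n_eff,
      bic = ld + log(n_eff) * kpar / n_eff,
      hqc = ld + 2 * log(log(n_eff)) * kpar / n_eff
    )
  })
  list(selected = crit$p[which.min(crit$bic)], criteria = crit)
}

#' Pairwise Granger causality tests from an unrestricted VAR(1)
#'
#' For each ordered pair (source j, destination i), Wald test of the
#' coefficient on `E_{j,t-1}` in the OLS equation for `E_it` of the
#' unrestricted VAR(1) (constant and step dummies included).  The
#' diagonal is reported as `NA` (own-lag carryover, not a cross effect).
#'
#' @param panel Emotion panel tibble.
#' @return Tibble with `source`, `destination`, `statistic`, `df`,
#'   `p.value` for every ordered pair.
#' @export
granger_tests <- function(panel) {
  check_panel(panel)
  E <- panel_matrix(panel)
  X <- panel_exog(panel)
  tt <- nrow(E)
  emo <- colnames(E)
  n <- ncol(E)
  Z <- cbind(1, E[1:(tt - 1), , drop = FALSE])
  if (ncol(X) > 0) Z <- cbind(Z, X[2:tt, , drop = FALSE])
  Y <- E[2:tt, , drop = FALSE]
  xtxinv <- chol2inv(chol(crossprod(Z)))
  B <- xtxinv %*% crossprod(Z, Y)
  res <- Y - Z %*% B
  dfres <- nrow(Y) - ncol(Z)
  out <- tidyr::expand_grid(source = emo, destination = emo)
  out$statistic <- NA_real_
  for (r in seq_len(nrow(out))) {
    j <- match(out$source[r], emo)
    i <- match(out$destination[r], emo)
    if (i == j) next
    s2 <- sum(res[, i]^2) / dfres
    w <- B[1 + j, i]^2 / (s2 * xtxinv[1 + j, 1 + j])
    out$statistic[r] <- w
  }
  out$df <- ifelse(is.na(out$statistic), NA_integer_, 1L)
  out$p.value <- pchisq(out$statistic, df = 1, lower.tail = FALSE)
  out
}

#' Wald test of up/down transition-slope symmetry on one dimension
#'
#' Tests whether the cross-lagged transition slope for moving up a
#' dimension equals the slope for moving down it (`tau_up_k = tau_down_k`)
#' using the joint GLS covariance of the shared estimates; chi-squared
#' with one degree of freedom.
#'
#' @param params An `evar_params` or `evar_fit` with a joint covariance.
#' @param dimension Dimension name (e.g. `"dim_1"` or `"valence"`).
#' @return One-row tibble: `dimension`, `statistic`, `df`, `p.value`.
#' @export
wald_symmetry <- function(params, dimension) {
  if (inherits(params, "evar_fit")) params <- params$params
  stopifnot(inherits(params, "evar_params"))
  up <- paste0("tau_up_", dimension)
  down <- paste0("tau_down_", dimension)
  if (!all(c(up, down) %in% names(params$shared))) {
    abort(sprintf("unknown dimension '%s'", dimension))
  }
  if (is.null(params$shared_vcov)) abort("fit carries no joint covariance")
  d <- params$shared[[up]] - params$shared[[down]]
  v <- params$shared_vcov[up, up] + params$shared_vcov[down, down] -
    2 * params$shared_vcov[up, down]
  if (v <= 0) {
    stat <- if (abs(d) < 1e-12) 0 else Inf
  } else {
    stat <- d^2 / v
  }
  tibble::tibble(dimension = dimension, statistic = stat, df = 1L,
                 p.value = pchisq(stat, 1, lower.tail = FALSE))
}
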