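# Duration intervals, covariance-implied shock vectors, impulse-response
# propagation, and the pair-level distance regressions for co-occurrence
# and long-term transition patterns.

#' P% duration interval of an emotion
#'
#' Number of periods before P% of the cumulative effect of a shock to a
#' series with carryover `lambda` has materialized:
#' `log(1 - P/100) / log(lambda) - 1` (real-valued days).  Strictly
#' increasing in both arguments on their domains.
#'
#' @param lambda Carryover coefficient(s), each in (0, 1). Vectorized.
#' @param p Percentage of the cumulative effect, in (0, 100).
#' @return Duration(s) in days.
#' @export
#' @examples
#' duration_interval(0.855983, 90)  # about 13.8 days
duration_interval <- function(lambda, p = 90) {
  if (any(!is.finite(lambda)) || any(lambda <= 0) || any(lambda >= 1)) {
    abort("lambda must lie strictly between 0 and 1", class = "emodyn_domain_error")
  }
  if (length(p) != 1 || !is.finite(p) || p <= 0 || p >= 100) {
    abort("p must lie strictly between 0 and 100", class = "emodyn_domain_error")
  }
  log(1 - p / 100) / log(lambda) - 1
}

#' Duration intervals for +/- 1 SD appraisal profiles
#'
#' For each dimension, evaluates the duration interval at the carryover
#' implied by an emotion one standard deviation above and below average
#' on that dimension: `lambda = lambda_0 +/- lambda_k * sd_k`.
#'
#' @param lambda0 Baseline carryover (average emotion).
#' @param lambda_dims Named vector of carryover slopes per dimension.
#' @param dim_sd Named vector of dimension-score standard deviations.
#' @param p Percentage for the duration interval.
#' @return Tibble with one row per dimension: the high/low carryover and
#'   the corresponding durations in days.
#' @export
duration_profiles <- function(lambda0, lambda_dims, dim_sd, p = 90) {
  dn <- names(lambda_dims)
  if (is.null(dn) || !all(dn %in% names(dim_sd))) {
    abort("lambda_dims and dim_sd must be named consistently")
  }
  hi <- lambda0 + lambda_dims * dim_sd[dn]
  lo <- lambda0 - lambda_dims * dim_sd[dn]
  tibble::tibble(
    dimension = dn,
    lambda_high = unname(hi), lambda_low = unname(lo),
    duration_high = duration_interval(unname(hi), p),
    duration_low = duration_interval(unname(lo), p)
  )
}

#' Duration table for a fitted structured VAR
#'
#' Per-emotion duration intervals from the diagonal carryover
#' coefficients, plus the +/- 1 SD profile rows per dimension from the
#' shared carryover equation (SD taken across the fitted emotions'
#' scores).
#'
#' @param fit An `evar_fit`.
#' @param p Percentage for the duration interval.
#' @return Tibble with columns `type` (`"emotion"` or `"profile"`),
#'   `label`, `lambda`, `duration_days` (profiles add high/low rows).
#' @export
duration_table <- function(fit, p = 90) {
  stopifnot(inherits(fit, "evar_fit"))
  lam <- diag(fit$coeffs$gamma)
  ok <- lam > 0 & lam < 1
  emo_tbl <- tibble::tibble(
    type = "emotion", label = fit$emotions, lambda = unname(lam),
    duration_days = ifelse(ok, log(1 - p / 100) / log(pmin(pmax(lam, 1e-12), 1 - 1e-12)) - 1, NA_real_)
  )
  sh <- fit$params$shared
  dn <- fit$params$dim_names
  sds <- vapply(dn, function(d) sd(fit$dims[[d]]), numeric(1))
  prof <- duration_profiles(sh[["lambda_0"]],
                            setNames(sh[paste0("lambda_", dn)], dn), sds, p)
  prof_tbl <- tibble::tibble(
    type = "profile",
    label = c(paste0(prof$dimension, "_plus_1sd"), paste0(prof$dimension, "_minus_1sd")),
    lambda = c(prof$lambda_high, prof$lambda_low),
    duration_days = c(prof$duration_high, prof$duration_low)
  )
  dplyr::bind_rows(emo_tbl, prof_tbl)
}

#' Covariance-implied shock vector
#'
#' Day-0 effect of a shock of `delta` units to the source emotion on all
#' emotions, from the innovation covariance under joint normality: the
#' source gets `delta`, every other emotion the conditional expectation
#' `delta * sigma_ij / sigma_ii`.
#'
#' @param sigma Innovation covariance (N x N, symmetric, positive source
#'   variance).
#' @param source Source emotion index or name.
#' @param delta Shock size in frequency units.
#' @return Named shock vector of length N.
#' @export
#' @examples
#' shock_vector(matrix(c(4, 2, 2, 3), 2), 1, 1)  # c(1, 0.5)
shock_vector <- function(sigma, source, delta) {
  n <- nrow(sigma)
  i <- if (is.character(source)) match(source, rownames(sigma)) else as.integer(source)
  if (is.na(i) || i < 1 || i > n) abort("unknown source emotion")
  if (sigma[i, i] <= 0) abort("source innovation variance must be positive",
                              class = "emodyn_domain_error")
  v <- delta * sigma[, i] / sigma[i, i]
  v[i] <- delta
  names(v) <- rownames(sigma)
  v
}

#' Impulse-response function of the fitted VAR
#'
#' Propagates a day-0 shock vector through the autoregressive matrix:
#' `response_0 = shock`, `response_t = gamma %*% response_{t-1}`.
#' Responses are incremental deviations from the baseline path, so the
#' intercepts and exogenous terms cancel.  When the horizon covers at
#' least 30 days the cumulative response over days 1-29 (the long-term
#' transition measure) is attached.
#'
#' @param coeffs A [var_coefficients()] (or `evar_fit`).
#' @param shock Day-0 shock vector (length N).
#' @param horizon Days traced, including day 0 (default 30).
#' @param source,delta Optional bookkeeping on the shock's origin.
#' @return An `emo_irf` object: `responses` (horizon x N), `ce` (day-0
#'   contemporaneous effects), `cirf` (days 1-29 sums, when available).
#' @export
compute_irf <- function(coeffs, shock, horizon = 30, source = NA, delta = NA) {
  if (inherits(coeffs, "evar_fit")) coeffs <- coeffs$coeffs
  stopifnot(inherits(coeffs, "var_coefficients"))
  if (horizon < 1) abort("horizon must be at least 1")
  n <- length(coeffs$alpha)
  stopifnot(length(shock) == n)
  resp <- matrix(0, horizon, n)
  resp[1, ] <- shock
  for (t in seq_len(horizon - 1)) resp[t + 1, ] <- coeffs$gamma %*% resp[t, ]
  emo <- names(coeffs$alpha) %||% colnames(coeffs$gamma) %||% paste0("e", seq_len(n))
  dimnames(resp) <- list(paste0("day_", seq_len(horizon) - 1), emo)
  cirf <- if (horizon >= 30) colSums(resp[2:30, , drop = FALSE]) else NULL
  structure(list(source = source, delta = delta, shock = setNames(as.numeric(shock), emo),
                 responses = resp, ce = setNames(as.numeric(shock), emo),
                 cirf = cirf, horizon = horizon),
            class = "emo_irf")
}

#' @method tidy emo_irf
#' @export
tidy.emo_irf <- function(x, ...) {
  out <- tibble::as_tibble(x$responses)
  out$day <- seq_len(x$horizon) - 1L
  tidyr::pivot_longer(out, -"day", names_to = "emotion", values_to = "response")
}

#' Cumulative impulse response over a day window
#'
#' @param irf An `emo_irf`.
#' @param t_start,t_end Inclusive day window (defaults 1-29, the
#'   long-term transition window).
#' @return Named per-emotion vector of summed responses.
#' @export
cumulative_irf <- function(irf, t_start = 1, t_end = 29) {
  stopifnot(inherits(irf, "emo_irf"))
  if (t_start < 0 || t_end < t_start) abort("invalid day window")
  if (irf$horizon <= t_end) {
    abort(sprintf("horizon %d too short for days %d..%d", irf$horizon, t_start, t_end))
  }
  colSums(irf$responses[(t_start + 1):(t_end + 1), , drop = FALSE])
}

#' Impulse responses for a shock to every source emotion
#'
#' Applies, one source at a time, a shock of 10% (by default) of the
#' emotion's model-implied stationary mean `(I - gamma)^{-1} (alpha +
#' beta %*% xbar)`, builds the covariance-implied shock vector, traces
#' the IRF, and collects the day-0 contemporaneous-effect (CE) and
#' cumulative day 1-29 (CIRF) matrices (rows = destination, columns =
#' source).
#'
#' @param x An `evar_fit` or [var_coefficients()].
#' @param shock_fraction Shock size as a fraction of the baseline.
#' @param delta_mode Baseline for the percentage shock:
#'   `"stationary-mean"` (model-implied) or `"sample-mean"` (requires
#'   `sample_means`).
#' @param horizon IRF horizon in days (>= 30 to populate CIRFs).
#' @param xbar Average exogenous regressor values entering the
#'   stationary mean (taken from the fit when available).
#' @param sample_means Per-emotion sample means, for
#'   `delta_mode = "sample-mean"`.
#' @return An `emo_irf_set`: list of `emo_irf`s plus `ce` and `cirf`
#'   matrices and the per-source shock sizes `delta`.
#' @export
run_all_shocks <- function(x, shock_fraction = 0.10,
                           delta_mode = c("stationary-mean", "sample-mean"),
                           horizon = 30, xbar = NULL, sample_means = NULL) {
  delta_mode <- match.arg(delta_mode)
  if (inherits(x, "evar_fit")) {
    xbar <- xbar %||% x$xbar
    coeffs <- x$coeffs
  } else {
    coeffs <- x
  }
  stopifnot(inherits(coeffs, "var_coefficients"))
  n <- length(coeffs$alpha)
  emo <- names(coeffs$alpha) %||% paste0("e", seq_len(n))
  base <- switch(delta_mode,
    "stationary-mean" = {
      drift <- coeffs$alpha
      if (ncol(coeffs$beta) > 0 && length(xbar) == ncol(coeffs$beta)) {
        drift <- drift + drop(coeffs$beta %*% xbar)
      }
      solve(diag(n) - coeffs$gamma, drift)
    },
    "sample-mean" = {
      if (is.null(sample_means)) abort("sample_means required for delta_mode = 'sample-mean'")
      sample_means
    })
  delta <- shock_fraction * as.numeric(base)
  irfs <- purrr::map(seq_len(n), function(i) {
    compute_irf(coeffs, shock_vector(coeffs$sigma, i, delta[i]),
                horizon = horizon, source = emo[i], delta = delta[i])
  })
  ce <- vapply(irfs, function(z) z$ce, numeric(n))
  dimnames(ce) <- list(emo, emo)                    # rows destination, cols source
  cirf <- if (horizon >= 30) {
    cm <- vapply(irfs, function(z) z$cirf, numeric(n))
    dimnames(cm) <- list(emo, emo)
    cm
  } else NULL
  structure(list(irfs = irfs, ce = ce, cirf = cirf,
                 delta = setNames(delta, emo), emotions = emo,
                 horizon = horizon),
            class = "emo_irf_set")
}

#' @method tidy emo_irf_set
#' @export
tidy.emo_irf_set <- function(x, ...) {
  out <- tidyr::expand_grid(destination = x$emotions, source = x$emotions)
  out$ce <- x$ce[cbind(out$destination, out$source)]
  if (!is.null(x$cirf)) out$cirf <- x$cirf[cbind(out$destination, out$source)]
  out$delta_source <- x$delta[out$source]
  out
}

#' Regress pair-level effects on asymmetric appraisal distances
#'
#' Ordinary least squares of an effect for each ordered emotion pair
#' (source j to destination i, diagonal excluded) on a constant, the
#' upward and downward distances on each dimension, and (optionally) the
#' destination's centered dictionary size.  Used for both the day-0
#' co-occurrence (CE) and the long-term transition (CIRF) analyses.
#'
#' @param effects Tibble with `source`, `destination` and the effect
#'   column named by `effect` (e.g. the output of [tidy()] on an
#'   `emo_irf_set`).
#' @param dist Distance table from [asymmetric_distances()].
#' @param dims Centered dimension scores (for the dictionary-size
#'   control).
#' @param effect Name of the effect column (default `"cirf"`).
#' @param include_dict_size Include the destination dictionary-size
#'   control (default `TRUE`).
#' @return An `emo_distreg` wrapping the `lm` fit; `tidy()` and
#'   `glance()` give coefficient and fit summaries.
#' @export
distance_regression <- function(effects, dist, dims, effect = "cirf",
                                include_dict_size = TRUE) {
  if (!effect %in% names(effects)) abort(sprintf("no '%s' column in effects", effect))
  dat <- dplyr::filter(effects, .data$source != .data$destination)
  wide <- tidyr::pivot_wider(dist, names_from = "dimension",
                             values_from = c("dist_up", "dist_down"))
  dat <- dplyr::left_join(dat, wide, by = c("source", "destination"))
  preds <- setdiff(names(wide), c("source", "destination"))
  if (include_dict_size) {
    dimsc <- ensure_centered(dims)
    dat$dict_size_dest <- dimsc$dict_size[match(dat$destination, dimsc$emotion)]
    preds <- c(preds, "dict_size_dest")
  }
  if (any(!complete.cases(dat[preds]))) abort("effects and distance table do not align")
  fml <- stats::as.formula(paste0("`", effect, "` ~ ", paste(preds, collapse = " + ")))
  fit <- lm(fml, data = dat)
  if (any(is.na(coef(fit)))) {
    abort("distance regression design is rank deficient",
          class = "emodyn_estimation_error")
  }
  structure(list(model = fit, effect = effect, n_pairs = nrow(dat)),
            class = "emo_distreg")
}

#' @method tidy emo_distreg
#' @export
tidy.emo_distreg <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @method glance emo_distreg
#' @export
glance.emo_distreg <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(effect = x$effect, n_pairs = x$n_pairs,
                 r.squared = s$r.squared, sigma = s$sigma)
}

#' @export
print.emo_distreg <- function(x, ...) {
  cat(sprintf("<emo_distreg> %s on asymmetric distances, %d ordered pairs\n",
              x$effect, x$n_pairs))
  print(tidy(x))
  invisible(x)
}
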