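#' Configuration for the synthetic-data generator
#'
#' Bundles the study-design constants used by the simulation functions:
#' the number of emotions tracked, the dimensionality of the appraisal
#' space, the length of the daily panel, and the exogenous step dummies.
#' Defaults emulate the conditions of a two-year daily social-media panel:
#' 24 emotions observed for 790 days with two permanent step dummies
#' switching on late in the sample (platform-level events such as the
#' 280-character rollout).
#'
#' @param n_emotions Number of emotion series (N). At least 2.
#' @param n_dims Number of appraisal dimensions (K).
#' @param n_days Length of the simulated panel in days (T). At least 10.
#' @param n_exog Number of exogenous step dummies (M).
#' @param exog_break_fractions Fractions of `n_days` (strictly increasing,
#'   in (0, 1)) at which each step dummy switches from 0 to 1 and stays on.
#' @param burn_in Days simulated and discarded before the panel starts.
#' @param seed Integer seed; all generator randomness flows from it.
#' @param noise_scale Typical daily innovation standard deviation on the
#'   relative-frequency scale.
#' @param target_spectral_radius Upper bound, in (0, 1), imposed on the
#'   spectral radius of the simulated autoregressive matrix.
#'
#' @return A `sim_config` list, validated.
#' @export
#' @examples
#' cfg <- sim_config(n_emotions = 6, n_days = 200, seed = 42)
sim_config <- function(n_emotions = 24,
                       n_dims = 3,
                       n_days = 790,
                       n_exog = 2,
                       exog_break_fractions = c(0.75, 0.87),
                       burn_in = 200,
                       seed = 1,
                       noise_scale = 0.004,
                       target_spectral_radius = 0.9) {
  cfg <- list(
    n_emotions = as.integer(n_emotions),
    n_dims = as.integer(n_dims),
    n_days = as.integer(n_days),
    n_exog = as.integer(n_exog),
    exog_break_fractions = as.numeric(exog_break_fractions),
    burn_in = as.integer(burn_in),
    seed = as.integer(seed),
    noise_scale = as.numeric(noise_scale),
    target_spectral_radius = as.numeric(target_spectral_radius)
  )
  if (cfg$n_emotions < 2) abort("n_emotions must be at least 2", class = "emodyn_config_error")
  if (cfg$n_dims < 1) abort("n_dims must be at least 1", class = "emodyn_config_error")
  if (cfg$n_days < 10) abort("n_days must be at least 10", class = "emodyn_config_error")
  if (cfg$n_exog < 0) abort("n_exog must be non-negative", class = "emodyn_config_error")
  if (length(cfg$exog_break_fractions) != cfg$n_exog) {
    abort("exog_break_fractions must have one entry per exogenous dummy",
          class = "emodyn_config_error")
  }
  if (cfg$n_exog > 0) {
    f <- cfg$exog_break_fractions
    if (any(f <= 0) || any(f >= 1) || any(diff(f) <= 0)) {
      abort("exog_break_fractions must be strictly increasing within (0, 1)",
            class = "emodyn_config_error")
    }
  }
  if (cfg$burn_in < 0) abort("burn_in must be non-negative", class = "emodyn_config_error")
  if (cfg$noise_scale < 0) abort("noise_scale must be non-negative", class = "emodyn_config_error")
  if (cfg$target_spectral_radius <= 0 || cfg$target_spectral_radius >= 1) {
    abort("target_spectral_radius must lie strictly between 0 and 1",
          class = "emodyn_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d emotions, %d appraisal dims, %d days (+%d burn-in)\n",
              x$n_emotions, x$n_dims, x$n_days, x$burn_in))
  cat(sprintf("  %d step dummies at fractions %s\n",
              x$n_exog, paste(x$exog_break_fractions, collapse = ", ")))
  cat(sprintf("  seed %d, noise scale %g, target spectral radius %g\n",
              x$seed, x$noise_scale, x$target_spectral_radius))
  invisible(x)
}
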