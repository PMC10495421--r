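# Stacked restricted design implied by plugging the structural equations
# for the intercepts (mu), carryover (lambda) and cross-lagged
# transitions (tau) into the VARX(1).

#' Build the stacked restricted design for structured VAR estimation
#'
#' For each destination emotion i and day t >= 2, the response `E_it` is
#' paired with the shared regressors implied by the structural equations:
#' the base-level block `[1, DIM_i1..K, S_i]`, the carryover block
#' `[E_{i,t-1}, DIM_ik * E_{i,t-1}, S_i * E_{i,t-1}]`, the transition
#' block `[sum_{j!=i} E_{j,t-1}, sum_j DIST+_ijk E_{j,t-1} per k,
#' sum_j DIST-_ijk E_{j,t-1} per k, S_i * sum_{j!=i} E_{j,t-1}]`, plus
#' equation-specific step-dummy columns for the free exogenous
#' coefficients.  Shared-parameter count is `4K + 6` (18 when K = 3);
#' equations are stacked destination-major.
#'
#' @param panel Emotion panel tibble (`date`, emotion columns, optional
#'   `X_` step dummies).
#' @param dims Dimension-score tibble; centered automatically if not
#'   already.
#' @param dist Optional distance table from [asymmetric_distances()];
#'   computed from `dims` by default.
#' @return An `evar_design` list: `Y` ((T-1) x N responses), `X`
#'   ((T-1) x p x N regressor array), term names, and metadata.
#' @export
build_design <- function(panel, dims, dist = NULL) {
  check_panel(panel)
  check_dims(dims)
  if (nrow(panel) < 3) abort("panel must have at least 3 days")
  dimsc <- ensure_centered(dims)
  dn <- dim_names(dimsc)
  k <- length(dn)
  emo <- emotion_cols(panel)
  if (!setequal(emo, dimsc$emotion)) {
    abort("panel emotions and dimension-score emotions do not match")
  }
  dimsc <- dimsc[match(emo, dimsc$emotion), ]
  if (is.null(dist)) dist <- asymmetric_distances(dimsc)
  da <- dist_arrays(dist, emo, dn)

  E <- panel_matrix(panel)[, emo, drop = FALSE]
  X <- panel_exog(panel)
  tt <- nrow(E)
  n <- length(emo)
  m <- ncol(X)
  Y <- E[2:tt, , drop = FALSE]
  Elag <- E[1:(tt - 1), , drop = FALSE]
  Xcur <- X[2:tt, , drop = FALSE]
  DIM <- as.matrix(dimsc[dn])
  S <- dimsc$dict_size

  Rmat <- rowSums(Elag) - Elag                   # sum over sources j != i
  upmat <- array(0, c(tt - 1, n, k))
  downmat <- array(0, c(tt - 1, n, k))
  for (kk in seq_len(k)) {
    upmat[, , kk] <- Elag %*% t(da$up[, , kk])   # col i: sum_j DIST+_ijk E_{j,t-1}
    downmat[, , kk] <- Elag %*% t(da$down[, , kk])
  }

  p_shared <- 4L * k + 6L
  p <- p_shared + n * m
  exog_names <- colnames(X) %||% character(0)
  terms <- c("mu_0", paste0("mu_", dn), "mu_dict_size",
             "lambda_0", paste0("lambda_", dn), "lambda_dict_size",
             "tau_0", paste0("tau_up_", dn), paste0("tau_down_", dn), "tau_dict_size")
  if (m > 0) {
    terms <- c(terms, paste0("beta_", rep(emo, each = m), "_",
                             rep(exog_names, times = n)))
  }

  Xarr <- array(0, c(tt - 1, p, n), dimnames = list(NULL, terms, emo))
  for (i in seq_len(n)) {
    Xarr[, 1, i] <- 1
    Xarr[, 2:(k + 1), i] <- matrix(DIM[i, ], tt - 1, k, byrow = TRUE)
    Xarr[, k + 2, i] <- S[i]
    Xarr[, k + 3, i] <- Elag[, i]
    Xarr[, (k + 4):(2 * k + 3), i] <- Elag[, i] %o% DIM[i, ]
    Xarr[, 2 * k + 4, i] <- S[i] * Elag[, i]
    Xarr[, 2 * k + 5, i] <- Rmat[, i]
    Xarr[, (2 * k + 6):(3 * k + 5), i] <- upmat[, i, ]
    Xarr[, (3 * k + 6):(4 * k + 5), i] <- downmat[, i, ]
    Xarr[, 4 * k + 6, i] <- S[i] * Rmat[, i]
    if (m > 0) {
      Xarr[, p_shared + (i - 1) * m + seq_len(m), i] <- Xcur
    }
  }

  structure(list(
    Y = Y, X = Xarr, terms = terms, p_shared = p_shared,
    emotions = emo, dim_names = dn, k = k, m = m,
    exog_names = exog_names, dims = dimsc, dist = dist,
    xbar = if (m > 0) colMeans(Xcur) else numeric(0),
    dates = as.Date(panel$date)[2:tt]
  ), class = "evar_design")
}
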