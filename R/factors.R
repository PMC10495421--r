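#' Reduce appraisal survey ratings to higher-order factor scores
#'
#' Performs an exploratory factor analysis of per-emotion mean ratings on
#' a set of appraisal dimensions (valence, arousal, dominance,
#' motivational state, time orientation, agency, certainty, attentional
#' activity, effort): principal-axis factoring on the correlation matrix,
#' varimax rotation, and regression-method factor scores.  When `k = 3`
#' and the appraisals include valence, arousal and dominance, each factor
#' is named after the eponymous appraisal loading on it most strongly and
#' its sign is fixed so that loading is positive; otherwise signs are
#' fixed by each factor's dominant variable.
#'
#' @param survey Data frame with an `emotion` column, numeric appraisal
#'   rating columns, and optionally a `dict_size` column carried through.
#' @param k Number of factors to extract (default 3). Must be less than
#'   the number of emotions.
#' @param rotate Apply a varimax rotation (default `TRUE`). Rotation is
#'   orthogonal, so communalities are unchanged.
#' @return A tibble with `emotion`, one column of factor scores per
#'   factor, and `dict_size` if supplied; attributes `loadings`,
#'   `communalities` and `uniquenesses` carry the measurement side.
#' @export
reduce_appraisals <- function(survey, k = 3, rotate = TRUE) {
  if (!"emotion" %in% names(survey)) abort("survey needs an 'emotion' column")
  keep <- setdiff(names(survey)[vapply(survey, is.numeric, logical(1))], "dict_size")
  x <- as.matrix(survey[keep])
  n <- nrow(x)
  p <- ncol(x)
  if (n <= k) abort("need more emotions than factors")
  if (k < 1 || k > p) abort("k must be between 1 and the number of appraisals")
  if (any(apply(x, 2, sd) == 0)) abort("constant appraisal column; cannot standardize")
  z <- scale(x)
  r <- cor(x)

  lo <- paf_loadings(r, k)
  if (rotate && k > 1) {
    rot <- varimax(lo, normalize = TRUE)
    lo <- lo %*% rot$rotmat
  }
  lo <- label_factors(lo, appraisals = keep, k = k)

  # regression-method scores; pseudo-inverse handles rank-deficient R
  w <- tryCatch(solve(r, lo), error = function(e) MASS::ginv(r) %*% lo)
  scores <- z %*% w
  colnames(scores) <- colnames(lo)

  out <- tibble::as_tibble(scores)
  out$emotion <- as.character(survey$emotion)
  out <- dplyr::relocate(out, "emotion")
  if ("dict_size" %in% names(survey)) out$dict_size <- survey$dict_size
  attr(out, "centered") <- FALSE
  attr(out, "loadings") <- lo
  attr(out, "communalities") <- rowSums(lo^2)
  attr(out, "uniquenesses") <- 1 - rowSums(lo^2)
  out
}

# Iterated principal-axis factoring of a correlation matrix.
paf_loadings <- function(r, k, max_iter = 200, tol = 1e-9) {
  p <- ncol(r)
  if (k == p) {
    e <- eigen(r, symmetric = TRUE)
    if (min(e$values) < -1e-8) abort("correlation matrix is not PSD")
    lo <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), p)
    rownames(lo) <- rownames(r)
    return(lo)
  }
  h2 <- init_communalities(r)
  lo <- NULL
  for (it in seq_len(max_iter)) {
    rr <- r
    diag(rr) <- h2
    e <- eigen(rr, symmetric = TRUE)
    ev <- pmax(e$values[seq_len(k)], 0)
    lo <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
    h2_new <- pmin(rowSums(lo^2), 1)
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      break
    }
    h2 <- h2_new
  }
  rownames(lo) <- rownames(r)
  lo
}

# Squared multiple correlations when R is invertible, max |r| fallback
# for singular correlation matrices (e.g. data on an exact factor model).
init_communalities <- function(r) {
  h2 <- tryCatch(1 - 1 / diag(solve(r)), error = function(e) NULL)
  if (is.null(h2) || any(!is.finite(h2))) {
    a <- abs(r)
    diag(a) <- 0
    h2 <- apply(a, 1, max)
  }
  pmin(pmax(h2, 0.05), 0.999)
}

label_factors <- function(lo, appraisals, k) {
  canon <- c("valence", "arousal", "dominance")
  nm <- tolower(appraisals)
  if (k == 3 && all(canon %in% nm)) {
    assigned <- integer(0)
    labels <- rep(NA_character_, 3)
    # greedily assign each eponymous appraisal to its strongest factor
    strength <- vapply(canon, function(a) max(abs(lo[match(a, nm), ])), numeric(1))
    for (a in canon[order(-strength)]) {
      row <- lo[match(a, nm), ]
      cand <- setdiff(order(-abs(row)), assigned)
      fac <- cand[1]
      assigned <- c(assigned, fac)
      labels[fac] <- a
      if (row[fac] < 0) lo[, fac] <- -lo[, fac]
    }
    labels[is.na(labels)] <- paste0("factor_", which(is.na(labels)))
    colnames(lo) <- labels
    lo <- lo[, order(match(colnames(lo), canon)), drop = FALSE]
  } else {
    for (j in seq_len(ncol(lo))) {
      top <- which.max(abs(lo[, j]))
      if (lo[top, j] < 0) lo[, j] <- -lo[, j]
    }
    colnames(lo) <- paste0("factor_", seq_len(ncol(lo)))
  }
  lo
}
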