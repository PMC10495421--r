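#' Mean-center dimension scores and dictionary sizes across emotions
#'
#' Subtracts the per-column mean (across emotions) from every appraisal
#' score column and from the dictionary-size control, so that the model's
#' baseline coefficients refer to an emotion scoring average on every
#' dimension.  Idempotent: centering twice equals centering once.
#'
#' @param dims Tibble with `emotion`, score columns, `dict_size`.
#' @return The centered tibble, flagged with `attr(, "centered") = TRUE`.
#' @export
center_scores <- function(dims) {
  check_dims(dims)
  dn <- c(dim_names(dims), "dict_size")
  out <- dims
  for (col in dn) out[[col]] <- as.numeric(out[[col]] - mean(out[[col]]))
  attr(out, "centered") <- TRUE
  out
}

ensure_centered <- function(dims) {
  if (is_centered(dims)) dims else center_scores(dims)
}

#' Asymmetric appraisal-space distances between emotion pairs
#'
#' For each ordered pair (destination i, source j) and dimension k, the
#' upward distance is `max(score_i - score_j, 0)` (the destination lies
#' above the source on dimension k) and the downward distance is
#' `max(score_j - score_i, 0)`.  Exactly one of the two is nonzero unless
#' the scores tie; both are zero on the diagonal.  These distances let
#' cross-lagged transition coefficients differ by direction of travel
#' along each dimension.
#'
#' @param dims Dimension-score tibble (centered or raw; pairwise
#'   differences are unaffected by centering).
#' @return A tibble with columns `destination`, `source`, `dimension`,
#'   `dist_up`, `dist_down`, one row per ordered pair and dimension.
#' @export
#' @examples
#' dims <- sim_dimension_scores(sim_config(n_emotions = 4, seed = 1))
#' asymmetric_distances(dims)
asymmetric_distances <- function(dims) {
  check_dims(dims)
  dn <- dim_names(dims)
  emo <- dims$emotion
  out <- tidyr::expand_grid(destination = emo, source = emo, dimension = dn)
  sc <- as.matrix(dims[dn])
  rownames(sc) <- emo
  di <- sc[out$destination, , drop = FALSE][cbind(seq_len(nrow(out)), match(out$dimension, dn))]
  dj <- sc[out$source, , drop = FALSE][cbind(seq_len(nrow(out)), match(out$dimension, dn))]
  out$dist_up <- pmax(di - dj, 0)
  out$dist_down <- pmax(dj - di, 0)
  attr(out, "emotions") <- emo
  attr(out, "dims") <- dn
  out
}

# N x N x K arrays (up, down) from the tidy distance table, in the
# emotion/dimension order of `emotions` / `dnames`.
dist_arrays <- function(dist, emotions, dnames) {
  n <- length(emotions)
  k <- length(dnames)
  up <- array(0, c(n, n, k), dimnames = list(emotions, emotions, dnames))
  down <- up
  ii <- match(dist$destination, emotions)
  jj <- match(dist$source, emotions)
  kk <- match(dist$dimension, dnames)
  if (any(is.na(ii)) || any(is.na(jj)) || any(is.na(kk))) {
    abort("distance table does not match the emotion/dimension sets")
  }
  up[cbind(ii, jj, kk)] <- dist$dist_up
  down[cbind(ii, jj, kk)] <- dist$dist_down
  list(up = up, down = down)
}
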