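#' Simulate emotion dimension scores and dictionary sizes
#'
#' Draws an N x K table of appraisal-dimension scores (standard normal per
#' column) together with per-emotion dictionary sizes (log-uniform between
#' 10 and 500 terms), emulating the kind of factor-score table produced by
#' reducing an appraisal survey.  Fully determined by `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `emotion`, `dim_1` .. `dim_K`, `dict_size`
#'   (uncentered; see [center_scores()]).
#' @export
#' @examples
#' sim_dimension_scores(sim_config(n_emotions = 6, seed = 7))
sim_dimension_scores <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_emotions
  k <- config$n_dims
  set.seed(config$seed + 101L)
  scores <- matrix(rnorm(n * k), n, k)
  # guard the (vanishingly unlikely) degenerate draw with zero column spread
  for (j in seq_len(k)) {
    while (var(scores[, j]) <= .Machine$double.eps) scores[, j] <- rnorm(n)
  }
  colnames(scores) <- paste0("dim_", seq_len(k))
  dict_size <- as.integer(round(exp(runif(n, log(10), log(500)))))
  out <- tibble::as_tibble(scores)
  out <- dplyr::mutate(out,
                       emotion = sprintf("emotion_%02d", seq_len(n)),
                       dict_size = dict_size)
  out <- dplyr::relocate(out, "emotion")
  attr(out, "centered") <- FALSE
  out
}
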