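# End-to-end orchestration: simulate or load inputs, run diagnostics,
# fit, and produce the duration / co-occurrence / transition analyses
# with machine-readable artifacts.

#' Run the full emotion-dynamics analysis pipeline
#'
#' Sequences the package's stages: obtain a daily emotion panel and
#' dimension scores (loaded from CSV paths, passed as tibbles, or
#' simulated from a [sim_config()]), optionally label and aggregate a raw
#' corpus, run pre-estimation diagnostics (ADF per series, lag-order
#' selection, optional Granger tests), fit the structured VAR by FGLS,
#' tabulate durations (per emotion and +/- 1 SD profiles), trace IRFs
#' for a shock to every source emotion, and regress the day-0 (CE) and
#' day 1-29 cumulative (CIRF) effects on asymmetric distances.  All
#' randomness flows from `config$seed`; rerunning with the same
#' configuration reproduces the results byte for byte.
#'
#' @param config Named list (or path to a YAML file) with entries:
#'   `seed`; `out_dir` (optional: artifacts written when set); `panel`
#'   and `dims` (tibbles or CSV paths; omit both to simulate); `simulate`
#'   (list of [sim_config()] arguments for the synthetic route);
#'   `corpus`/`dictionaries` (optional JSONL/JSON paths for the labeling
#'   route); `duration_p` (default 90); `horizon` (default 30);
#'   `shock_fraction` (default 0.10); `delta_mode`; `p_max` (lag search,
#'   default 5); `granger` (default TRUE).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a results bundle: `fit`, `duration`, `shocks`,
#'   `ce_regression`, `cirf_regression`, `diagnostics`, `truth` (when
#'   simulated), `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    if (!requireNamespace("yaml", quietly = TRUE)) abort("yaml package required to read config files")
    config <- yaml::read_yaml(config)
  }
  say <- function(...) if (!quiet) inform(sprintf(...))
  seed <- as.integer(config$seed %||% 1L)
  duration_p <- config$duration_p %||% 90
  horizon <- config$horizon %||% 30
  shock_fraction <- config$shock_fraction %||% 0.10
  delta_mode <- config$delta_mode %||% "stationary-mean"
  p_max <- config$p_max %||% 5
  truth <- NULL

  # --- stage: inputs -------------------------------------------------
  if (!is.null(config$corpus) && !is.null(config$dictionaries)) {
    say("stage label: reading dictionaries and corpus, labeling, aggregating")
    dicts <- if (is.character(config$dictionaries)) read_dictionaries_json(config$dictionaries) else config$dictionaries
    corpus <- if (is.character(config$corpus)) {
      read_corpus_jsonl(config$corpus, names(dicts))
    } else config$corpus
    labeled <- label_corpus(corpus[c("date", "doc_id", "tokens")], dicts)
    panel <- aggregate_daily(labeled)
    dims <- load_dims(config$dims)
  } else if (!is.null(config$panel)) {
    say("stage load: reading panel and dimension scores")
    panel <- if (is.character(config$panel)) read_panel_csv(config$panel) else config$panel
    dims <- load_dims(config$dims)
  } else {
    say("stage simulate: generating scores, truth and panel (seed %d)", seed)
    sim_args <- config$simulate %||% list()
    sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    dims <- sim_dimension_scores(cfg)
    truth <- sim_structured_params(dims, cfg)
    panel <- simulate_panel(truth$coeffs, cfg)
  }
  check_panel(panel)

  # --- stage: diagnostics --------------------------------------------
  say("stage diagnose: ADF per series, lag order (p_max %d)", p_max)
  emo <- emotion_cols(panel)
  adf <- purrr::map_dfr(emo, function(e) {
    dplyr::mutate(adf_test(panel[[e]]), emotion = e, .before = 1)
  })
  lag_sel <- select_lag_order(panel, p_max = p_max)
  granger <- if (isTRUE(config$granger %||% TRUE)) granger_tests(panel) else NULL

  # --- stage: fit ----------------------------------------------------
  say("stage fit: FGLS on the structured design (%d emotions, %d days)",
      length(emo), nrow(panel))
  fit <- fit_emotion_var(panel, dims)

  # --- stage: dynamics -----------------------------------------------
  say("stage dynamics: durations (P = %g), %d-day IRFs, distance regressions",
      duration_p, horizon)
  durations <- duration_table(fit, p = duration_p)
  shocks <- run_all_shocks(fit, shock_fraction = shock_fraction,
                           delta_mode = delta_mode, horizon = horizon,
                           sample_means = colMeans(panel_matrix(panel)))
  pair_effects <- tidy(shocks)
  ce_reg <- distance_regression(pair_effects, fit$dist, fit$dims, effect = "ce")
  cirf_reg <- if (!is.null(shocks$cirf)) {
    distance_regression(pair_effects, fit$dist, fit$dims, effect = "cirf")
  } else NULL

  manifest <- list(
    package = "emodyn",
    version = as.character(utils::packageVersion("emodyn")),
    seed = seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    n_emotions = length(emo),
    n_days = nrow(panel)
  )
  bundle <- list(
    panel = panel, dims = dims, fit = fit, duration = durations,
    shocks = shocks, ce_regression = ce_reg, cirf_regression = cirf_reg,
    diagnostics = list(adf = adf, lag_order = lag_sel, granger = granger),
    truth = truth, manifest = manifest
  )

  if (!is.null(config$out_dir)) {
    say("stage report: writing artifacts to %s", config$out_dir)
    write_bundle(bundle, config$out_dir)
  }
  invisible(bundle)
}

load_dims <- function(dims) {
  if (is.null(dims)) abort("config must provide dimension scores ('dims')")
  if (is.character(dims)) read_dim_scores_csv(dims) else dims
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- bundle$fit
  results <- list(
    manifest = bundle$manifest,
    parameters = tidy(fit),
    duration = bundle$duration,
    ce_regression = tidy(bundle$ce_regression),
    cirf_regression = if (!is.null(bundle$cirf_regression)) tidy(bundle$cirf_regression),
    adf = bundle$diagnostics$adf,
    lag_order = bundle$diagnostics$lag_order$criteria,
    lag_selected = bundle$diagnostics$lag_order$selected
  )
  if (!is.null(bundle$truth)) {
    results$truth_shared <- as.list(bundle$truth$truth$shared)
  }
  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  write_panel_csv(bundle$panel, file.path(out_dir, "panel.csv"))
  readr::write_csv(bundle$duration, file.path(out_dir, "duration.csv"))
  readr::write_csv(tidy(bundle$shocks), file.path(out_dir, "pair_effects.csv"))
  readr::write_csv(tidy(fit), file.path(out_dir, "parameters.csv"))
  readr::write_csv(bundle$diagnostics$adf, file.path(out_dir, "adf.csv"))
  invisible(out_dir)
}

#' Heatmap of a destination-by-source effect matrix in appraisal order
#'
#' Reorders the rows and columns of a square effect matrix (e.g. the
#' CIRF matrix) so emotions appear in ascending order of a chosen
#' dimension score, writes the permuted matrix as CSV when asked, and
#' draws a tile heatmap.
#'
#' @param mat Square matrix with emotion dimnames (rows = destination).
#' @param dims Dimension-score tibble with the ordering dimension.
#' @param order_by Dimension column used to sort (e.g. `"valence"`).
#' @param csv Optional path for the permuted matrix as CSV.
#' @param file Optional path for the plot image (via [ggplot2::ggsave()]).
#' @return An `emo_heatmap` list: `matrix` (permuted), `plot` (ggplot),
#'   `order` (emotion ordering used).
#' @export
render_heatmap <- function(mat, dims, order_by, csv = NULL, file = NULL) {
  if (nrow(mat) != ncol(mat)) abort("effect matrix must be square")
  if (!order_by %in% dim_names(dims)) {
    abort(sprintf("unknown ordering dimension '%s'", order_by))
  }
  emo <- rownames(mat)
  if (is.null(emo) || !setequal(emo, dims$emotion)) {
    abort("matrix dimnames must match the dimension-score emotions")
  }
  ord <- dims$emotion[order(dims[[order_by]])]
  pm <- mat[ord, ord]
  if (!is.null(csv)) {
    readr::write_csv(dplyr::bind_cols(tibble::tibble(destination = rownames(pm)),
                                      tibble::as_tibble(pm)), csv)
  }
  long <- tibble::as_tibble(pm, rownames = "destination") |>
    tidyr::pivot_longer(-"destination", names_to = "source", values_to = "effect") |>
    dplyr::mutate(destination = factor(.data$destination, levels = ord),
                  source = factor(.data$source, levels = ord))
  plt <- ggplot2::ggplot(long, ggplot2::aes(x = .data$source, y = .data$destination,
                                            fill = .data$effect)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(x = paste0("source (ascending ", order_by, ")"),
                  y = paste0("destination (ascending ", order_by, ")"),
                  fill = "effect") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  if (!is.null(file)) ggplot2::ggsave(file, plt, width = 7, height = 6)
  structure(list(matrix = pm, plot = plt, order = ord), class = "emo_heatmap")
}

#' @export
print.emo_heatmap <- function(x, ...) {
  print(x$plot)
  invisible(x)
}

#' Plot impulse-response paths
#'
#' @param object An `emo_irf`.
#' @param ... Unused.
#' @return A ggplot of per-emotion response paths over days.
#' @method autoplot emo_irf
#' @export
autoplot.emo_irf <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$day, y = .data$response,
                               colour = .data$emotion)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "days since shock", y = "incremental frequency response") +
    ggplot2::theme_minimal()
}

#' Plot a daily emotion-frequency panel
#'
#' @param panel Emotion panel tibble.
#' @param emotions Optional subset of emotion columns to draw.
#' @return A ggplot of daily relative-frequency series.
#' @export
plot_panel <- function(panel, emotions = NULL) {
  check_panel(panel)
  emo <- emotions %||% emotion_cols(panel)
  long <- tidyr::pivot_longer(panel[c("date", emo)], -"date",
                              names_to = "emotion", values_to = "frequency")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$date, y = .data$frequency,
                                     colour = .data$emotion)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "daily relative frequency") +
    ggplot2::theme_minimal()
}
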