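# Plain-text readers/writers for the package's tabular interchange
# formats: panels and dimension scores as CSV, dictionaries as JSON,
# corpora as JSONL.

#' Read / write an emotion panel as CSV
#'
#' The panel CSV has an ISO-8601 `date` column, one column per emotion,
#' and optional exogenous step-dummy columns prefixed `X_`.
#'
#' @param path File path.
#' @return `read_panel_csv()` returns a validated panel tibble.
#' @export
read_panel_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  out$date <- as.Date(out$date)
  check_panel(out)
  out
}

#' @rdname read_panel_csv
#' @param panel Panel tibble.
#' @export
write_panel_csv <- function(panel, path) {
  check_panel(panel)
  readr::write_csv(panel, path)
  invisible(path)
}

#' Read / write dimension scores as CSV
#'
#' Columns: `emotion`, one numeric column per dimension, `dict_size`.
#' An optional `centered` comment is not stored; read scores are treated
#' as uncentered until [center_scores()] is applied.
#'
#' @param path File path.
#' @export
read_dim_scores_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  check_dims(out)
  attr(out, "centered") <- FALSE
  out
}

#' @rdname read_dim_scores_csv
#' @param dims Dimension-score tibble.
#' @export
write_dim_scores_csv <- function(dims, path) {
  check_dims(dims)
  readr::write_csv(dims, path)
  invisible(path)
}

#' Read / write emotion dictionaries as JSON
#'
#' Schema: `{"emotion": {"unigrams": [...], "bigrams": [["w1","w2"], ...]}}`.
#'
#' @param path File path.
#' @export
read_dictionaries_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- lapply(raw, function(d) {
    list(unigrams = as.character(unlist(d$unigrams)),
         bigrams = lapply(d$bigrams, function(b) as.character(unlist(b))))
  })
  emotion_dictionaries(out)
}

#' @rdname read_dictionaries_json
#' @param dicts An [emotion_dictionaries()] object.
#' @export
write_dictionaries_json <- function(dicts, path) {
  stopifnot(inherits(dicts, "emotion_dictionaries"))
  jsonlite::write_json(unclass(dicts), path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' Read / write a labeled corpus as JSONL
#'
#' One JSON object per line: `{"date": "...", "tokens": [...],
#' "true_labels": [0/1, ...]}`, labels in dictionary order.
#'
#' @param path File path.
#' @param emotions Emotion names giving the label order (required to
#'   write; recovered on read when stored).
#' @export
write_corpus_jsonl <- function(corpus, path, emotions = NULL) {
  if (is.null(emotions)) {
    emotions <- sub("^true_", "", grep("^true_", names(corpus), value = TRUE))
  }
  lab <- as.matrix(corpus[paste0("true_", emotions)])
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    writeLines(jsonlite::toJSON(list(
      date = as.character(corpus$date[i]),
      tokens = corpus$tokens[[i]],
      true_labels = unname(lab[i, ])
    ), auto_unbox = FALSE), con)
  }
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @param corpus Corpus tibble with `date`, `tokens`, `true_<emotion>`.
#' @export
read_corpus_jsonl <- function(path, emotions) {
  lines <- readLines(path)
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
  lab <- do.call(rbind, lapply(recs, function(r) as.integer(r$true_labels)))
  colnames(lab) <- paste0("true_", emotions)
  dplyr::bind_cols(
    tibble::tibble(
      date = as.Date(vapply(recs, function(r) r$date, character(1))),
      doc_id = seq_along(recs),
      tokens = lapply(recs, function(r) as.character(r$tokens))
    ),
    tibble::as_tibble(lab)
  )
}
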