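# Dictionary-based emotion labeling and daily aggregation.

#' Build or validate emotion dictionaries
#'
#' An emotion dictionary maps each emotion to a set of lemmatized unigrams
#' and a set of ordered bigrams.  Matching (see [label_document()]) is by
#' exact, case-folded string equality; bigrams must occur as adjacent
#' ordered token pairs.
#'
#' @param x Named list: one entry per emotion, each a list with character
#'   vector `unigrams` and a list `bigrams` of length-2 character vectors.
#' @return The validated dictionary list, classed `emotion_dictionaries`.
#' @export
emotion_dictionaries <- function(x) {
  if (is.null(names(x)) || anyDuplicated(names(x)) || any(names(x) == "")) {
    abort("dictionaries must be a named list with unique emotion names")
  }
  for (emo in names(x)) {
    d <- x[[emo]]
    uni <- d$unigrams %||% character(0)
    big <- d$bigrams %||% list()
    if (any(!nzchar(uni))) abort(sprintf("empty unigram in dictionary '%s'", emo))
    for (b in big) {
      if (length(b) != 2 || any(!nzchar(b))) {
        abort(sprintf("bigrams in dictionary '%s' must be two non-empty tokens", emo))
      }
    }
    x[[emo]] <- list(unigrams = as.character(uni),
                     bigrams = lapply(big, as.character))
  }
  structure(x, class = "emotion_dictionaries")
}

#' Simulate synthetic emotion dictionaries
#'
#' Creates disjoint per-emotion vocabularies of synthetic unigram and
#' bigram terms, useful as fixtures for the labeling pipeline.
#'
#' @param emotions Character vector of emotion names.
#' @param n_unigrams,n_bigrams Terms per emotion.
#' @return An [emotion_dictionaries()] object.
#' @export
sim_dictionaries <- function(emotions, n_unigrams = 3, n_bigrams = 2) {
  out <- lapply(seq_along(emotions), function(i) {
    list(
      unigrams = sprintf("e%02d_u%02d", i, seq_len(n_unigrams)),
      bigrams = lapply(seq_len(n_bigrams),
                       function(j) sprintf("e%02d_b%02d_%s", i, j, c("a", "b")))
    )
  })
  names(out) <- emotions
  emotion_dictionaries(out)
}

all_dictionary_tokens <- function(dicts) {
  unique(tolower(unlist(lapply(dicts, function(d) c(d$unigrams, unlist(d$bigrams))))))
}

#' Label one document with emotion indicators
#'
#' Emotion i is flagged when any of its unigrams appears among the
#' document tokens, or any of its bigrams appears as an adjacent ordered
#' token pair.  Matching is exact string equality after case-folding;
#' a document may carry none, one, or several emotions.
#'
#' @param tokens Character vector of pre-lemmatized tokens (may be empty).
#' @param dicts An [emotion_dictionaries()] object.
#' @return Named integer vector of 0/1 indicators, one per emotion.
#' @export
#' @examples
#' d <- emotion_dictionaries(list(joy = list(unigrams = "happy",
#'                                           bigrams = list(c("very", "good")))))
#' label_document(c("a", "happy", "day"), d)
label_document <- function(tokens, dicts) {
  stopifnot(inherits(dicts, "emotion_dictionaries"))
  tok <- tolower(as.character(tokens))
  pairs <- if (length(tok) >= 2) paste(tok[-length(tok)], tok[-1]) else character(0)
  vapply(dicts, function(d) {
    hit <- any(tolower(d$unigrams) %in% tok)
    if (!hit && length(d$bigrams) > 0) {
      bg <- vapply(d$bigrams, function(b) paste(tolower(b), collapse = " "), character(1))
      hit <- any(bg %in% pairs)
    }
    as.integer(hit)
  }, integer(1))
}

#' Label every document in a corpus
#'
#' @param corpus Tibble with a `tokens` list-column (and typically `date`).
#' @param dicts An [emotion_dictionaries()] object.
#' @return `corpus` with one added 0/1 indicator column per emotion.
#' @export
label_corpus <- function(corpus, dicts) {
  stopifnot(inherits(dicts, "emotion_dictionaries"))
  if (!"tokens" %in% names(corpus)) abort("corpus needs a 'tokens' list-column")
  lab <- t(vapply(corpus$tokens, label_document, integer(length(dicts)), dicts = dicts))
  if (length(dicts) == 1) lab <- matrix(lab, ncol = 1)
  colnames(lab) <- names(dicts)
  dplyr::bind_cols(corpus, tibble::as_tibble(lab))
}

#' Aggregate labeled documents to daily relative frequencies
#'
#' The daily relative frequency of an emotion is the share of that day's
#' documents carrying its label (denominator: all documents that day, so
#' multi-label days need not sum to one).  The date range must be
#' gap-free; a day with no documents inside the span is an error naming
#' the missing date.
#'
#' @param labeled Tibble with `date` and 0/1 indicator columns (any
#'   numeric columns other than `date`, `doc_id`; `tokens` is ignored).
#' @return An emotion panel tibble: `date` plus one frequency column per
#'   emotion, values in [0, 1].
#' @export
aggregate_daily <- function(labeled) {
  if (!"date" %in% names(labeled)) abort("labeled corpus needs a 'date' column")
  labeled$date <- as.Date(labeled$date)
  span <- seq(min(labeled$date), max(labeled$date), by = "day")
  missing <- setdiff(as.character(span), as.character(unique(labeled$date)))
  if (length(missing) > 0) {
    abort(sprintf("no documents on %s; the daily span must be gap-free",
                  paste(missing, collapse = ", ")),
          class = "emodyn_missing_day_error")
  }
  label_cols <- setdiff(names(labeled)[vapply(labeled, is.numeric, logical(1))], "doc_id")
  if (length(label_cols) == 0) abort("no indicator columns to aggregate")
  out <- labeled |>
    dplyr::group_by(.data$date) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(label_cols), mean), .groups = "drop") |>
    dplyr::arrange(.data$date)
  out
}

#' Simulate a dated, labeled token corpus with planted emotion rates
#'
#' Each document on day t independently contains, for each emotion, one
#' randomly chosen dictionary term with probability equal to that day's
#' planted rate, padded with filler tokens drawn from a vocabulary
#' disjoint from every dictionary.  Bigram terms are kept adjacent.  The
#' planted indicators are recorded as `true_<emotion>` columns, so the
#' labeling pipeline can be checked against ground truth.
#'
#' @param dicts An [emotion_dictionaries()] object.
#' @param rates Tibble: `date` plus one rate column in [0, 1] per emotion
#'   (names must match the dictionary).
#' @param docs_per_day Documents generated per day.
#' @param seed Integer seed.
#' @param mean_filler Mean number of filler tokens per document.
#' @return Tibble with `date`, `doc_id`, `tokens` (list-column) and
#'   `true_<emotion>` indicator columns.
#' @export
sim_corpus <- function(dicts, rates, docs_per_day = 200, seed = 1, mean_filler = 8) {
  stopifnot(inherits(dicts, "emotion_dictionaries"))
  emos <- names(dicts)
  if (!all(emos %in% names(rates))) abort("rates must have a column per dictionary emotion")
  rmat <- as.matrix(rates[emos])
  if (any(rmat < 0 | rmat > 1)) abort("rates must lie in [0, 1]")
  filler <- sprintf("filler_%03d", 1:200)
  if (any(filler %in% all_dictionary_tokens(dicts))) {
    abort("dictionary vocabulary overlaps the filler vocabulary",
          class = "emodyn_generation_error")
  }
  terms <- lapply(dicts, function(d) c(as.list(d$unigrams), d$bigrams))

  set.seed(seed)
  days <- purrr::map(seq_len(nrow(rates)), function(t) {
    inc <- matrix(runif(docs_per_day * length(emos)) < rep(rmat[t, ], each = docs_per_day),
                  docs_per_day, length(emos))
    docs <- purrr::map(seq_len(docs_per_day), function(d) {
      units <- purrr::map(which(inc[d, ]), function(e) {
        tset <- terms[[e]]
        tset[[sample.int(length(tset), 1)]]
      })
      nf <- rpois(1, mean_filler) + 1
      units <- c(units, as.list(sample(filler, nf, replace = TRUE)))
      unlist(units[sample.int(length(units))], use.names = FALSE)
    })
    lab <- matrix(as.integer(inc), docs_per_day, length(emos))
    colnames(lab) <- paste0("true_", emos)
    dplyr::bind_cols(
      tibble::tibble(date = as.Date(rates$date[t]),
                     doc_id = seq_len(docs_per_day),
                     tokens = docs),
      tibble::as_tibble(lab)
    )
  })
  dplyr::bind_rows(days)
}
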