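# Internal helpers shared across modules.

# Columns of a panel tibble that hold emotion frequencies: numeric columns
# that are neither the date nor exogenous step dummies (prefixed "X_").
emotion_cols <- function(panel) {
  nm <- names(panel)
  num <- vapply(panel, is.numeric, logical(1))
  nm[num & nm != "date" & !startsWith(nm, "X_")]
}

exog_cols <- function(panel) {
  nm <- names(panel)
  nm[startsWith(nm, "X_")]
}

panel_matrix <- function(panel) {
  em <- emotion_cols(panel)
  if (length(em) < 1) abort("panel has no emotion columns")
  as.matrix(panel[em])
}

panel_exog <- function(panel) {
  xc <- exog_cols(panel)
  m <- as.matrix(panel[xc])
  if (length(xc) == 0) m <- matrix(0, nrow(panel), 0)
  m
}

check_panel <- function(panel) {
  if (!"date" %in% names(panel)) abort("panel must have a 'date' column")
  d <- as.Date(panel$date)
  if (nrow(panel) >= 2 && any(diff(d) != 1)) {
    abort("panel dates must be consecutive days")
  }
  E <- panel_matrix(panel)
  if (any(!is.finite(E))) abort("panel frequencies must be finite")
  X <- panel_exog(panel)
  if (ncol(X) > 0 && any(apply(X, 2, function(x) any(diff(x) < 0)))) {
    abort("exogenous step-dummy columns must be monotone non-decreasing")
  }
  invisible(panel)
}

# Dimension-score tables: numeric score columns are everything numeric
# except the dictionary-size control.
dim_names <- function(dims) {
  nm <- names(dims)
  num <- vapply(dims, is.numeric, logical(1))
  nm[num & nm != "dict_size"]
}

check_dims <- function(dims) {
  if (!"emotion" %in% names(dims)) abort("dimension scores need an 'emotion' column")
  if (!"dict_size" %in% names(dims)) abort("dimension scores need a 'dict_size' column")
  dn <- dim_names(dims)
  if (length(dn) < 1) abort("dimension scores need at least one score column")
  sc <- as.matrix(dims[dn])
  if (any(!is.finite(sc))) abort("dimension scores must be finite")
  invisible(dims)
}

is_centered <- function(dims) isTRUE(attr(dims, "centered"))

spectral_radius <- function(m) max(Mod(eigen(m, only.values = TRUE)$values))

check_psd <- function(sigma, name = "sigma", tol = 1e-8) {
  if (!isTRUE(all.equal(sigma, t(sigma), tolerance = 1e-8))) {
    abort(paste0(name, " must be symmetric"))
  }
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1)) {
    abort(paste0(name, " must be positive semi-definite"))
  }
  invisible(sigma)
}
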