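# File I/O. Persons are rows and items are columns; the column order in the
# file IS the administration order that defines the lag terms, so ability
# estimates from auto-regressive models depend on it.

#' Read a persons x items binary response matrix from delimited text
#'
#' Cells must be 0, 1, or one of `missing_codes`; anything else is a parse
#' error naming the offending row and column. Ragged rows are rejected.
#'
#' @param path File path.
#' @param delimiter Field delimiter (default comma).
#' @param missing_codes Tokens treated as missing (default `"NA"` and the
#'   empty string).
#' @param has_header Does the first line hold column names? (default TRUE)
#' @param id_column Optional name or index of a person-identifier column to
#'   drop from the responses.
#' @return A tibble of 0/1/NA integer columns, with attributes
#'   `n_missing` (count of missing cells) and `person_id` (when
#'   `id_column` was given).
#' @export
read_response_matrix <- function(path, delimiter = ",",
                                 missing_codes = c("NA", ""),
                                 has_header = TRUE, id_column = NULL) {
  if (!file.exists(path)) abort_input("File not found: %s", path)
  df <- readr::read_delim(path, delim = delimiter,
                          col_names = has_header,
                          col_types = readr::cols(.default = readr::col_character()),
                          na = character(), trim_ws = TRUE,
                          progress = FALSE, show_col_types = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort_input("Malformed file %s: %s at row %d.", path,
                probs$expected[1], probs$row[1])
  }
  person_id <- NULL
  if (!is.null(id_column)) {
    idx <- if (is.numeric(id_column)) as.integer(id_column) else match(id_column, names(df))
    if (is.na(idx) || idx < 1L || idx > ncol(df)) {
      abort_input("`id_column` does not identify a column of %s.", path)
    }
    person_id <- df[[idx]]
    df <- df[-idx]
  }
  out <- matrix(NA_integer_, nrow(df), ncol(df))
  for (jc in seq_along(df)) {
    tok <- df[[jc]]
    missing <- tok %in% missing_codes
    valid <- missing | tok %in% c("0", "1")
    if (!all(valid)) {
      i <- which(!valid)[1]
      abort_input("Non-binary token \"%s\" at row %d, column %d of %s.",
                  tok[i], i, jc, path)
    }
    out[!missing, jc] <- as.integer(tok[!missing])
  }
  colnames(out) <- if (has_header) names(df) else sprintf("item_%d", seq_len(ncol(out)))
  res <- tibble::as_tibble(as.data.frame(out))
  attr(res, "n_missing") <- sum(is.na(out))
  if (!is.null(person_id)) attr(res, "person_id") <- person_id
  res
}

#' Write a response matrix to delimited text
#'
#' Missing responses are written as `NA`. The written file round-trips
#' through [read_response_matrix()].
#'
#' @param data Persons x items responses (matrix or data frame).
#' @param path Output path.
#' @param delimiter Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(data, path, delimiter = ",") {
  X <- as_response_matrix(data)
  df <- as.data.frame(X)
  names(df) <- sprintf("item_%d", seq_len(ncol(X)))
  readr::write_delim(df, path, delim = delimiter, na = "NA")
  invisible(path)
}

#' Write model parameters to a CSV table
#'
#' One row per item with columns `model`, `item`, `slope`, `threshold`,
#' followed by one row per lag coefficient (`parameter` column
#' distinguishes the blocks).
#'
#' @param model An [arirt_model()].
#' @param path Output path.
#' @param label Model label for the `model` column.
#' @return `path`, invisibly.
#' @export
write_parameter_csv <- function(model, path, label = "model") {
  bank <- model$bank
  items <- tibble::tibble(model = label, parameter = "item",
                          item = bank$item,
                          slope = bank$slope,
                          threshold = bank$threshold,
                          lag = NA_integer_, estimate = NA_real_)
  out <- items
  if (model$lags$n_coef > 0) {
    lab <- lag_coef_labels(model$lags)
    lag_est <- model$lag_coefficients
    lag_rows <- tibble::tibble(model = label, parameter = "lag",
                               item = NA_integer_, slope = NA_real_,
                               threshold = NA_real_,
                               lag = as.integer(sub(".*m=(\\d+).*", "\\1", lab)),
                               estimate = lag_est)
    out <- dplyr::bind_rows(items, lag_rows)
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a simulation scenario from a YAML file
#'
#' A scenario file names the generating model (either a packaged fixture via
#' `fixture:` or explicit `slopes` / `thresholds` / `lag` blocks), the
#' sample size, replicate count, test level, seed, and the nested pair of
#' lag structures to fit. Defaults (`alpha: 0.05`, `null: none`,
#' `alt: fixed lag-1`) are filled in and echoed back in the returned object
#' for provenance.
#'
#' @param path YAML file path.
#' @return A list with elements `generating_model`, `n_persons`,
#'   `n_replicates`, `alpha`, `seed`, `null_lags`, `alt_lags`, ready to pass
#'   to [run_simulation_study()] via `do.call`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) abort_input("Scenario file not found: %s", path)
  y <- yaml::read_yaml(path)
  need <- c("n_persons", "n_replicates")
  miss <- setdiff(need, names(y))
  if (length(miss)) abort_input("Scenario is missing field(s): %s",
                                paste(miss, collapse = ", "))
  model <- if (!is.null(y$fixture)) {
    spm_parameters(y$fixture)
  } else {
    if (is.null(y$slopes) || is.null(y$thresholds)) {
      abort_input("Scenario needs either `fixture` or `slopes` + `thresholds`.")
    }
    bank <- item_bank(as.numeric(y$slopes), as.numeric(y$thresholds))
    if (!is.null(y$lag)) {
      lg <- lag_structure(nrow(bank), y$lag$order %||% 1L,
                          y$lag$mode %||% "fixed")
      arirt_model(bank, lg, as.numeric(y$lag$coefficients))
    } else {
      arirt_model(bank)
    }
  }
  p <- n_items_of(model)
  parse_lags <- function(spec, default) {
    if (is.null(spec)) return(default)
    lag_structure(p, spec$order %||% 0L, spec$mode %||% "none")
  }
  list(
    generating_model = model,
    n_persons = as.integer(y$n_persons),
    n_replicates = as.integer(y$n_replicates),
    alpha = y$alpha %||% 0.05,
    seed = as.integer(y$seed %||% 1L),
    null_lags = parse_lags(y$fit_null, lag_structure(p, 0L, "none")),
    alt_lags = parse_lags(y$fit_alt, lag_structure(p, 1L, "fixed"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
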