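# Packaged reference parameters: published slope-intercept estimates for the
# 12-item SPM-LS progressive-matrices short form (499 adults), for the plain
# 2PL and the fixed lag-1 auto-regressive 2PL, plus the fixed lag effects of
# the lag-1 and lag-2 models. These are estimates read from the published
# analysis, not data; they drive worked examples and simulation defaults.

spm_fixture_names <- c("2pl", "ar1_2pl", "ar2_2pl")

#' Published SPM-LS item parameter table
#'
#' The slope-intercept item parameter estimates (and standard errors) of the
#' 2PL and AR1-2PL models for the 12-item SPM-LS progressive-matrices test,
#' as published. Note the threshold is a negated intercept on the logit
#' scale, not the classical IRT difficulty `b = threshold / slope`; use
#' [convert_parameters()] for the latter.
#'
#' @param model Optional filter: `"2pl"` or `"ar1_2pl"`.
#' @return A tibble with columns `model`, `item`, `slope`, `slope_se`,
#'   `threshold`, `threshold_se`.
#' @export
spm_parameter_table <- function(model = NULL) {
  path <- system.file("extdata", "spm_ls_item_parameters.csv", package = "arirt")
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(model)) {
    check_fixture_name(model, c("2pl", "ar1_2pl"))
    tab <- dplyr::filter(tab, .data$model == !!model)
  }
  tab
}

#' Published fixed lag-effect estimates
#'
#' Fixed lag coefficients (and standard errors) of the AR1-2PL (lag-1
#' effect 0.572) and AR2-2PL (lag-1 effect 0.667, lag-2 effect 0.370)
#' models for the SPM-LS.
#'
#' @param model Optional filter: `"ar1_2pl"` or `"ar2_2pl"`.
#' @return A tibble with columns `model`, `lag`, `estimate`, `se`.
#' @export
spm_lag_effects <- function(model = NULL) {
  path <- system.file("extdata", "spm_ls_lag_effects.csv", package = "arirt")
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(model)) {
    check_fixture_name(model, c("ar1_2pl", "ar2_2pl"))
    tab <- dplyr::filter(tab, .data$model == !!model)
  }
  tab
}

#' Load a published model as a ready-to-use arirt_model
#'
#' Assembles the packaged SPM-LS estimates into an [arirt_model()]:
#' `"2pl"` has no lag structure, `"ar1_2pl"` a fixed lag-1 coefficient of
#' 0.572, and `"ar2_2pl"` fixed lag-1/lag-2 coefficients 0.667 and 0.370
#' attached to the AR1-2PL item bank (the published analysis prints no
#' separate AR2 item bank, so this combination is a convenience for
#' simulation, not a published joint estimate).
#'
#' @param model One of `"2pl"`, `"ar1_2pl"`, `"ar2_2pl"`.
#' @return An [arirt_model()].
#' @examples
#' spm_parameters("ar1_2pl")
#' @export
spm_parameters <- function(model = c("2pl", "ar1_2pl", "ar2_2pl")) {
  check_fixture_name(model[1], spm_fixture_names)
  model <- model[1]
  bank_model <- if (model == "2pl") "2pl" else "ar1_2pl"
  tab <- spm_parameter_table(bank_model)
  bank <- item_bank(tab$slope, tab$threshold)
  if (model == "2pl") return(arirt_model(bank))
  lags <- spm_lag_effects(model)
  structure <- lag_structure(nrow(bank), max(lags$lag), "fixed")
  arirt_model(bank, structure, lags$estimate[order(lags$lag)])
}

check_fixture_name <- function(name, allowed) {
  if (!name %in% allowed) {
    abort_input("Unknown fixture \"%s\"; available: %s.",
                name, paste(allowed, collapse = ", "))
  }
  invisible(name)
}
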