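#!/usr/bin/env Rscript
# Optional real-data analysis of the SPM-LS progressive-matrices dataset
# (12 binary items, 499 adults). The dataset is public but NOT shipped with
# the package; download it and supply a persons x items 0/1 CSV (items in
# administration order).
#
# Usage: Rscript scripts/spm_ls_analysis.R <responses.csv> [out_dir]

suppressMessages({
  library(arirt)
  library(dplyr)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  stop("Usage: Rscript scripts/spm_ls_analysis.R <responses.csv> [out_dir]",
       call. = FALSE)
}
out_dir <- if (length(args) >= 2) args[2] else "results/spm_ls"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

responses <- read_response_matrix(args[1])
message(sprintf("Read %d persons x %d items (%d missing cells).",
                nrow(responses), ncol(responses),
                attr(responses, "n_missing")))
p <- ncol(responses)

fits <- list(
  `2pl` = fit_arirt(responses),
  ar1_fixed = fit_arirt(responses, order = 1),
  ar1_variable = fit_arirt(responses, lags = lag_structure(p, 1, "variable")),
  ar2_fixed = fit_arirt(responses, order = 2)
)

message("Model fit summary:")
fit_summary <- bind_rows(lapply(fits, glance), .id = "model")
print(fit_summary)

message("Nested comparisons:")
print(lr_test(fits$`2pl`, fits$ar1_fixed))
print(lr_test(fits$ar1_fixed, fits$ar1_variable))
print(lr_test(fits$ar1_fixed, fits$ar2_fixed))

message("Lag effects (fixed lag-1 model):")
print(tidy(fits$ar1_fixed) |> filter(parameter == "lag") |>
        mutate(odds_ratio = odds_ratio(estimate)))

message("Item-parameter comparison (2PL vs AR1-2PL):")
print(compare_item_parameters(fits$`2pl`$model$bank,
                              fits$ar1_fixed$model$bank))

message("Person-score comparison (AR1-2PL vs 2PL), BCa with 5000 resamples:")
s_ar1 <- eap_scores(fits$ar1_fixed)
s_2pl <- eap_scores(fits$`2pl`)
print(score_comparison(s_ar1, s_2pl, n_resamples = 5000, seed = 1))

for (nm in names(fits)) {
  write_fit_json(fits[[nm]], file.path(out_dir, paste0(nm, ".json")))
  write_parameter_csv(fits[[nm]]$model,
                      file.path(out_dir, paste0(nm, "_parameters.csv")),
                      label = nm)
}
readr::write_csv(bind_rows(ar1 = s_ar1, `2pl` = s_2pl, .id = "model"),
                 file.path(out_dir, "eap_scores.csv"))
message(sprintf("Artifacts written to %s/", out_dir))
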