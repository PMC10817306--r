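# File formats

## Response matrices (CSV / delimited text)

Persons are rows, items are columns; the column order IS the administration
order that defines lag terms. Cells are `0`, `1`, or a missing code
(default `NA` or empty). Read with `read_response_matrix()` (reports the
offending cell on any other token; rejects ragged rows), write with
`write_response_matrix()` (columns named `item_1 .. item_p`). An optional
person-identifier column can be named via `id_column` and is returned as an
attribute.

## Parameter tables (CSV)

`write_parameter_csv()` emits one row per item then one row per lag
coefficient, with columns:

    model, parameter ("item" | "lag"), item, slope, threshold, lag, estimate

The packaged reference tables use:

* `spm_ls_item_parameters.csv`: `model, item, slope, slope_se, threshold,
  threshold_se` (models `2pl`, `ar1_2pl`; threshold is a negated intercept,
  not the classical difficulty).
* `spm_ls_lag_effects.csv`: `model, lag, estimate, se` (models `ar1_2pl`,
  `ar2_2pl`).

## Fit serialization (JSON)

`write_fit_json()` / `read_fit_json()`: named `estimates` and `std_errors`,
the `lag_structure` block (`n_items`, `order`, `mode`, `terms`),
`log_likelihood`, `n_parameters`, `n_persons`, `n_items`, a `convergence`
block (`converged`, `n_iterations`, `max_abs_gradient`), and the fit
`options`.

## Simulation scenarios (YAML)

Read with `read_scenario()`. Required: `n_persons`, `n_replicates`. The
generating model is either `fixture:` (a packaged model name) or explicit
`slopes:` / `thresholds:` plus an optional `lag:` block (`order`, `mode`,
`coefficients`). Optional with defaults echoed back: `alpha` (.05), `seed`
(1), `fit_null` / `fit_alt` blocks (`order`, `mode`; defaults none vs fixed
lag-1). See `inst/extdata/scenario_null.yaml` and `scenario_ar1.yaml`.
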