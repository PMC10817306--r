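# Null-model simulation study: data generated from the published 2PL item
# parameters (no sequential dependency), N = 499 persons, 1000 replicates;
# the fitted pair is 2PL (null) vs fixed lag-1 AR1-2PL (alt), LRT at .05.
# Scale n_replicates down for quick runs.
fixture: 2pl
n_persons: 499
n_replicates: 1000
alpha: 0.05
seed: 1
fit_null:
  order: 0
  mode: none
fit_alt:
  order: 1
  mode: fixed
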