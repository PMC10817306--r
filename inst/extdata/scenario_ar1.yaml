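# Power / recovery study: data generated from the published AR1-2PL
# parameters (fixed lag-1 effect 0.572), N = 499 persons, 1000 replicates;
# same fitted pair and test as the null scenario.
fixture: ar1_2pl
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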