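# MMI model weights, BIC criterion, original baselines.
# Concentrated almost entirely on the linear Grant model (unambiguous
# anchor); the residual 0.01 assignment is an interpretation.
criterion: BIC
baseline_method: original
weights:
  EAR:
    GRANT_L: 0.97
    GRANT_LQ: 0.02
    UNSCEAR_L: 0.01
  ERR:
    GRANT_L: 0.99
    GRANT_LQ: 0.01
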