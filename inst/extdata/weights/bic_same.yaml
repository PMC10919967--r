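# MMI model weights, BIC criterion, same (common parametric) baseline.
# Dominated by BEIR VII; the small residual assignment is an
# interpretation of the typeset source.
criterion: BIC
baseline_method: same
weights:
  EAR:
    BEIR7: 1.0
  ERR:
    BEIR7: 0.95
    UNSCEAR_L: 0.04
    UNSCEAR_LQ: 0.01
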