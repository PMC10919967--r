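# MMI model weights, AIC criterion, same (common parametric) baseline.
# Unambiguous in the source: split between the two UNSCEAR forms.
criterion: AIC
baseline_method: same
weights:
  EAR:
    UNSCEAR_L: 0.73
    UNSCEAR_LQ: 0.27
  ERR:
    UNSCEAR_L: 0.73
    UNSCEAR_LQ: 0.27
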