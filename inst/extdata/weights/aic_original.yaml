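# MMI model weights, AIC criterion, original baselines.
# NOTE: the published table's cell-to-column alignment is not fully
# unambiguous; this file is one consistent sum-to-one interpretation and
# is deliberately editable configuration, not a hard-coded constant.
criterion: AIC
baseline_method: original
weights:
  EAR:
    BEIR7: 0.67
    GRANT_L: 0.09
    GRANT_LQ: 0.24
  ERR:
    BEIR7: 0.65
    GRANT_L: 0.08
    GRANT_LQ: 0.18
    PRESTON_L: 0.01
    INWORKS_L: 0.01
    INWORKS_LQ: 0.02
    UNSCEAR_L: 0.05
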