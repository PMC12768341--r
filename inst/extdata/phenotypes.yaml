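# Experimental bioenergetic phenotypes coded on the qualitative -3..+3 scale.
# Convention: statistically significant, visually large changes are coded +/-2
# (the minimal experimentally detectable grade); non-significant changes 0.
# resp_dpsi_* features are the membrane-potential response magnitude |1 - FC|
# to the inhibitor, so a blunted depolarization codes as a decrease.
tgad:
  codes:
    basal_ocr: 0
    leak_ocr: 0
    max_ocr: -2
  provenance: >-
    Transgenic Alzheimer's-model primary cortical neurons: unchanged basal and
    leak OCR, decreased maximal OCR.
park:
  codes:
    basal_ocr: 2
    max_ocr: 0
    atp_m: -2
  provenance: >-
    Parkin-knockout dopaminergic neurons: increased basal OCR, unchanged
    maximal OCR, reduced ATP content (mapped to mitochondrial ATP in the
    feature schema).
pink1:
  codes:
    basal_ocr: -2
    max_ocr: -2
    leak_ocr: 0
    resp_dpsi_antia: -2
    resp_dpsi_rot: 0
  provenance: >-
    Pink1-knockout primary cortical neurons: significant reductions in basal
    and maximal OCR, unchanged leak OCR, reduced membrane-potential
    sensitivity to antimycin A, unchanged response to rotenone.
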