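# Phenotype threshold bands, diplotype-level activity-score overrides for
# the non-additive diplotypes, acetylator haplotype classes and the fragment
# length used by the ambiguity rule.
bands:
  CYP2D6:
    - {label: PM, lo: 0.0, hi: 0.5, lo_open: false, hi_open: false}
    - {label: IM, lo: 0.5, hi: 1.25, lo_open: true, hi_open: true}
    - {label: NM, lo: 1.25, hi: 2.25, lo_open: false, hi_open: false}
    - {label: UM, lo: 2.25, hi: .inf, lo_open: true, hi_open: false}
  UGT1A1:
    - {label: PM, lo: 0.0, hi: 1.0, lo_open: false, hi_open: true}
    - {label: IM, lo: 1.0, hi: 2.0, lo_open: false, hi_open: true}
    - {label: NM, lo: 2.0, hi: .inf, lo_open: false, hi_open: false}
overrides:
  CYP2D6:
    "*2 x 2/*5": 1.0
    "*4/*41,*68": 0.5
  UGT1A1:
    "*36/*60": 2.125
    "*36/*37": 1.3
acetylator:
  slow: ["*5", "*6", "*7", "*14"]
  rapid: ["*4", "*12", "*13"]
ambiguity:
  fragment_length: 200
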