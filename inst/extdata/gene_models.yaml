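# Synthetic gene models for simulation. Reference sequences are generated
# deterministically from the per-gene seeds at catalog load time; they are
# not shipped. Coordinates are 1-based.
spacer: 500
flank: 300
junction_flank: 100
genes:
  NAT2:
    locus_length: 9936
    coordinate_frame: cDNA
    # position of cDNA coordinate c.1 within the locus window
    cds_offset: 2000
    seed: 101
  UGT1A1:
    locus_length: 6000
    coordinate_frame: genomic-window
    seed: 102
    repeat_locus:
      position: 3000        # first base of the first TA unit (reference)
      unit: TA
      ref_units: 6          # the reference (*1) carries six TA units
      anchor_left: GGACCTGCGCAG
      anchor_right: CGGCAGGCCAGG
  CYP2D6:
    locus_length: 4000
    coordinate_frame: genomic-window
    seed: 103
    paralog:
      name: CYP2D7
      length: 4000
      junction: 800         # hybrid switches from CYP2D6 to CYP2D7 after here
      seed: 104
    # depth windows are chosen so that hybrid copies contribute to neither:
    # the gene window lies downstream of the junction (absent from the
    # hybrid's CYP2D6 part), the paralog window upstream of it (absent from
    # the hybrid's CYP2D7 part).
    depth_window_gene: [1000, 2800]
    depth_window_paralog: [100, 700]
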