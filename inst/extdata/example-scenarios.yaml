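# Example capstress configuration: thin-cap morphology with one concentrated
# and one distributed crystal arrangement.
morphology:
  cap_thickness: 0.091
  lumen_area: 5.77
  core_arc: 84.65
  core_area: 2.22
  stenosis_severity: 0.7053
pressure: 14.6
scenarios:
  - name: control
  - name: shoulder_2um
    crystals:
      - location: shoulder
        length_um: 269.1
        thickness_um: 3.0
        expansion_um: 2
  - name: distributed_2um
    crystals:
      - location: shoulder
        expansion_um: 2
      - location: halfway
        expansion_um: 2
      - location: center
        expansion_um: 2
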