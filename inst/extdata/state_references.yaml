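# Default metastable-state reference centroids in the (d242, d244) plane,
# Angstrom.  Operational values consistent with the crystallographic
# conformers: the activated state's ~3.0 A interrogation contact, the
# quarantine state's ~3.6 A stacking distance, and the displaced apo loop.
- label: apo
  d242: 12.0
  d244: 10.0
- label: in242
  d242: 3.0
  d244: 8.0
- label: in244
  d242: 8.0
  d244: 3.5
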