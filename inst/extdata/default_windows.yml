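# Atmospheric gaseous-absorption windows excluded before training/mapping
# (closed intervals in nm; overlapping intervals are applied as a union).
windows:
  - {min: 535,  max: 550}
  - {min: 755,  max: 780}
  - {min: 755,  max: 775}
  - {min: 810,  max: 855}
  - {min: 885,  max: 970}
  - {min: 1015, max: 1050}
  - {min: 1080, max: 1165}
  - {min: 1225, max: 1285}
  - {min: 1330, max: 1490}
  - {min: 1685, max: 1700}
  - {min: 1725, max: 1750}
  - {min: 1780, max: 1960}
  - {min: 1990, max: 2030}
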