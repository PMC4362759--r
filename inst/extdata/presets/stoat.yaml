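# Stoat preset: wide-spaced tunnel-trap lines for a wide-ranging mustelid.
species: stoat
detection:
  g0: 0.045
  sigma: 641.0         # metres; 95% home-range radius 1570.45 m
layout:
  trap_spacing: 200
  line_spacing: 800
  traps_per_line: 12   # 12 x 7 = 84 trap sites over a 2200 x 4800 m block
  n_lines: 7
  buffer: 300
  buffered_area: 1472
density_range: [0.02, 0.12]
immigration: null
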