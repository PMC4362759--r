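# Brushtail possum preset: best-practice leg-hold/kill-trap grid.
species: possum
detection:
  g0: 0.05
  sigma: 63.0          # metres; 95% home-range radius 2.45*sigma = 154.35 m
layout:
  trap_spacing: 50     # m between traps along a line
  line_spacing: 100    # m between lines
  traps_per_line: 81   # 81 x 26 = 2106 trap sites over a 4000 x 2500 m block
  n_lines: 26
  buffer: 100          # untrapped margin, m
  buffered_area: 1140  # nominal placement area, ha
density_range: [0.5, 3.0]   # typical maintenance densities, animals/ha
immigration: null           # closed population
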