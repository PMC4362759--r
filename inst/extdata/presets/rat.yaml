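# Ship-rat preset: dense snap-trap grid; rats reinvade quickly, so an
# immigration block is provided (enable with immigration = TRUE).
species: rat
detection:
  g0: 0.03
  sigma: 32.0          # metres; 95% home-range radius 78.4 m
layout:
  trap_spacing: 25
  line_spacing: 100
  traps_per_line: 140  # 140 x 30 = 4200 trap sites over a 3475 x 2900 m block
  n_lines: 30
  buffer: 100
  buffered_area: 1148
density_range: [1.0, 11.0]
immigration:
  total: null          # null = equal to the initial population over the period
  zone_weights: [0.6, 0.3, 0.1]   # outer / middle / inner placement
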