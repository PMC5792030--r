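units: um
pivot_rl:
- 25.0
- 60.0
rl_bm_angle_deg: 37.25999999999999801
l_rl: 45.0
l_ohc: 72.5
ohc_tilt_deg: 18.19999999999999929
dc_anchor:
- 136.0
- 0.0
outer_pillar_foot:
- 38.0
- 0.0
inner_pillar_foot:
- 0.0
- 0.0
phi0: 1.19999999999999996
hensen_control_points:
- - 164.0
  - 0.0
- - 167.0
  - 30.5
- - 166.5
  - 77.0
- - 145.0
  - 104.0
- - 78.0
  - 102.0
- - 60.81533560064571731
  - 87.244480832145058
tracked_fractions:
  top: 0.55000000000000004
  side: 0.20000000000000001
n_nodes: 100
bm_axis:
- 1.0
- 0.0
ohc_apex: ~
ohc_base: ~
metadata:
  source: schematic digitization of a guinea-pig apical organ of Corti micrograph
    (20 um scale bar)
  scale_bar_um: 20.0
  digitization_ranges:
    l_rl:
    - 35.0
    - 55.0
    l_ohc:
    - 55.0
    - 90.0
    l_dc:
    - 30.0
    - 60.0
    l_hc:
    - 140.0
    - 210.0

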