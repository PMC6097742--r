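# Ten-case parametric patch-reconstruction study.
# Shared defaults; each case overrides what differs from Baseline.
vessel:
  inner_diameter_mm: 18
  wall_thickness_mm: 1
  stenosis_pct: 70
  stenosis_length_mm: 50
  total_length_mm: 100
incision:
  shape: straight
  cut_length_mm: 50
  helix_angle_deg: 0
  gap_mm: 16
patch_material: PTFE
stages:
  residual_mmHg: 5
  postop_mmHg: 25
flow:
  rate_lpm: 4
  density: 1060
  viscosity: 3.5e-3
mesh:
  edge_mm: 2.5
cases:
  - name: Baseline
  - name: Length_1
    incision: {shape: straight, cut_length_mm: 40, helix_angle_deg: 0, gap_mm: 16}
  - name: Length_2
    incision: {shape: straight, cut_length_mm: 60, helix_angle_deg: 0, gap_mm: 16}
  - name: Shape_1
    incision: {shape: oblique, cut_length_mm: 50, helix_angle_deg: 5, gap_mm: 16}
  - name: Shape_2
    incision: {shape: double, cut_length_mm: 50, helix_angle_deg: 0, gap_mm: 16}
  - name: Stenosis
    vessel: {inner_diameter_mm: 18, wall_thickness_mm: 1, stenosis_pct: 80,
             stenosis_length_mm: 50, total_length_mm: 100}
  - name: Material_1
    patch_material: human pericardium
  - name: Material_2
    patch_material: porcine xenopericardium
  - name: Material_3
    patch_material: Dacron
  - name: Pressure
    stages: {residual_mmHg: 5, postop_mmHg: 45}
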