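# Desk-scale vial phantom: a water body with three contrast vials.
# Usage: unetu simulate --spec example_phantom.yaml --out data/ --n 6
shape: [48, 64, 64]
voxel_size: 0.125
background:
  material: water
  concentration: 1.0
objects:
  - shape: cylinder
    center: [24.5, 32.5, 32.5]
    radii: [24, 27, 27]
    material: water
    concentration: 1.0
  - shape: cylinder
    center: [24.5, 32.5, 47]
    radii: [20, 5, 5]
    material: I
    concentration: 10.0
  - shape: cylinder
    center: [24.5, 45, 25]
    radii: [20, 5, 5]
    material: Gd
    concentration: 10.0
  - shape: cylinder
    center: [24.5, 20, 25]
    radii: [20, 5, 5]
    material: Ta
    concentration: 10.0
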