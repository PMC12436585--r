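# Example scenario configuration for rootflow.
# Annular-enlargement case: 23 mm native annulus receiving a 29 mm valve.
scenario: YAAE
profile: ci
label: yaae-example
seed: 1
geometry:
  annulus_diameter: 23
  sinus_bulge_radius: 4
  sinus_height: 20
  stj_diameter: 26
  aorta_diameter: 30
  lvot_length: 10
  aorta_length: 40
  # coronary ostium size/placement are modeling choices (no reference
  # values exist for the idealized root)
  coronary_diameter: 3
valve:
  implanted_internal_diameter: 29
waveform:
  heart_rate: 70
  stroke_volume: 73500
  systolic_fraction: 0.35
windkessel:
  R: 0.121
  C: 9.37
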