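# Trichromatic chlorophyll equations, 90% acetone, 1 cm path length.
# Concentrations in ug/mL from absorbances at 630, 647 and 664 nm.
medium: 90% acetone
path_length_cm: 1
chl_a:
  A664: 11.85
  A647: -1.54
  A630: -0.08
chl_c:
  A630: 24.52
  A647: -7.60
  A664: -1.67
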