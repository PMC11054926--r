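parameter,low,high,median
age_y,22,35,28.5
body_mass_kg,75,94,84.5
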