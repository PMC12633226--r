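feed:
  volume_ml: 360.0
  species: synthetic_default_species.csv
stages:
- membrane: 0.2 um
  mean_pore_diameter_nm: 185.0
  role: clarifier
  volume_reduction_factor: 10.0
  diavolumes: 0.0
  advance_stream: permeate
  collect_retentate: no
  fraction_label: 0.2 um
- membrane: 0.05 um
  mean_pore_diameter_nm: 50.0
  role: fractionating
  volume_reduction_factor: 10.0
  diavolumes: 9.0
  advance_stream: permeate
  collect_retentate: yes
  fraction_label: F1
- membrane: 500 kDa
  mean_pore_diameter_nm: 25.0
  role: fractionating
  volume_reduction_factor: 10.0
  diavolumes: 9.0
  advance_stream: permeate
  collect_retentate: yes
  fraction_label: F2
- membrane: 300 kDa
  mean_pore_diameter_nm: 15.0
  role: fractionating
  volume_reduction_factor: 10.0
  diavolumes: 9.0
  advance_stream: permeate
  collect_retentate: yes
  fraction_label: F3
- membrane: 100 kDa
  mean_pore_diameter_nm: 5.0
  role: terminal
  volume_reduction_factor: 10.0
  diavolumes: 9.0
  advance_stream: permeate
  collect_retentate: yes
  fraction_label: F4
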