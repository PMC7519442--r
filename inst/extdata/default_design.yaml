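# Default two-group rat tissue-distribution design:
# 8 tissues, 7 sacrifice times, 6 animals (3M/3F) per point per group.
tissues: [heart, liver, spleen, lung, kidney, uterus, ovary, testes]
sex_specific:
  heart: both
  liver: both
  spleen: both
  lung: both
  kidney: both
  uterus: female_only
  ovary: female_only
  testes: male_only
time_points_min: [10, 30, 90, 180, 360, 480, 720]
animals_per_point_per_group: 6
groups: [crude, salt_processed]
dose_volume_per_bw: 1.2      # mL per 200 g body weight, oral
homogenate_dilution_factor: 3  # tissue + two volumes iced saline
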