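bands:
- - 1.0
  - 6.0
- - 6.0
  - 12.0
- - 12.0
  - 26.0
- - 26.0
  - 52.0
- - 52.0
  - 104.0
- - 104.0
  - 183.0
include_sub_band_frequencies_in_first: yes
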