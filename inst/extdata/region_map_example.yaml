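# Ligand region map: three labelled interaction regions covering the
# heavy atoms of the steroid-like example ligand (see load_region_map()).
i:
  - C1
  - C2
  - C3
  - C4
  - C5
  - C6
  - O3
ii:
  - C7
  - C8
  - C9
  - C10
iii:
  - C11
  - C12
  - C13
  - C14
  - C15
  - C16
  - C17
  - O17
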