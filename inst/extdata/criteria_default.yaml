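animal_style:
- predicate: modal_support_5p
  comparator: ge
  threshold: 2.0
- predicate: modal_support_3p
  comparator: ge
  threshold: 2.0
- predicate: precision_5p
  comparator: ge
  threshold: 0.5
- predicate: precision_3p
  comparator: ge
  threshold: 0.5
- predicate: overhang_lower
  comparator: between
  threshold:
  - 1.0
  - 3.0
- predicate: overhang_upper
  comparator: between
  threshold:
  - 1.0
  - 3.0
- predicate: loop_len
  comparator: ge
  threshold: 8.0
- predicate: paired_fraction
  comparator: ge
  threshold: 0.6
- predicate: precursor_len
  comparator: le
  threshold: 150.0
plant_style:
- predicate: precursor_len
  comparator: le
  threshold: 300.0
- predicate: n_mismatch
  comparator: le
  threshold: 5.0
- predicate: asymmetric_bulge_nt
  comparator: le
  threshold: 3.0
- predicate: duplex_read_fraction
  comparator: ge
  threshold: 0.75
- predicate: overhang_lower
  comparator: between
  threshold:
  - 1.0
  - 3.0
- predicate: expressed_reps
  comparator: ge
  threshold: 2.0
combined:
- predicate: single_stem_loop
  comparator: is_true
  threshold: yes
- predicate: both_arms_mapped
  comparator: is_true
  threshold: yes
- predicate: precision_5p
  comparator: ge
  threshold: 0.5
- predicate: precision_3p
  comparator: ge
  threshold: 0.5
- predicate: duplex_read_fraction
  comparator: ge
  threshold: 0.5
- predicate: ncrna_overlap
  comparator: is_false
  threshold: no
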