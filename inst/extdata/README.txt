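synthetic_v1_reference_profiles.csv
  SYNTHETIC reference connectivity profiles used to exercise the
  connectivity-score machinery. These are NOT digitised experimental
  values: they are hand-written curves with the qualitative shape reported
  for mouse V1 functional connectivity (like-to-like short-range
  connectivity decreasing with orientation difference; direction profiles
  elevated at similar and opposite directions; a co-axial long-range bias
  absent in the co-orthogonal sector). Real reference profiles can be
  supplied in the same schema: columns `profile` (name), `bin_center_deg`
  (bin centre in degrees), `value` (connection probability).
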