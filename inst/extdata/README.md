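# Bundled small fixtures

- `spn3us_table1.tsv` — the published per-protein abundance table for the
  SPN3US virion (peak gel slice, precursor and processed molecular mass in
  kDa, MudPIT total spectral count). Used to recompute SC/M values.
- `spn3us_refs.tsv` — virion proteins of known per-particle copy number
  (major capsid 1560, tail sheath 264, portal 12), the calibration anchors
  for copy-number estimation.
- `spn3us_gel_windows_approx.tsv` — approximate slice mass windows
  reconstructed from the reported peak-slice assignments; a synthetic
  stand-in for the actual gel lane geometry, adequate for window-membership
  checks only.
- `spn3us_proteome_*.tsv` — protein identifier lists for the wild-type
  virion and the 218(am101) and 47(am1) amber-mutant particles, as reported
  in the published presence/absence comparison.
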