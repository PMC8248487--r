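# Externally sourced study tables

This directory is a drop-in point for the study tables that the package can
reproduce published headline numbers from, but which are not redistributable
with the package (cohort variant extracts, precomputed deleteriousness
scores, replicate stability scans, per-site evolutionary rates, and the
reference coding sequence). Nothing here is required for the package, its
synthetic workflow, or the bulk of its tests.

Expected files and formats (all tab-delimited with a header unless noted):

- `gnomad_variants.tsv`, `ukb_variants.tsv`, `topmed_variants.tsv` — one
  per cohort, CDS coordinates: `pos ref alt ac an af` (`ac`/`an` optional
  when `af` is present).
- `variant_scores.tsv` — per-variant scores for the merged set:
  `pos ref alt protein_pos cadd_phred primateai` (missing as empty).
- `site_rates.tsv` — per-residue normalized evolutionary rates:
  `pos score` (one row per precursor residue).
- `ddg_runs_glucagon.tsv` — replicate stability scan for the
  glucagon–receptor complex: `complex_id position ref alt run_index ddg`
  (positions are peptide-local).
- `reference_cds.fa` — FASTA with the canonical coding sequence (with
  terminal stop codon) of the precursor transcript.
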