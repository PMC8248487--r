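#!/usr/bin/env Rscript
# In-silico saturation of the coding sequence: substitute every alternative
# base at every CDS position, translate, and tabulate consequences. The
# observed cohort union is then a small subset of the theoretically
# possible missense space. Writes results/theoretical_enumeration.tsv.

suppressPackageStartupMessages(library(pepscape))

model <- transcript_model(
  read_fasta_seq("results/sim/cds.synthetic.fa", "dna"), "SYNTH_GCG")
enum <- enumerate_possible_missense(model)
write_enumeration(enum, "results/theoretical_enumeration.tsv")

message(sprintf("scanned %d codons (9 SNVs each = %d events)",
                model$n_codons, 9 * model$n_codons))
message(sprintf("missense events: %d; unique aa substitutions: %d; synonymous: %d; stop-gain: %d",
                enum$n_missense_events, enum$n_unique_aa_subs,
                enum$n_synonymous, enum$n_stop_gain))

merged <- read.delim("results/merged_variants.tsv")
message(sprintf("observed union covers %.1f%% of possible missense events",
                100 * nrow(merged) / enum$n_missense_events))
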