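#!/usr/bin/env Rscript
# Merge the per-cohort variant tables into the cross-cohort union under the
# max-AF rule, call merged-level singletons, and summarize the sharing/AF
# spectrum. Writes results/merged_variants.tsv and results/sharing_summary.tsv.

suppressPackageStartupMessages(library(pepscape))

simdir <- "results/sim"
cohorts <- sim_config(seed = 1)$cohorts
obs <- lapply(cohorts, function(co)
  read_cohort_variants(file.path(simdir, paste0(co$name, ".tsv")), "tsv", co))

merged <- merge_cohorts(obs)
model <- transcript_model(read_fasta_seq(file.path(simdir, "cds.synthetic.fa"),
                                         "dna"), "SYNTH_GCG")
annotated <- annotate_protein_consequence(merged, model)
write_merged_variants(merged, "results/merged_variants.tsv")

shr <- sharing_summary(merged)
write.table(shr, "results/sharing_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("union: %d unique missense variants over %d positions",
                nrow(merged), length(unique(annotated$protein_pos))))
message(sprintf("singletons: %d (%.0f%%); shared by all cohorts: %d (mean max AF %.1e)",
                sum(merged$is_singleton), 100 * mean(merged$is_singleton),
                ifelse(any(shr$sharing_class == 3),
                       shr$n[shr$sharing_class == 3], 0),
                ifelse(any(shr$sharing_class == 3),
                       shr$mean_max_af[shr$sharing_class == 3], NA)))
for (co in cohorts)
  message(sprintf("  %s singleton AF: 1/(2*%d) -> log10 %.1f", co$name,
                  co$n_individuals,
                  singleton_af(co$n_individuals)$log10_af))
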