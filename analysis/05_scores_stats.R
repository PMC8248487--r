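#!/usr/bin/env Rscript
# Deleteriousness-score statistics over the merged variants: per-peptide
# means of the CADD-like and PrimateAI-like tracks, their Pearson
# correlation, and per-variant contrasts against the glucagon peptide.
# Writes results/peptide_score_summary.tsv and results/score_contrasts.tsv.

suppressPackageStartupMessages(library(pepscape))

ann <- gcg_annotation()
scores <- read.delim("results/sim/scores.tsv")

r <- pearson(scores$cadd_phred, scores$primateai)
message(sprintf("mean CADD %.1f; Pearson(CADD, PrimateAI) = %.2f over %d variants",
                mean(scores$cadd_phred), r, nrow(scores)))

s <- peptide_score_summary(scores, ann)
write.table(s, "results/peptide_score_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

contr <- contrast_vs_reference(scores, ann, "primateai",
                               reference = "glucagon", n_boot = 5000,
                               seed = 20210617)
write.table(contr, "results/score_contrasts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- contr$peptide[!is.na(contr$p) & contr$p < 0.05]
message(sprintf("PrimateAI contrasts vs glucagon: %d/%d peptides at p < 0.05%s",
                length(sig), nrow(contr),
                if (length(sig)) paste0(" (", paste(sig, collapse = ", "), ")")
                else ""))
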