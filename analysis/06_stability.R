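#!/usr/bin/env Rscript
# Stability effects: aggregate the replicate ddG scan per substitution,
# classify into the ordered category ladder, list highly destabilizing
# hotspots, and score category recovery against the simulated truth.
# Writes results/stability_classification.tsv and results/hotspots.tsv.

suppressPackageStartupMessages(library(pepscape))

runs <- read_ddg_table("results/sim/ddg_runs.tsv")
rec <- stability_records(runs)
write.table(rec, "results/stability_classification.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

hs <- hotspot_list(rec)
write.table(hs, "results/hotspots.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("%d substitutions aggregated over %d runs each; %d hotspots (ddG > 1.84 kcal/mol)",
                nrow(rec), rec$n_runs[1], nrow(hs)))
if (nrow(hs))
  message("  hotspots: ", paste(hs$substitution, collapse = ", "))

truth <- read.delim("results/sim/ddg_truth.tsv")
key <- function(d) paste(d$position, d$ref, d$alt)
rec2 <- rec[match(key(truth), key(rec)), ]
message(sprintf("category recovery vs truth: %.0f%%",
                100 * mean(as.character(rec2$category) ==
                             truth$true_category)))
message(sprintf("mean |run-mean - true mean|: %.3f kcal/mol (run sd %.2f, n=%d)",
                mean(abs(rec2$mean_ddg - truth$true_mean)),
                sd(runs$ddg[runs$run_index == 1] -
                     truth$true_mean[match(key(runs[runs$run_index == 1, ]),
                                           key(truth))]),
                rec$n_runs[1]))
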