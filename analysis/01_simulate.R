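#!/usr/bin/env Rscript
# Generate the synthetic study inputs: three biobank-scale cohort variant
# tables over the fixture precursor transcript, an orthologue alignment
# with known site rates, correlated deleteriousness scores, and a
# replicate stability scan. Everything downstream (02-06) reads from
# results/sim/. Deterministic: one global seed fans out per stage.

suppressPackageStartupMessages(library(pepscape))

seed <- 20210617
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

ann <- gcg_annotation()
model <- synthetic_transcript()
cfg <- sim_config(seed = seed,
                  msa = list(n_seqs = 100, n_sites = nchar(ann$protein),
                             gamma_shape = 2, gamma_scale = 0.5))

sim <- simulate_cohorts(cfg, model)
write_simulated_cohorts(sim, out)
message(sprintf("simulated %d union variants across %d cohorts (%.0f%% singletons)",
                nrow(sim$truth), length(sim$cohorts),
                100 * mean(sim$truth$is_singleton)))

msa <- simulate_msa(cfg)
writeLines(as.vector(rbind(paste0(">", names(msa$msa)), msa$msa)),
           file.path(out, "orthologue_msa.fa"))
write.table(data.frame(pos = seq_along(msa$true_rates),
                       true_rate = msa$true_rates),
            file.path(out, "true_site_rates.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

scores <- simulate_scores(cfg, sim$truth)
write.table(scores, file.path(out, "scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ddg <- simulate_ddg(cfg, n_subs = 24, complex_id = "glucagon_gcgr")
write.table(ddg$runs_table, file.path(out, "ddg_runs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ddg$truth, file.path(out, "ddg_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

writeLines(c(">SYNTH_GCG_cds synthetic reverse-translated CDS", model$cds),
           file.path(out, "cds.synthetic.fa"))
message("inputs written to ", out)
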