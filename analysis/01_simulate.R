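#!/usr/bin/env Rscript
# Stage 1: state the synthetic world and write its datasets to disk.
#
# The world emulates a six-entity FFPE tumor cohort at desk scale: 40 samples
# per entity (the real cohort had 145-265 per entity, 1220 total), ~2000
# proteins spanning six orders of magnitude in abundance, 67% shared across
# entities, 3% exclusive to one, the rest enriched by 2 log2 units in one
# entity, abundance-dependent missingness, peptide loads with 50% CoV and 5%
# TIC measurement noise, an 8-point 16-1000 ng calibration series, and 40
# retention-time standards drifting 0.1 min per run.

library(panffpe)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
cfg <- synthetic_config(seed = 20260918)

tic <- generate_tic_dataset(cfg)
write_tic_records(tic$dilution_records, "results/data/dilution_tic.tsv")
write_tic_records(tic$sample_records, "results/data/sample_tic.tsv")
write.table(tic$samples, "results/data/sample_sheet.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tic$truth$loads, "results/data/true_loads.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

quant <- generate_quant_matrix(cfg)
write_quant_matrix(quant$matrix, "results/data/cohort")
write.table(quant$scores, "results/data/protein_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(quant$truth$proteins, "results/data/protein_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

rt <- generate_rt_runs(cfg, n_runs = 24)
write.table(rt, "results/data/rt_standards.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d samples x %d proteins (%.1f%% missing), %d score records, %d RT runs\n",
            ncol(quant$matrix$lfq), nrow(quant$matrix$lfq),
            100 * mean(is.na(quant$matrix$lfq)), nrow(quant$scores),
            length(unique(rt$run_id))))
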