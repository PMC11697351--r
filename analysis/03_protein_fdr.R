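#!/usr/bin/env Rscript
# Stage 3: protein-level FDR control. PEP = 1 - protein probability; the
# q-value of a protein is the mean PEP of all proteins with smaller or equal
# PEP; entries with q <= 0.01 are retained and contaminants removed.

library(panffpe)

scores <- read.delim("results/data/protein_scores.tsv")
truth <- read.delim("results/data/protein_truth.tsv")

sc <- compute_qvalues(scores)
sc <- filter_fdr(sc, alpha = 0.01)
kept <- sc[sc$retained, ]

cat(sprintf("%d of %d entries retained at 1%% FDR\n", nrow(kept), nrow(sc)))
cat(sprintf("realized false fraction among retained: %.3f (planted truth)\n",
            mean(kept$is_false)))

# contaminant removal against a small synthetic accession set
contaminants <- c("F00001", "F00002")  # stand-ins for e.g. keratins/trypsin
kept <- remove_contaminants(kept, contaminants)
cat(sprintf("%d contaminant group(s) removed, %d remain\n",
            attr(kept, "n_removed"), nrow(kept)))

write.table(sc, "results/protein_fdr.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(kept["group_id"], "results/retained_proteins.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
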