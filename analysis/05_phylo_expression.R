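#!/usr/bin/env Rscript
# Homolog phylogeny and expression analysis: NJ tree with bootstrap
# support from the aligned protein family, a percent-identity matrix,
# and 2^-ddCt quantification of hormone-feedback repression.

suppressMessages(library(mutseek))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

aln <- read_alignment_fasta("results/data/protein_family.faa")
tree <- bootstrap_support(aln, n_reps = 1000L, seed = 7L)
ape::write.tree(tree, "results/tables/family_nj.nwk")
sup <- suppressWarnings(as.numeric(tree$node.label))
message(sprintf("NJ tree of %d proteins; median bootstrap support %.0f%%",
                length(aln), median(sup, na.rm = TRUE)))

pid <- percent_identity(aln)
write.table(round(pid, 1), "results/tables/percent_identity.tsv",
            sep = "\t", quote = FALSE)

ct <- read.csv("results/data/qpcr_ct.csv")
fb <- feedback_report(ct, target = "target", reference = "ref_gene")
print(fb)
write.table(fb, "results/tables/feedback_expression.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
n_wt_rep <- sum(fb$status == "repressed" & fb$genotype == "WT")
n_mut_rep <- sum(fb$status == "repressed" & fb$genotype == "mutant")
message(sprintf(paste0("repression flagged in %d/%d WT organ contrasts ",
                       "and %d/%d mutant contrasts (alpha = 0.01)"),
                n_wt_rep, sum(fb$genotype == "WT"),
                n_mut_rep, sum(fb$genotype == "mutant")))
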