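#!/usr/bin/env Rscript
# The modified-MutMap scan: read the two VCFs written by 01_simulate.R,
# derive mutant-specific sites, compute 5-SNP sliding-window SNP
# indices, call the candidate region, annotate effects, run the filter
# cascade and screen survivors against the natural panel.

suppressMessages(library(mutseek))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1L)
mutant <- read_variants_vcf("results/data/mutant_pool.vcf")
wt <- read_variants_vcf("results/data/wt_parent.vcf")
genome_seqs <- read_genome_fasta("results/data/genome.fa")
genes <- read_gene_models_gff3("results/data/genes.gff3")

sites <- derive_mutant_specific_sites(mutant, wt)
message(nrow(mutant), " pool sites -> ", nrow(sites),
        " mutant-specific after removing shared parental variants")

windows <- sliding_window(sites, k = cfg$window_size)
regions <- call_candidate_region(windows, threshold = cfg$index_threshold)
write.table(windows, "results/tables/snp_index_windows.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_regions_bed(regions, "results/tables/candidate_regions.bed")
top <- regions[1L, ]
message(sprintf("candidate region: %s:%d-%d (peak window index %.3f)",
                top$chrom, top$start, top$end, top$peak_index))

png("results/figures/snp_index.png", width = 900, height = 1200)
plot_snp_index(windows, regions, threshold = cfg$index_threshold)
dev.off()

in_region <- sites[sites$chrom == top$chrom & sites$pos >= top$start &
                     sites$pos <= top$end, ]
effects <- annotate_effects(in_region, genes, genome_seqs)
casc <- filter_cascade(effects, top, min_index = cfg$min_index,
                       min_alt_depth = cfg$min_alt_depth)
casc$funnel$n[1] <- nrow(sites)
print(casc$funnel)
write.table(casc$funnel, "results/tables/filter_funnel.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

panel <- as.matrix(read.delim("results/data/panel_genotypes.tsv",
                              row.names = 1, check.names = FALSE))
surv <- casc$survivors
for (i in seq_len(nrow(surv))) {
  scr <- panel_uniqueness_screen(surv[i, ], panel)
  message(sprintf("survivor %s:%d %s>%s (%s, codon %d): %d panel carriers -> %s",
                  surv$chrom[i], surv$pos[i], surv$ref[i], surv$alt[i],
                  surv$effect[i], surv$codon_number[i], scr$n_carriers,
                  scr$verdict))
  surv$panel_verdict[i] <- scr$verdict
}
write.table(surv, "results/tables/cascade_survivors.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
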