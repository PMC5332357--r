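#!/usr/bin/env Rscript
# Generate one complete synthetic study data set with the default design
# (7 x 500 kb genome, 0.3 EMS mutations/kb, 42-plant recessive bulk at
# ~30x, 184-plant F2 mapping population, 412-line natural panel) and
# write every pipeline input to results/data/.

suppressMessages(library(mutseek))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1L)
print(cfg)

genome <- simulate_genome(cfg)
print(genome)
mutations <- simulate_ems_mutations(genome, cfg)
bulks <- simulate_bulk_depths(genome, mutations, cfg)
panel <- simulate_panel(cfg, bulks)
markers <- simulate_marker_table(cfg)
ct <- simulate_ct_table(cfg)
fam <- simulate_protein_family(n_taxa = 16L, n_sites = 400L, seed = cfg$seed)

write_genome_fasta(genome, file.path(out, "genome.fa"))
write_gff3(genome$genes, file.path(out, "genes.gff3"))
write_variants_vcf(bulks$mutant, file.path(out, "mutant_pool.vcf"),
                   sample_name = "mutant_pool")
write_variants_vcf(bulks$wt, file.path(out, "wt_parent.vcf"),
                   sample_name = "wt_parent")
write_variants_tsv(bulks$mutant, file.path(out, "mutant_pool.tsv"))
write_variants_tsv(bulks$wt, file.path(out, "wt_parent.tsv"))
write.table(data.frame(line = rownames(panel), panel, check.names = FALSE),
            file.path(out, "panel_genotypes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(markers, file.path(out, "f2_markers.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.csv(ct, file.path(out, "qpcr_ct.csv"), row.names = FALSE)
write_alignment_fasta(fam$alignment, file.path(out, "protein_family.faa"))
ape::write.tree(fam$tree, file.path(out, "protein_family_true.nwk"))

causal <- bulks$causal
message(sprintf("planted causal stop-gain: %s:%d %s>%s (gene %s)",
                causal$chrom, causal$pos, causal$ref, causal$alt,
                genome$causal_gene_id))
message(sprintf("%d EMS mutations (%.2f /kb); %d sites in the mutant pool",
                nrow(mutations),
                nrow(mutations) / (7 * 500),
                nrow(bulks$mutant)))
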