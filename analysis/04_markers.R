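#!/usr/bin/env Rscript
# Marker work around the mapped SNP: a dCAPS assay that genotypes the
# causal site by allele-specific restriction digestion, bulked-segregant
# marker screening, and an F2 linkage map with Kosambi distances.

suppressMessages(library(mutseek))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

genome_seqs <- read_genome_fasta("results/data/genome.fa")
surv <- read.delim("results/tables/cascade_survivors.tsv")
snp <- surv[1L, ]
message(sprintf("designing a digestion assay for %s:%d %s>%s",
                snp$chrom, snp$pos, snp$ref, snp$alt))

assay <- design_dcaps(genome_seqs, snp)
if (assay$found) {
  print(assay)
  sink("results/tables/dcaps_assay.txt")
  print(assay)
  sink()
} else {
  message("no assay found: ", assay$reason)
}

# bulked-segregant screen of the F2 marker panel (5 + 5 plants)
mk <- read.delim("results/data/f2_markers.tsv")
mutants <- mk$id[mk$phenotype == "mutant"]
normals <- mk$id[mk$phenotype == "normal"]
bsa <- bsa_screen(mk, wt_bulk = normals[1:5], mutant_bulk = mutants[1:5])
print(bsa)
write.table(bsa, "results/tables/bsa_screen.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# marker-trait linkage from mutant-class plants only, then grouping
linked <- setdiff(names(mk), c("id", "phenotype"))
trait_rows <- lapply(linked, function(m) {
  est <- estimate_r_trait(mk[[m]][mk$phenotype == "mutant"])
  data.frame(marker = m, r_hat = round(est$r_hat, 4),
             lod = round(est$lod, 2), cm = round(est$cm, 2))
})
trait_tab <- do.call(rbind, trait_rows)
print(trait_tab)
write.table(trait_tab, "results/tables/marker_trait_linkage.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

est <- pairwise_linkage(mk)
groups <- group_markers(est, lod_threshold = 4)
map_tab <- do.call(rbind, lapply(seq_along(groups), function(i) {
  data.frame(group = i, groups[[i]])
}))
print(map_tab)
write.table(map_tab, "results/tables/linkage_map.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
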