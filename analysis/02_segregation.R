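#!/usr/bin/env Rscript
# Mendelian segregation analysis: the two published F2 counts tested
# against 3:1, the simulated F2 population, and F3 progeny-test genotype
# inference.  Writes results/tables/segregation.tsv.

suppressMessages(library(mutseek))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

rows <- list()
add <- function(label, obs) {
  res <- chi_square_ratio_test(obs, c(3, 1))
  print(res)
  rows[[length(rows) + 1L]] <<- data.frame(
    population = label, normal = obs[1], mutant = obs[2],
    chi2 = round(res$chi2, 4), p_value = round(res$p_value, 4))
}

# reported F2 counts of the two crosses
add("C257 x WT F2 (448:130)", c(448, 130))
add("C257 x Gy14 F2 (1038:318)", c(1038, 318))

# the simulated 184-plant mapping population segregates the same way
cfg <- sim_config(seed = 1L)
mk <- simulate_marker_table(cfg)
add("simulated F2 (seed 1)",
    c(sum(mk$phenotype == "normal"), sum(mk$phenotype == "mutant")))

seg <- do.call(rbind, rows)
write.table(seg, "results/tables/segregation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# F3 progeny tests of 36 plants each: a zero-mutant family is called
# homozygous WT with misclassification probability (3/4)^36
fam <- progeny_test_batch(data.frame(
  family = c("F3-a", "F3-b", "F3-c"),
  normal = c(27, 36, 30), mutant = c(9, 0, 6)))
print(fam)
write.table(fam, "results/tables/progeny_tests.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("segregation consistent with a single recessive locus")
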