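test_that("configuration validation rejects impossible designs", {
  expect_error(sim_config(ems_rate = 0), "ems_rate")
  expect_error(sim_config(bulk_size = 0))
  expect_error(sim_config(causal_chrom = "chr99"), "chr99")
  expect_error(sim_config(causal_gene = 50L))
  expect_error(sim_config(causal_cds_len = 1000L))   # not a codon multiple
})

test_that("synthetic genomes satisfy their structural invariants", {
  cfg <- tiny_config(seed = 14)
  genome <- simulate_genome(cfg)
  expect_equal(length(genome$chromosomes), 2L)
  expect_true(all(nchar(genome$chromosomes) == cfg$chrom_length_bp))
  for (g in genome$genes) {
    expect_true(g$start >= 1 &&
                  g$end <= nchar(genome$chromosomes[[g$chrom]]))
    expect_true(!is.unsorted(g$exons$start))
    cds_len <- sum(g$cds$end - g$cds$start + 1L)
    expect_equal(cds_len %% 3L, 0L)
    cds <- mutseek:::spliced_cds(genome, g)
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, cds_len - 2, cds_len) %in%
                  c("TAA", "TAG", "TGA"))
    # no internal stop codon
    expect_equal(nchar(translate_cds(cds)), cds_len / 3 - 1)
  }
  causal <- genome$genes[[genome$causal_gene_id]]
  expect_equal(sum(causal$cds$end - causal$cds$start + 1L), 1392L)
  expect_equal(nrow(causal$exons), cfg$causal_exons)
})

test_that("generators are bit-reproducible and stage-independent", {
  cfg <- tiny_config(seed = 99)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1$chromosomes, g2$chromosomes)
  m1 <- simulate_ems_mutations(g1, cfg)
  m2 <- simulate_ems_mutations(g2, cfg)
  expect_identical(m1, m2)
  # a different panel size must not perturb the mutation stage
  cfg_b <- tiny_config(seed = 99, n_panel = 7L)
  expect_identical(simulate_ems_mutations(g1, cfg_b), m1)
  b1 <- simulate_bulk_depths(g1, m1, cfg)
  b2 <- simulate_bulk_depths(g1, m1, cfg)
  expect_identical(b1$mutant, b2$mutant)
})

test_that("EMS mutations are transitions at the configured density", {
  cfg <- tiny_config(seed = 3)   # 200 kb genome, 0.3 /kb -> lambda ~ 60
  genome <- simulate_genome(cfg)
  muts <- simulate_ems_mutations(genome, cfg)
  expect_true(all(paste(muts$ref, muts$alt) %in% c("G A", "C T")))
  expect_false(any(duplicated(paste(muts$chrom, muts$pos))))
  lambda <- 0.3 * 200
  expect_lt(abs(nrow(muts) - lambda), 3 * sqrt(lambda) + 1)
  # every recorded ref matches the genome base
  idx <- sample(nrow(muts), 25)
  for (i in idx) {
    expect_equal(substr(genome$chromosomes[[muts$chrom[i]]],
                        muts$pos[i], muts$pos[i]), muts$ref[i])
  }
})

test_that("mutation counts follow the Poisson law over many seeds", {
  counts <- integer(60)
  for (s in seq_along(counts)) {
    cfg <- sim_config(seed = s, n_chromosomes = 1L,
                      chrom_length_bp = 60000L, genes_per_chromosome = 1L,
                      causal_chrom = "chr1", causal_gene = 1L)
    genome <- simulate_genome(cfg)
    counts[s] <- nrow(simulate_ems_mutations(genome, cfg))
  }
  # Poisson(rate x kb) random mutations plus the planted causal site
  lambda <- 0.3 * 60 + 1
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 60))
  disp <- var(counts) / mean(counts)
  expect_gt(disp, 0.55)
  expect_lt(disp, 1.6)
})

test_that("the planted causal SNP is a unique stop-gain in its gene", {
  cfg <- tiny_config(seed = 21)
  genome <- simulate_genome(cfg)
  muts <- simulate_ems_mutations(genome, cfg)
  causal <- muts[muts$is_causal, ]
  expect_equal(nrow(causal), 1L)
  eff <- annotate_effect(causal$chrom, causal$pos, causal$ref,
                         causal$alt, genome$genes, genome)
  expect_equal(eff$effect, "stop_gained")
  expect_equal(eff$gene_id, genome$causal_gene_id)
  expect_equal(eff$codon_number, 157L)
  # no other mutation falls in the causal gene's CDS
  g <- genome$genes[[genome$causal_gene_id]]
  others <- muts[!muts$is_causal & muts$chrom == g$chrom, ]
  in_cds <- vapply(others$pos, function(p)
    any(p >= g$cds$start & p <= g$cds$end), logical(1))
  expect_false(any(in_cds))
})

test_that("a near-zero EMS rate leaves only the planted causal SNP", {
  cfg <- tiny_config(seed = 50, ems_rate = 1e-9)
  genome <- simulate_genome(cfg)
  muts <- simulate_ems_mutations(genome, cfg)
  expect_equal(nrow(muts), 1L)
  expect_true(muts$is_causal)
})

test_that("a gene with no possible stop-gain raises a diagnostic", {
  # codons starting with A or G can never mutate into a stop via
  # G->A / C->T (stops all start with T)
  cds <- paste(c("ATG", rep("AAA", 48), "TAA"), collapse = "")
  mg <- manual_genome(cds)
  expect_error(mutseek:::plant_stop_gain(mg$genome, mg$gene),
               "no codon")
})

test_that("bulk allele depths encode linkage to the causal locus", {
  cfg <- tiny_config(seed = 17)
  genome <- simulate_genome(cfg)
  muts <- simulate_ems_mutations(genome, cfg)
  bulks <- simulate_bulk_depths(genome, muts, cfg)
  mt <- bulks$mutant
  expect_true(all(mt$ref_depth + mt$alt_depth > 0))
  causal <- bulks$causal
  expect_equal(causal$snp_index, 1)
  expect_equal(causal$ref_depth, 0L)
  # unlinked chromosome: mean index near 0.5, pooled over resampled
  # bulks so the Monte-Carlo error is well below the tolerance
  ems_keys <- site_key(muts$chrom, muts$pos)
  unl_idx <- unlist(lapply(1:10, function(s) {
    b <- simulate_bulk_depths(genome, muts,
                              tiny_config(seed = s + 100))
    m <- b$mutant
    m$snp_index[m$chrom != causal$chrom &
                  site_key(m$chrom, m$pos) %in% ems_keys]
  }))
  expect_gt(length(unl_idx), 200L)
  expect_equal(mean(unl_idx), 0.5, tolerance = 0.02)
  # linked sites decay with distance on the causal chromosome
  ems_same <- mt[mt$chrom == causal$chrom & mt$alt_depth > 0 &
                   site_key(mt$chrom, mt$pos) %in%
                     site_key(muts$chrom, muts$pos), ]
  d <- abs(ems_same$pos - causal$pos)
  expect_lt(cor(d, ems_same$snp_index), -0.3)
  # WT parent carries only reference alleles at EMS sites
  wt_ems <- bulks$wt[site_key(bulks$wt$chrom, bulks$wt$pos) %in%
                       site_key(muts$chrom, muts$pos), ]
  expect_true(all(wt_ems$alt_depth == 0))
})

test_that("zero-depth sites are dropped from the variant tables", {
  cfg <- tiny_config(seed = 12, mean_depth = 1)
  genome <- simulate_genome(cfg)
  muts <- simulate_ems_mutations(genome, cfg)
  bulks <- suppressMessages(simulate_bulk_depths(genome, muts, cfg))
  expect_true(all(bulks$mutant$ref_depth + bulks$mutant$alt_depth > 0))
  expect_lt(nrow(bulks$mutant), nrow(muts) + cfg$n_background)
})

test_that("F2 trait segregation is Mendelian 3:1", {
  cfg <- sim_config(seed = 23, n_f2 = 578L)
  mk <- simulate_marker_table(cfg)
  n_mut <- sum(mk$phenotype == "mutant")
  expect_lt(abs(n_mut - 578 * 0.25), 3 * sqrt(578 * 0.25 * 0.75))
  res <- chi_square_ratio_test(c(sum(mk$phenotype == "normal"), n_mut))
  expect_gt(res$p_value, 0.001)
})

test_that("a 0 cM marker predicts phenotype; unlinked markers do not", {
  cfg <- sim_config(seed = 31, n_f2 = 150L)
  map <- data.frame(marker = c("at0", "far"), group = c(1L, 2L),
                    cm = c(0, 0))
  mk <- simulate_marker_table(cfg, map)
  expect_true(all((mk$at0 == "B") == (mk$phenotype == "mutant")))
  # unlinked marker: association no more often than chance
  sig <- 0L
  for (s in 1:25) {
    m2 <- simulate_marker_table(sim_config(seed = s, n_f2 = 100L), map)
    p <- suppressWarnings(
      stats::chisq.test(table(m2$far, m2$phenotype))$p.value)
    sig <- sig + (p < 0.05)
  }
  expect_lte(sig, 5L)
  expect_error(simulate_marker_table(cfg,
                                     data.frame(marker = "m", group = 1,
                                                cm = NA)), "finite")
})

test_that("the natural panel is monomorphic wild type at EMS sites", {
  cfg <- tiny_config(seed = 2, n_panel = 412L)
  genome <- simulate_genome(cfg)
  muts <- simulate_ems_mutations(genome, cfg)
  bulks <- simulate_bulk_depths(genome, muts, cfg)
  panel <- simulate_panel(cfg, bulks)
  expect_equal(nrow(panel), 412L)
  causal_key <- site_key(bulks$causal$chrom, bulks$causal$pos)
  expect_true(all(panel[, causal_key] == 0L))
  ems_keys <- intersect(site_key(muts$chrom, muts$pos), colnames(panel))
  expect_true(all(panel[, ems_keys] == 0L))
  # background variants do segregate
  bg_keys <- setdiff(colnames(panel), ems_keys)
  expect_gt(mean(panel[, bg_keys] > 0), 0.2)
  # injected carrier is visible to the uniqueness screen
  panel2 <- simulate_panel(cfg, bulks, inject_carriers = 1L)
  scr <- panel_uniqueness_screen(bulks$causal, panel2)
  expect_equal(scr$n_carriers, 1)
  expect_equal(scr$verdict, "not_unique")
  # boundary: a single-line panel
  cfg1 <- tiny_config(seed = 2, n_panel = 1L)
  expect_equal(nrow(simulate_panel(cfg1, bulks)), 1L)
})

test_that("Ct tables have the replicate structure of the assay design", {
  cfg <- tiny_config(seed = 44)
  tab <- simulate_ct_table(cfg, organs = c("root", "leaf"))
  expect_true(all(tab$ct > 0))
  counts <- table(tab$sample, tab$condition, tab$gene)
  expect_true(all(counts == 9L))   # 3 bio x 3 tech
  expect_equal(sort(unique(tab$condition)),
               sort(c("WT:mock", "WT:BL", "mutant:mock", "mutant:BL")))
})
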