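test_that("a G-to-A change at CDS position 470 of a TGG codon is a stop", {
  # codon 157 spans CDS positions 469-471; make it TGG and hit the middle G
  cds <- random_test_cds(464, seed = 9)
  substr(cds, 469, 471) <- "TGG"
  for (strand in c("+", "-")) {
    mg <- manual_genome(cds, strand = strand,
                        seg_len = c(150L, 400L, 842L))
    gpos <- mutseek:::cds_to_genomic(mg$gene, 470L)
    ref <- substr(mg$genome$chromosomes[["chrT"]], gpos, gpos)
    alt <- if (strand == "+") "A" else "T"
    expect_equal(ref, if (strand == "+") "G" else "C")
    eff <- annotate_effect("chrT", gpos, ref, alt, mg$genome$genes,
                           mg$genome)
    expect_equal(eff$cds_pos, 470L)
    expect_equal(eff$codon_number, 157L)
    expect_equal(eff$ref_codon, "TGG")
    expect_equal(eff$alt_codon, "TAG")
    expect_equal(eff$effect, "stop_gained")
  }
})

test_that("wobble-position transitions are synonymous", {
  # ATG GGG <29 sense codons> <stop>
  cds <- paste0("ATG", "GGG",
                substr(random_test_cds(31, seed = 3), 4, 31 * 3))
  mg <- manual_genome(cds, strand = "+", seg_len = nchar(cds))
  gpos <- mutseek:::cds_to_genomic(mg$gene, 6L)
  eff <- annotate_effect("chrT", gpos, "G", "A", mg$genome$genes,
                         mg$genome)
  expect_equal(eff$codon_number, 2L)
  expect_equal(eff$ref_codon, "GGG")
  expect_equal(eff$alt_codon, "GGA")
  expect_equal(eff$effect, "synonymous")
})

test_that("region labels cover intergenic, intronic and coding sites", {
  cds <- random_test_cds(100, seed = 5)
  mg <- manual_genome(cds, seg_len = c(100L, 200L), intron_len = 80L)
  g <- mg$gene
  eff_inter <- annotate_effect(
    "chrT", 10L, substr(mg$genome$chromosomes[["chrT"]], 10, 10), "A",
    mg$genome$genes, mg$genome)
  expect_equal(eff_inter$region, "intergenic")
  intron_pos <- g$exons$end[1] + 10L
  eff_intron <- annotate_effect(
    "chrT", intron_pos,
    substr(mg$genome$chromosomes[["chrT"]], intron_pos, intron_pos), "A",
    mg$genome$genes, mg$genome)
  expect_equal(eff_intron$region, "intronic")
  expect_true(is.na(eff_intron$codon_number))
})

test_that("reference mismatches and out-of-bounds sites are errors", {
  cds <- random_test_cds(50, seed = 6)
  mg <- manual_genome(cds)
  seq1 <- mg$genome$chromosomes[["chrT"]]
  wrong <- setdiff(c("A", "C", "G", "T"), substr(seq1, 600, 600))[1]
  expect_error(annotate_effect("chrT", 600L, wrong, "A",
                               mg$genome$genes, mg$genome),
               "reference mismatch")
  expect_error(annotate_effect("chrT", nchar(seq1) + 10L, "A", "G",
                               mg$genome$genes, mg$genome), "outside")
  expect_error(annotate_effect("chrZ", 5L, "A", "G",
                               mg$genome$genes, mg$genome),
               "not in genome")
})

test_that("a gene whose CDS length breaks frame is reported by name", {
  expect_error(gene_model("bad", "chrT", "+",
                          data.frame(start = 1L, end = 10L)),
               "bad.*not a multiple of 3")
})

test_that("annotation agrees with a full-protein translation oracle", {
  # random multi-exon genes on both strands, random substitutions
  set.seed(31)
  n_checked <- 0L
  for (rep in 1:12) {
    n_codons <- sample(40:120, 1)
    cds <- random_test_cds(n_codons)
    k <- sample(1:3, 1)
    seg <- mutseek:::split_lengths(nchar(cds), k, min_part = 12L)
    strand <- sample(c("+", "-"), 1)
    mg <- manual_genome(cds, strand = strand, seg_len = seg,
                        intron_len = 60L, seed = sample.int(1e6, 1))
    g <- mg$gene
    for (i in 1:40) {
      pos <- sample(g$start:g$end, 1)
      ref <- substr(mg$genome$chromosomes[["chrT"]], pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      eff <- annotate_effect("chrT", pos, ref, alt, mg$genome$genes,
                             mg$genome)
      orc <- oracle_effect(mg$genome, g, pos, alt)
      expect_equal(eff$region, orc$region)
      if (orc$region == "coding") {
        expect_equal(eff$effect, orc$effect)
        if (!is.na(orc$codon_number)) {
          expect_equal(eff$codon_number, orc$codon_number)
          expect_equal(eff$alt_aa, orc$alt_aa)
        }
        expect_equal(eff$codon_number,
                     as.integer(ceiling(eff$cds_pos / 3)))
      }
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 480L)
})

test_that("translation stops at the first stop and counts residues", {
  expect_equal(translate_cds("ATGTAA"), "M")
  cds1392 <- random_test_cds(464, seed = 12)
  expect_equal(nchar(cds1392), 1392L)
  expect_equal(nchar(translate_cds(cds1392)), 463L)
  # premature stop at codon 157 of 464 truncates to 156 residues
  trunc <- cds1392
  substr(trunc, 469, 471) <- "TAG"
  expect_equal(nchar(translate_cds(trunc)), 156L)
  expect_equal(nchar(translate_cds(trunc)) / 463, 0.3369, tolerance = 1e-3)
  expect_error(translate_cds("ATGN_A"), "non-ACGT")
  expect_error(translate_cds("ATGA"), "multiple of 3")
})

test_that("the filter cascade funnels in fixed order with tallies", {
  calls <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    pos = c(100L, 200L, 300L, 400L, 100L),
    region = c("coding", "coding", "coding", "intronic", "coding"),
    effect = c("missense", "synonymous", "stop_gained", NA, "missense"),
    snp_index = c(1, 1, 0.6, 1, 1),
    alt_depth = c(30L, 30L, 18L, 30L, 30L),
    stringsAsFactors = FALSE)
  region <- data.frame(chrom = "chr1", start = 50L, end = 500L)
  out <- filter_cascade(calls, region)
  expect_equal(out$funnel$n, c(5L, 4L, 3L, 2L, 1L))
  expect_equal(out$survivors$pos, 100L)
  # strict equality rule drops nothing extra here but is available
  strict <- filter_cascade(calls, region, strict = TRUE)
  expect_equal(strict$funnel$n[5], 1L)
  # all-synonymous input dies at stage 3
  syn <- transform(calls, effect = "synonymous")
  expect_equal(filter_cascade(syn, region)$funnel$n[4], 0L)
  # region covering nothing dies at stage 1
  far <- data.frame(chrom = "chr9", start = 1L, end = 2L)
  expect_equal(filter_cascade(calls, far)$funnel$n[2], 0L)
})

test_that("panel screen counts carriers and errors on bad input", {
  panel <- matrix(0L, nrow = 5, ncol = 2,
                  dimnames = list(NULL, c("chr1:100", "chr1:200")))
  site <- list(chrom = "chr1", pos = 100L)
  res <- panel_uniqueness_screen(site, panel)
  expect_equal(res$n_carriers, 0)
  expect_equal(res$verdict, "unique")
  panel[3, "chr1:100"] <- 1L
  res2 <- panel_uniqueness_screen(site, panel)
  expect_equal(res2$n_carriers, 1)
  expect_equal(res2$verdict, "not_unique")
  expect_error(panel_uniqueness_screen(list(chrom = "chr1", pos = 999L),
                                       panel), "absent")
  expect_error(panel_uniqueness_screen(site, panel[0, , drop = FALSE]),
               "empty")
})
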