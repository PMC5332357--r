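#' Simulation configuration for a bulked-segregant mutant study
#'
#' Bundles every tunable of the synthetic-data generator.  Defaults emulate
#' the design of an EMS dwarf-mutant study at desk scale: a 7-chromosome
#' genome, an EMS load of 0.3 mutations per kb, a bulk of 42 homozygous
#' recessive F2 plants resequenced to ~30x, one planted exonic stop-gain
#' causal SNP, an F2 mapping population of 184 plants and a 412-line
#' natural panel monomorphic for the wild-type allele.
#'
#' @param seed master seed; every stage derives its own seed from it via
#'   [stage_seed()].
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp length of each chromosome in bp.  The default
#'   500 kb keeps full pipeline runs in the low seconds while preserving
#'   multi-chromosome structure.
#' @param genes_per_chromosome gene models per chromosome, evenly spaced.
#' @param ems_rate expected EMS mutations per kb of genome (G:C -> A:T
#'   transitions).
#' @param causal_chrom chromosome carrying the planted causal gene.
#' @param causal_gene index (on `causal_chrom`) of the gene receiving the
#'   planted stop-gain mutation.
#' @param causal_cds_len coding length of the causal gene in bp (default
#'   1392, i.e. a 463-residue protein).
#' @param causal_exons exon count of the causal gene (default 9).
#' @param bulk_size number of homozygous-recessive plants pooled in the
#'   mutant bulk.
#' @param mean_depth mean sequencing depth per site (Poisson).
#' @param n_f2 F2 mapping-population size for marker tables.
#' @param n_panel natural-panel size for the uniqueness screen.
#' @param cm_per_mb genetic map rate in cM/Mb.  The default 200 gives each
#'   500-kb chromosome a realistic genetic length of 100 cM; see the
#'   methods vignette for why genetic length, not the per-bp rate, is the
#'   quantity preserved at reduced physical scale.
#' @param n_background shared (non-EMS) parental variants present in both
#'   the mutant pool and the wild-type parent; these emulate residual
#'   natural variation against the public reference and must be removed by
#'   the mutant-specific site derivation.
#' @param window_size SNPs per sliding window.
#' @param index_threshold mean SNP-index threshold for candidate regions.
#' @param min_index,min_alt_depth operational "SNP index = 1" rule: a site
#'   counts as homozygous in the pool when `snp_index >= min_index` and
#'   `alt_depth >= min_alt_depth`.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 7L,
                       chrom_length_bp = 500000L,
                       genes_per_chromosome = 6L,
                       ems_rate = 0.3,
                       causal_chrom = "chr5",
                       causal_gene = 3L,
                       causal_cds_len = 1392L,
                       causal_exons = 9L,
                       bulk_size = 42L,
                       mean_depth = 30,
                       n_f2 = 184L,
                       n_panel = 412L,
                       cm_per_mb = 200,
                       n_background = 100L,
                       window_size = 5L,
                       index_threshold = 0.9,
                       min_index = 0.95,
                       min_alt_depth = 10L) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.integer(chrom_length_bp),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              ems_rate = ems_rate,
              causal_chrom = causal_chrom,
              causal_gene = as.integer(causal_gene),
              causal_cds_len = as.integer(causal_cds_len),
              causal_exons = as.integer(causal_exons),
              bulk_size = as.integer(bulk_size),
              mean_depth = mean_depth,
              n_f2 = as.integer(n_f2),
              n_panel = as.integer(n_panel),
              cm_per_mb = cm_per_mb,
              n_background = as.integer(n_background),
              window_size = as.integer(window_size),
              index_threshold = index_threshold,
              min_index = min_index,
              min_alt_depth = as.integer(min_alt_depth))
  stopifnot(cfg$ems_rate > 0,
            cfg$bulk_size >= 1L,
            cfg$n_chromosomes >= 1L,
            cfg$chrom_length_bp >= 1000L,
            cfg$genes_per_chromosome >= 1L,
            cfg$causal_cds_len %% 3L == 0L,
            cfg$mean_depth > 0,
            cfg$n_f2 >= 1L,
            cfg$n_panel >= 1L,
            cfg$cm_per_mb > 0,
            cfg$window_size >= 1L,
            cfg$causal_gene >= 1L,
            cfg$causal_gene <= cfg$genes_per_chromosome)
  chrom_names <- paste0("chr", seq_len(cfg$n_chromosomes))
  if (!cfg$causal_chrom %in% chrom_names) {
    stop("causal_chrom '", cfg$causal_chrom, "' is not one of ",
         paste(chrom_names, collapse = ", "))
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Bulked-segregant simulation configuration\n")
  cat(sprintf("  genome: %d chromosomes x %d kb, %d genes each\n",
              x$n_chromosomes, x$chrom_length_bp %/% 1000L,
              x$genes_per_chromosome))
  cat(sprintf("  EMS rate %.2f /kb; causal stop-gain in gene %d on %s\n",
              x$ems_rate, x$causal_gene, x$causal_chrom))
  cat(sprintf("  bulk %d plants @ %.0fx; F2 n=%d; panel n=%d; %.0f cM/Mb\n",
              x$bulk_size, x$mean_depth, x$n_f2, x$n_panel, x$cm_per_mb))
  invisible(x)
}
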