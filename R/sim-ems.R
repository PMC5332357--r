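# Positions of G/C bases on a chromosome (EMS alkylates guanine; the
# canonical spectrum is G:C -> A:T, seen on the top strand as G->A or C->T).
gc_positions <- function(seq) {
  m <- gregexpr("[GC]", seq)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# Find CDS positions in `gene` where a G->A or C->T top-strand change
# creates a stop codon; returns data.frame(cds_pos, pos, ref, alt).
stop_gain_candidates <- function(genome, gene) {
  cds <- spliced_cds(genome, gene)
  n_codons <- nchar(cds) %/% 3L
  out <- list()
  for (codon_i in seq_len(n_codons - 1L)) {     # skip the terminal stop
    start <- 3L * (codon_i - 1L) + 1L
    codon <- substr(cds, start, start + 2L)
    if (translate_codon(codon) == "*") next
    for (within in 1L:3L) {
      base <- substr(codon, within, within)
      # transitions on the coding strand: G->A, C->T
      alt_coding <- switch(base, G = "A", C = "T", NULL)
      if (is.null(alt_coding)) next
      alt_codon <- codon
      substr(alt_codon, within, within) <- alt_coding
      if (translate_codon(alt_codon) != "*") next
      cds_pos <- start + within - 1L
      gpos <- cds_to_genomic(gene, cds_pos)
      ref <- genome_base(genome, gene$chrom, gpos)
      alt <- if (gene$strand == "+") alt_coding else
        complement_base(alt_coding)
      out[[length(out) + 1L]] <- data.frame(
        cds_pos = cds_pos, pos = gpos, ref = ref, alt = alt,
        codon_number = codon_i, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

# Pick the planted causal stop-gain site in the designated gene.  Prefers
# the engineered TGG codon at position 157 (middle-G transition -> TAG);
# otherwise the candidate closest to one third of the CDS.
plant_stop_gain <- function(genome, gene) {
  cand <- stop_gain_candidates(genome, gene)
  if (is.null(cand)) {
    stop("gene ", gene$gene_id, " has no codon whose G->A/C->T change ",
         "yields a stop codon; cannot plant a causal stop-gain")
  }
  pref <- cand[cand$codon_number == 157L & cand$cds_pos %% 3L == 2L, ,
               drop = FALSE]
  if (nrow(pref) > 0L) return(pref[1L, ])
  third <- nchar(spliced_cds(genome, gene)) / 3
  cand[which.min(abs(cand$cds_pos - third)), ]
}

#' Simulate EMS-induced mutations over a genome
#'
#' Draws a Poisson(`ems_rate` x genome kb) number of G:C -> A:T transition
#' mutations at unique G/C positions, plus exactly one planted causal
#' stop-gain SNP in the designated gene's CDS.  The designated gene's CDS
#' carries no other mutation (the emulated mutant line has a single lesion
#' in its causal gene), so random draws landing there are resampled.
#'
#' @param genome a [simulate_genome()] result.
#' @param config the [sim_config()] used to build it.
#' @return data.frame(chrom, pos, ref, alt, is_causal), sorted by
#'   (chrom, pos), positions 1-based.
#' @export
simulate_ems_mutations <- function(genome, config) {
  stopifnot(inherits(genome, "synthetic_genome"))
  set.seed(stage_seed(config$seed, "ems"))
  causal_gene <- genome$genes[[genome$causal_gene_id]]
  causal <- plant_stop_gain(genome, causal_gene)
  genome_kb <- sum(nchar(genome$chromosomes)) / 1000
  n_total <- stats::rpois(1L, config$ems_rate * genome_kb)
  chrom_names <- names(genome$chromosomes)
  chrom_weights <- nchar(genome$chromosomes)
  n_per_chrom <- as.vector(stats::rmultinom(
    1L, n_total, chrom_weights / sum(chrom_weights)))
  rows <- list()
  for (ci in seq_along(chrom_names)) {
    chrom <- chrom_names[ci]
    if (n_per_chrom[ci] == 0L) next
    gc_pos <- if (!is.null(genome$gc_pos)) genome$gc_pos[[chrom]] else
      gc_positions(genome$chromosomes[[chrom]])
    if (chrom == causal_gene$chrom) {
      cds_pos <- unlist(mapply(seq, causal_gene$cds$start,
                               causal_gene$cds$end, SIMPLIFY = FALSE))
      gc_pos <- setdiff(gc_pos, c(cds_pos, causal$pos))
    }
    n_take <- min(n_per_chrom[ci], length(gc_pos))
    pos <- sort(sample(gc_pos, n_take))
    ref <- vapply(pos, function(p) genome_base(genome, chrom, p),
                  character(1))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, pos = pos, ref = ref,
      alt = ifelse(ref == "G", "A", "T"),
      is_causal = FALSE, stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    chrom = causal_gene$chrom, pos = causal$pos, ref = causal$ref,
    alt = causal$alt, is_causal = TRUE, stringsAsFactors = FALSE)
  muts <- do.call(rbind, rows)
  muts <- muts[order(muts$chrom, muts$pos), ]
  rownames(muts) <- NULL
  muts
}

#' Simulate pooled allele depths for the mutant bulk and the WT parent
#'
#' Each EMS site gets a true mutant-allele frequency in the bulk from
#' Mendelian sampling: for a bulk of n homozygous-recessive plants the
#' 2n gametes each carry the mutant allele with probability `1 - r`, where
#' r is the recombination fraction between the site and the causal locus
#' (inverse Kosambi of the cM distance under the configured cM/Mb map;
#' unlinked chromosomes use r = 0.5).  The causal site itself has
#' frequency exactly 1.  Read depth is Poisson(`mean_depth`) per site and
#' alt reads are Binomial(depth, frequency); zero-depth sites are dropped.
#' The WT parent is reference-homozygous at every EMS site.  Shared
#' background variants (residual natural variation against the reference,
#' carried by both pools) are appended to both tables and must be removed
#' downstream by [derive_mutant_specific_sites()].
#'
#' @param genome a [simulate_genome()] result.
#' @param mutations output of [simulate_ems_mutations()].
#' @param config the [sim_config()].
#' @return list with `mutant` and `wt` variant tables
#'   (chrom, pos, ref, alt, ref_depth, alt_depth, snp_index) and `causal`
#'   (the causal site row of the mutant table).
#' @export
simulate_bulk_depths <- function(genome, mutations, config) {
  set.seed(stage_seed(config$seed, "bulk"))
  causal <- mutations[mutations$is_causal, ]
  stopifnot(nrow(causal) == 1L)
  n_gam <- 2L * config$bulk_size
  d_cm <- ifelse(mutations$chrom == causal$chrom,
                 abs(mutations$pos - causal$pos) / 1e6 * config$cm_per_mb,
                 Inf)
  r <- kosambi_r(pmin(d_cm, 1e6))
  freq <- stats::rbinom(nrow(mutations), n_gam, 1 - r) / n_gam
  freq[mutations$is_causal] <- 1
  depth <- stats::rpois(nrow(mutations), config$mean_depth)
  alt_depth <- stats::rbinom(nrow(mutations), depth, freq)
  mutant <- data.frame(chrom = mutations$chrom, pos = mutations$pos,
                       ref = mutations$ref, alt = mutations$alt,
                       ref_depth = depth - alt_depth,
                       alt_depth = alt_depth,
                       is_causal = mutations$is_causal,
                       stringsAsFactors = FALSE)
  wt_depth <- stats::rpois(nrow(mutations), config$mean_depth)
  wt <- data.frame(chrom = mutations$chrom, pos = mutations$pos,
                   ref = mutations$ref, alt = mutations$alt,
                   ref_depth = wt_depth, alt_depth = 0L,
                   stringsAsFactors = FALSE)
  # shared parental background variants: homozygous alt in both pools
  if (config$n_background > 0L) {
    taken <- site_key(mutations$chrom, mutations$pos)
    bg <- list()
    per_chrom <- as.vector(stats::rmultinom(
      1L, config$n_background,
      rep(1 / config$n_chromosomes, config$n_chromosomes)))
    for (ci in seq_len(config$n_chromosomes)) {
      if (per_chrom[ci] == 0L) next
      chrom <- names(genome$chromosomes)[ci]
      repeat {
        pos <- sort(sample.int(nchar(genome$chromosomes[[chrom]]),
                               per_chrom[ci]))
        if (!any(site_key(chrom, pos) %in% taken)) break
      }
      ref <- vapply(pos, function(p) genome_base(genome, chrom, p),
                    character(1))
      alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L),
                    character(1))
      bg[[length(bg) + 1L]] <- data.frame(
        chrom = chrom, pos = pos, ref = ref, alt = alt,
        stringsAsFactors = FALSE)
    }
    bg <- do.call(rbind, bg)
    d1 <- stats::rpois(nrow(bg), config$mean_depth)
    d2 <- stats::rpois(nrow(bg), config$mean_depth)
    mutant <- rbind(mutant,
                    data.frame(bg, ref_depth = 0L, alt_depth = d1,
                               is_causal = FALSE))
    wt <- rbind(wt, data.frame(bg, ref_depth = 0L, alt_depth = d2))
  }
  mutant <- mutant[mutant$ref_depth + mutant$alt_depth > 0L, ]
  wt <- wt[wt$ref_depth + wt$alt_depth > 0L, ]
  mutant$snp_index <- compute_snp_index(mutant$ref_depth,
                                        mutant$alt_depth)
  mutant <- mutant[order(mutant$chrom, mutant$pos), ]
  wt <- wt[order(wt$chrom, wt$pos), ]
  rownames(mutant) <- rownames(wt) <- NULL
  attr(mutant, "reference") <- attr(wt, "reference") <- "synthetic_ref_v1"
  list(mutant = mutant, wt = wt,
       causal = mutant[mutant$is_causal, ])
}
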