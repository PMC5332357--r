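GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

#' Construct and validate a gene model
#'
#' @param gene_id identifier.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons data.frame with 1-based inclusive `start`, `end`, sorted,
#'   non-overlapping.
#' @param cds data.frame of coding segments (defaults to `exons`).
#' @return a `gene_model` list.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds = exons) {
  stopifnot(strand %in% c("+", "-"),
            is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  if (any(exons$end < exons$start) ||
      (nrow(exons) > 1L &&
       any(exons$start[-1L] <= exons$end[-nrow(exons)]))) {
    stop("gene ", gene_id, ": exons must be sorted and non-overlapping")
  }
  cds_len <- sum(cds$end - cds$start + 1L)
  if (cds_len %% 3L != 0L) {
    stop("gene ", gene_id, ": CDS length ", cds_len,
         " is not a multiple of 3")
  }
  list(gene_id = gene_id, chrom = chrom, strand = strand,
       exons = exons, cds = cds,
       start = min(exons$start), end = max(exons$end))
}

# Map a genomic position to the 1-based spliced CDS position, or NA if the
# position is not inside a coding segment.  Strand-aware.
genomic_to_cds <- function(gene, pos) {
  seg_len <- gene$cds$end - gene$cds$start + 1L
  hit <- which(pos >= gene$cds$start & pos <= gene$cds$end)
  if (length(hit) == 0L) return(NA_integer_)
  if (gene$strand == "+") {
    before <- if (hit > 1L) sum(seg_len[seq_len(hit - 1L)]) else 0L
    as.integer(before + (pos - gene$cds$start[hit] + 1L))
  } else {
    k <- nrow(gene$cds)
    after <- if (hit < k) sum(seg_len[seq(hit + 1L, k)]) else 0L
    as.integer(after + (gene$cds$end[hit] - pos + 1L))
  }
}

# Inverse of genomic_to_cds.
cds_to_genomic <- function(gene, cds_pos) {
  seg_len <- gene$cds$end - gene$cds$start + 1L
  total <- sum(seg_len)
  stopifnot(cds_pos >= 1L, cds_pos <= total)
  if (gene$strand == "+") {
    cum <- cumsum(seg_len)
    hit <- which(cds_pos <= cum)[1L]
    before <- if (hit > 1L) cum[hit - 1L] else 0L
    as.integer(gene$cds$start[hit] + (cds_pos - before - 1L))
  } else {
    cum <- cumsum(rev(seg_len))        # transcription order on - strand
    hit_t <- which(cds_pos <= cum)[1L]
    before <- if (hit_t > 1L) cum[hit_t - 1L] else 0L
    hit <- nrow(gene$cds) - hit_t + 1L
    as.integer(gene$cds$end[hit] - (cds_pos - before - 1L))
  }
}

translate_codon <- function(codon) {
  aa <- GENETIC_CODE_TABLE[codon]
  if (is.na(aa)) stop("cannot translate codon '", codon, "'")
  unname(aa)
}

#' Translate a coding sequence
#'
#' Standard nuclear code; translation stops at the first stop codon, which
#' is not counted as a residue.
#'
#' @param cds nucleotide string, length a multiple of 3, A/C/G/T only.
#' @return the protein as a single string (no stop symbol).
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length ", nchar(cds), " is not a multiple of 3")
  }
  if (grepl("[^ACGT]", cds)) {
    stop("CDS contains non-ACGT characters")
  }
  n <- nchar(cds) %/% 3L
  starts <- 3L * (seq_len(n) - 1L) + 1L
  codons <- substring(cds, starts, starts + 2L)
  aas <- GENETIC_CODE_TABLE[codons]
  stop_at <- which(aas == "*")
  if (length(stop_at) > 0L) aas <- aas[seq_len(stop_at[1L] - 1L)]
  paste(aas, collapse = "")
}

find_gene_at <- function(gene_models, chrom, pos) {
  for (g in gene_models) {
    if (g$chrom == chrom && pos >= g$start && pos <= g$end) return(g)
  }
  NULL
}

#' Annotate the coding effect of a SNP
#'
#' Maps a genomic substitution onto gene models: region label
#' (intergenic / intronic / exonic_noncoding / coding), spliced-CDS
#' position, codon number, reference and alternate codons and amino acids,
#' and an effect class (synonymous, missense, stop_gained, stop_lost,
#' start_lost).  Strand-aware: for minus-strand genes the alternate base is
#' complemented before codon substitution.
#'
#' @param chrom,pos,ref,alt the substitution (1-based, top-strand bases).
#' @param gene_models list of [gene_model()]s (or a `synthetic_genome`'s
#'   `$genes`).
#' @param genome a `synthetic_genome`, or a named character vector of
#'   chromosome sequences.
#' @return one-row data.frame: chrom, pos, ref, alt, gene_id, region,
#'   cds_pos, codon_number, ref_codon, alt_codon, ref_aa, alt_aa, effect.
#' @export
annotate_effect <- function(chrom, pos, ref, alt, gene_models, genome) {
  if (!inherits(genome, "synthetic_genome")) {
    stopifnot(is.character(genome), !is.null(names(genome)))
    genome <- structure(list(chromosomes = genome, genes = gene_models,
                             cds_cache = NULL),
                        class = "synthetic_genome")
  }
  if (!chrom %in% names(genome$chromosomes)) {
    stop("chromosome '", chrom, "' not in genome")
  }
  if (pos < 1L || pos > nchar(genome$chromosomes[[chrom]])) {
    stop("position ", pos, " outside ", chrom)
  }
  gbase <- genome_base(genome, chrom, pos)
  if (gbase != ref) {
    stop("reference mismatch at ", chrom, ":", pos, " (genome ", gbase,
         ", site ", ref, ")")
  }
  na_row <- function(region, gene_id = NA_character_) {
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
               gene_id = gene_id, region = region,
               cds_pos = NA_integer_, codon_number = NA_integer_,
               ref_codon = NA_character_, alt_codon = NA_character_,
               ref_aa = NA_character_, alt_aa = NA_character_,
               effect = NA_character_, stringsAsFactors = FALSE)
  }
  gene <- find_gene_at(gene_models, chrom, pos)
  if (is.null(gene)) return(na_row("intergenic"))
  in_exon <- any(pos >= gene$exons$start & pos <= gene$exons$end)
  if (!in_exon) return(na_row("intronic", gene$gene_id))
  cds_pos <- genomic_to_cds(gene, pos)
  if (is.na(cds_pos)) return(na_row("exonic_noncoding", gene$gene_id))
  cds_len <- sum(gene$cds$end - gene$cds$start + 1L)
  if (cds_len %% 3L != 0L) {
    stop("gene ", gene$gene_id, ": CDS length not a multiple of 3")
  }
  cds <- spliced_cds(genome, gene)
  codon_number <- as.integer(ceiling(cds_pos / 3))
  within <- cds_pos - 3L * (codon_number - 1L)   # 1..3
  codon_start <- 3L * (codon_number - 1L) + 1L
  ref_codon <- substr(cds, codon_start, codon_start + 2L)
  alt_coding <- if (gene$strand == "+") alt else complement_base(alt)
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt_coding
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  effect <- if (codon_number == 1L && ref_codon == "ATG" &&
                alt_codon != "ATG") {
    "start_lost"
  } else if (ref_aa == alt_aa) {
    "synonymous"
  } else if (alt_aa == "*") {
    "stop_gained"
  } else if (ref_aa == "*") {
    "stop_lost"
  } else {
    "missense"
  }
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             gene_id = gene$gene_id, region = "coding",
             cds_pos = cds_pos, codon_number = codon_number,
             ref_codon = ref_codon, alt_codon = alt_codon,
             ref_aa = ref_aa, alt_aa = alt_aa, effect = effect,
             stringsAsFactors = FALSE)
}

#' Annotate a table of variant sites
#'
#' @param sites data.frame with chrom, pos, ref, alt (extra columns such as
#'   depths and snp_index are carried through).
#' @inheritParams annotate_effect
#' @return `sites` with annotation columns appended.
#' @export
annotate_effects <- function(sites, gene_models, genome) {
  ann <- do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
    annotate_effect(sites$chrom[i], sites$pos[i], sites$ref[i],
                    sites$alt[i], gene_models, genome)
  }))
  cbind(sites,
        ann[, setdiff(names(ann), c("chrom", "pos", "ref", "alt")),
            drop = FALSE])
}

NONSYN_EFFECTS <- c("missense", "stop_gained", "stop_lost", "start_lost")

#' Four-stage candidate filter cascade
#'
#' Applies, in fixed order: (1) site inside the candidate region,
#' (2) exonic (coding), (3) non-synonymous, (4) homozygous in the mutant
#' pool under the operational SNP-index rule (`snp_index >= min_index` and
#' `alt_depth >= min_alt_depth`, or strict `snp_index == 1`).  The order is
#' fixed so funnel reports are comparable across runs.
#'
#' @param effect_calls annotated sites (from [annotate_effects()]) carrying
#'   `snp_index` and `alt_depth` columns.
#' @param region one-row candidate region (chrom, start, end) as returned
#'   by [call_candidate_region()].
#' @param min_index,min_alt_depth homozygosity rule; see [sim_config()].
#' @param strict if TRUE require literal `snp_index == 1`.
#' @return list with `survivors` (the filtered table) and `funnel`
#'   (data.frame of stage names and counts surviving each stage).
#' @export
filter_cascade <- function(effect_calls, region, min_index = 0.95,
                           min_alt_depth = 10L, strict = FALSE) {
  x <- effect_calls
  n0 <- nrow(x)
  x <- x[x$chrom == region$chrom & x$pos >= region$start &
           x$pos <= region$end, , drop = FALSE]
  n1 <- nrow(x)
  x <- x[!is.na(x$region) & x$region == "coding", , drop = FALSE]
  n2 <- nrow(x)
  x <- x[x$effect %in% NONSYN_EFFECTS, , drop = FALSE]
  n3 <- nrow(x)
  keep <- if (strict) {
    x$snp_index == 1
  } else {
    x$snp_index >= min_index & x$alt_depth >= min_alt_depth
  }
  x <- x[keep, , drop = FALSE]
  n4 <- nrow(x)
  funnel <- data.frame(
    stage = c("input", "in_region", "exonic", "non_synonymous",
              "homozygous_in_pool"),
    n = c(n0, n1, n2, n3, n4))
  list(survivors = x, funnel = funnel)
}

#' Screen a SNP against a natural panel
#'
#' Counts panel lines carrying the mutant allele at a site; the site is
#' "unique" to the mutant when no line carries it.
#'
#' @param site list or one-row data.frame with `chrom` and `pos`.
#' @param panel_genotypes matrix/data.frame of alt-allele counts (0/1/2),
#'   lines x sites, columns named "chrom:pos".
#' @return list with `n_carriers` and `verdict` ("unique"/"not_unique").
#' @export
panel_uniqueness_screen <- function(site, panel_genotypes) {
  key <- site_key(site$chrom, site$pos)
  panel_genotypes <- as.matrix(panel_genotypes)
  if (nrow(panel_genotypes) == 0L) {
    stop("panel is empty")
  }
  if (!key %in% colnames(panel_genotypes)) {
    stop("site ", key, " absent from panel table")
  }
  n_carriers <- sum(panel_genotypes[, key] > 0)
  list(n_carriers = n_carriers,
       verdict = if (n_carriers == 0L) "unique" else "not_unique")
}
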