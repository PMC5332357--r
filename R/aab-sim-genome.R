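STOP_CODONS <- c("TAA", "TAG", "TGA")

all_codons <- function() {
  as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
}

SENSE_CODONS <- setdiff(all_codons(), STOP_CODONS)

# Split `total` into k positive parts, each >= min_part, with random sizes.
split_lengths <- function(total, k, min_part = 3L) {
  stopifnot(total >= k * min_part)
  if (k == 1L) return(total)
  w <- stats::runif(k, 0.5, 1.5)
  free <- total - k * min_part
  parts <- floor(free * w / sum(w))
  parts[1L] <- parts[1L] + (free - sum(parts))
  parts + min_part
}

# Build one gene model plus the genomic sequence of its span.
# `cds` is the spliced coding sequence in transcription order.
build_gene <- function(gene_id, chrom, start, strand, cds, n_exons,
                       intron_range = c(80L, 300L)) {
  stopifnot(strand %in% c("+", "-"), nchar(cds) %% 3L == 0L)
  L <- nchar(cds)
  seg_len <- split_lengths(L, n_exons, min_part = 9L)
  segs <- character(n_exons)
  off <- 0L
  for (i in seq_len(n_exons)) {
    segs[i] <- substr(cds, off + 1L, off + seg_len[i])
    off <- off + seg_len[i]
  }
  intron_len <- if (n_exons > 1L) {
    sample(seq(intron_range[1L], intron_range[2L]), n_exons - 1L,
           replace = TRUE)
  } else integer(0)
  # genomic exon contents: on + the segments in order, on - the reverse
  # complement of the segments in reverse order
  genomic_exons <- if (strand == "+") segs else
    vapply(rev(segs), revcomp, character(1))
  pieces <- character(2L * n_exons - 1L)
  exon_start <- integer(n_exons)
  exon_end <- integer(n_exons)
  pos <- start
  for (i in seq_len(n_exons)) {
    exon_start[i] <- pos
    exon_end[i] <- pos + nchar(genomic_exons[i]) - 1L
    pieces[2L * i - 1L] <- genomic_exons[i]
    pos <- exon_end[i] + 1L
    if (i < n_exons) {
      intron <- paste(sample(BASES, intron_len[i], replace = TRUE),
                      collapse = "")
      pieces[2L * i] <- intron
      pos <- pos + intron_len[i]
    }
  }
  gene <- list(gene_id = gene_id, chrom = chrom, strand = strand,
               exons = data.frame(start = exon_start, end = exon_end),
               cds = data.frame(start = exon_start, end = exon_end),
               start = start, end = pos - 1L)
  list(gene = gene, span_seq = paste(pieces, collapse = ""))
}

random_cds <- function(n_codons, force_trp_codon = NA_integer_) {
  stopifnot(n_codons >= 3L)
  body <- sample(SENSE_CODONS, n_codons - 2L, replace = TRUE)
  if (!is.na(force_trp_codon)) {
    stopifnot(force_trp_codon >= 2L, force_trp_codon <= n_codons - 1L)
    body[force_trp_codon - 1L] <- "TGG"
  }
  paste(c("ATG", body, sample(STOP_CODONS, 1L)), collapse = "")
}

#' Simulate a multi-chromosome genome with gene models
#'
#' Chromosomes are uniform-random nucleotide strings; genes are evenly
#' spaced along each chromosome, alternate strand, and carry multi-exon
#' coding sequences that start with ATG, contain no internal stop and end
#' with a stop codon.  The designated causal gene (a 9-exon, 1392-bp CDS
#' by default, emulating a cytochrome P450) is built with a tryptophan
#' (TGG) codon at position 157 so a planted G-to-A transition can create a
#' premature TAG stop.
#'
#' @param config a [sim_config()].
#' @return an object of class `synthetic_genome`: a list with
#'   `chromosomes` (named character vector), `genes` (named list of gene
#'   models), `causal_gene_id`, and the `config` used.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genome"))
  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))
  chromosomes <- character(config$n_chromosomes)
  names(chromosomes) <- chrom_names
  gc_pos <- vector("list", config$n_chromosomes)
  names(gc_pos) <- chrom_names
  base_codes <- utf8ToInt("ACGT")
  genes <- list()
  causal_gene_id <- NA_character_
  for (ci in seq_along(chrom_names)) {
    chrom <- chrom_names[ci]
    codes <- base_codes[sample.int(4L, config$chrom_length_bp,
                                   replace = TRUE)]
    spacing <- config$chrom_length_bp / config$genes_per_chromosome
    for (gi in seq_len(config$genes_per_chromosome)) {
      gene_id <- sprintf("%s_g%02d", chrom, gi)
      is_causal <- chrom == config$causal_chrom && gi == config$causal_gene
      if (is_causal) {
        n_codons <- config$causal_cds_len %/% 3L
        trp <- min(157L, n_codons - 1L)
        cds <- random_cds(n_codons, force_trp_codon = trp)
        n_exons <- config$causal_exons
      } else {
        cds <- random_cds(400L)   # 1200-bp CDS typical of plant genes
        n_exons <- 3L
      }
      strand <- if (gi %% 2L == 0L) "-" else "+"
      anchor <- as.integer(round((gi - 0.5) * spacing)) - 1500L
      anchor <- max(anchor, 1L)
      built <- build_gene(gene_id, chrom, anchor, strand, cds, n_exons)
      if (built$gene$end > config$chrom_length_bp) {
        stop("gene ", gene_id, " exceeds chromosome bounds; increase ",
             "chrom_length_bp or reduce genes_per_chromosome")
      }
      codes[built$gene$start:built$gene$end] <- utf8ToInt(built$span_seq)
      genes[[gene_id]] <- built$gene
      if (is_causal) causal_gene_id <- gene_id
    }
    chromosomes[chrom] <- intToUtf8(codes)
    gc_pos[[chrom]] <- which(codes == 67L | codes == 71L)   # C, G
  }
  structure(list(chromosomes = chromosomes, genes = genes,
                 gc_pos = gc_pos,
                 causal_gene_id = causal_gene_id, config = config,
                 cds_cache = new.env(parent = emptyenv())),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic genome: %d chromosomes (%s bp total), %d genes\n",
              length(x$chromosomes),
              format(sum(nchar(x$chromosomes)), big.mark = ","),
              length(x$genes)))
  cat("  causal gene:", x$causal_gene_id, "\n")
  invisible(x)
}

genome_base <- function(genome, chrom, pos) {
  substr(genome$chromosomes[[chrom]], pos, pos)
}

# Spliced CDS (transcription order), cached per gene.
spliced_cds <- function(genome, gene) {
  if (!is.null(genome$cds_cache)) {
    hit <- get0(gene$gene_id, envir = genome$cds_cache)
    if (!is.null(hit)) return(hit)
  }
  seqs <- substring(genome$chromosomes[[gene$chrom]],
                    gene$cds$start, gene$cds$end)
  out <- if (gene$strand == "+") paste(seqs, collapse = "") else
    revcomp(paste(seqs, collapse = ""))
  if (!is.null(genome$cds_cache)) {
    assign(gene$gene_id, out, envir = genome$cds_cache)
  }
  out
}
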