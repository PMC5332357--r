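# Small configurations and hand-built genomes shared across tests.

tiny_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_chromosomes = 2L, chrom_length_bp = 100000L,
             genes_per_chromosome = 2L, causal_chrom = "chr1",
             causal_gene = 1L, ...)
}

# A one-chromosome "genome" built by hand around a supplied spliced CDS.
# Returns a synthetic_genome-compatible object with a single plus- or
# minus-strand gene whose exon/CDS layout is generated from `seg_len`.
manual_genome <- function(cds, strand = "+", seg_len = NULL,
                          intron_len = 50L, pad = 500L, seed = 42L) {
  set.seed(seed)
  if (is.null(seg_len)) seg_len <- nchar(cds)
  stopifnot(sum(seg_len) == nchar(cds))
  segs <- character(length(seg_len))
  off <- 0L
  for (i in seq_along(seg_len)) {
    segs[i] <- substr(cds, off + 1L, off + seg_len[i])
    off <- off + seg_len[i]
  }
  genomic_exons <- if (strand == "+") segs else
    vapply(rev(segs), revcomp, character(1))
  pieces <- character(0)
  starts <- integer(length(seg_len))
  ends <- integer(length(seg_len))
  pos <- pad + 1L
  for (i in seq_along(genomic_exons)) {
    starts[i] <- pos
    ends[i] <- pos + nchar(genomic_exons[i]) - 1L
    pieces <- c(pieces, genomic_exons[i])
    pos <- ends[i] + 1L
    if (i < length(genomic_exons)) {
      pieces <- c(pieces,
                  paste(sample(c("A", "C", "G", "T"), intron_len,
                               replace = TRUE), collapse = ""))
      pos <- pos + intron_len
    }
  }
  left <- paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
                collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), pad, replace = TRUE),
                 collapse = "")
  chrom_seq <- paste0(left, paste(pieces, collapse = ""), right)
  gene <- gene_model("g1", "chrT", strand,
                     exons = data.frame(start = starts, end = ends))
  genome <- structure(list(chromosomes = c(chrT = chrom_seq),
                           genes = list(g1 = gene),
                           causal_gene_id = "g1",
                           cds_cache = new.env(parent = emptyenv())),
                      class = "synthetic_genome")
  list(genome = genome, gene = gene)
}

# random sense-codon CDS of n_codons (incl. start and terminal stop)
random_test_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- setdiff(
    as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                          paste0), c("A", "C", "G", "T"), paste0)),
    c("TAA", "TAG", "TGA"))
  paste(c("ATG", sample(sense, n_codons - 2L, replace = TRUE),
          sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
}
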