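#' Write chromosome sequences to FASTA
#'
#' @param genome a `synthetic_genome` or named character vector.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  chromosomes <- if (inherits(genome, "synthetic_genome"))
    genome$chromosomes else genome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(chromosomes), path)
  invisible(path)
}

#' Read chromosome sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write gene models as GFF3
#'
#' One gene/mRNA per model plus exon and CDS features; 1-based inclusive
#' coordinates.
#'
#' @param genes list of gene models (e.g. `genome$genes`).
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    mrna_id <- paste0(g$gene_id, ".t1")
    row <- function(type, start, end, attrs) {
      paste(g$chrom, "mutseek", type, start, end, ".", g$strand, ".",
            attrs, sep = "\t")
    }
    writeLines(c(
      row("gene", g$start, g$end, paste0("ID=", g$gene_id)),
      row("mRNA", g$start, g$end,
          paste0("ID=", mrna_id, ";Parent=", g$gene_id)),
      vapply(seq_len(nrow(g$exons)), function(i) {
        row("exon", g$exons$start[i], g$exons$end[i],
            paste0("Parent=", mrna_id))
      }, character(1)),
      vapply(seq_len(nrow(g$cds)), function(i) {
        row("CDS", g$cds$start[i], g$cds$end[i],
            paste0("Parent=", mrna_id))
      }, character(1))), con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects one transcript per gene with exon and CDS features (the layout
#' written by [write_gff3()]); parsed with rtracklayer.
#'
#' @param path GFF3 file.
#' @return named list of gene models.
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  first_chr <- function(x) vapply(x, function(v)
    if (length(v) > 0) as.character(v)[1] else NA_character_, character(1))
  df$parent <- first_chr(df$Parent)
  mrna <- df[df$type == "mRNA", ]
  genes <- list()
  for (i in seq_len(nrow(mrna))) {
    mrna_id <- as.character(mrna$ID[i])
    gene_id <- mrna$parent[i]
    exons <- df[df$type == "exon" & df$parent == mrna_id, ]
    cds <- df[df$type == "CDS" & df$parent == mrna_id, ]
    genes[[gene_id]] <- gene_model(
      gene_id, as.character(mrna$seqnames[i]),
      as.character(mrna$strand[i]),
      exons = data.frame(start = exons$start, end = exons$end),
      cds = data.frame(start = cds$start, end = cds$end))
  }
  genes
}

#' Write a variant table in the package TSV dialect
#'
#' Columns chrom, pos, ref, alt, ref_depth, alt_depth; a leading
#' `#reference=` line records the reference build.
#'
#' @param tab variant data.frame.
#' @param path output file.
#' @export
write_variants_tsv <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ref <- attr(tab, "reference")
  if (!is.null(ref)) writeLines(paste0("#reference=", ref), con)
  cols <- intersect(c("chrom", "pos", "ref", "alt", "ref_depth",
                      "alt_depth"), names(tab))
  utils::write.table(tab[, cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_variants_tsv
#' @return for the reader: the variant data.frame (with a "reference"
#'   attribute when recorded).
#' @export
read_variants_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  skip <- 0L
  ref <- NULL
  if (startsWith(first, "#reference=")) {
    ref <- sub("^#reference=", "", first)
    skip <- 1L
  }
  tab <- utils::read.delim(path, skip = skip, stringsAsFactors = FALSE)
  if (!is.null(ref)) attr(tab, "reference") <- ref
  tab
}

#' Write a variant table as VCF 4.2 with allele depths
#'
#' Single-sample VCF with GT:AD:DP FORMAT fields; genotypes are called
#' from the allele-depth fraction (>= 0.9 alt-homozygous, <= 0.1
#' ref-homozygous, heterozygous in between).
#'
#' @param tab variant data.frame (chrom, pos, ref, alt, ref_depth,
#'   alt_depth).
#' @param path output file.
#' @param sample_name sample column header.
#' @export
write_variants_vcf <- function(tab, path, sample_name = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  ref_build <- attr(tab, "reference")
  writeLines(c(
    "##fileformat=VCFv4.2",
    if (!is.null(ref_build)) paste0("##reference=", ref_build),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths for the ref and alt alleles\">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")), con)
  dp <- tab$ref_depth + tab$alt_depth
  frac <- ifelse(dp > 0, tab$alt_depth / dp, NA_real_)
  gt <- ifelse(is.na(frac), "./.",
               ifelse(frac >= 0.9, "1/1",
                      ifelse(frac <= 0.1, "0/0", "0/1")))
  writeLines(paste(tab$chrom, tab$pos, ".", tab$ref, tab$alt, ".",
                   "PASS", ".", "GT:AD:DP",
                   paste0(gt, ":", tab$ref_depth, ",", tab$alt_depth,
                          ":", dp),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a single-sample VCF with AD fields into a variant table
#'
#' @param path VCF file (parsed with vcfR).
#' @return data.frame chrom, pos, ref, alt, ref_depth, alt_depth, with a
#'   "reference" attribute if the header records one.
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  parts <- strsplit(ad[, 1L], ",", fixed = TRUE)
  tab <- data.frame(
    chrom = as.character(v@fix[, "CHROM"]),
    pos = as.integer(v@fix[, "POS"]),
    ref = as.character(v@fix[, "REF"]),
    alt = as.character(v@fix[, "ALT"]),
    ref_depth = vapply(parts, function(x) as.integer(x[1L]), integer(1)),
    alt_depth = vapply(parts, function(x) as.integer(x[2L]), integer(1)),
    stringsAsFactors = FALSE)
  meta <- v@meta
  refline <- grep("^##reference=", meta, value = TRUE)
  if (length(refline) > 0L) {
    attr(tab, "reference") <- sub("^##reference=", "", refline[1L])
  }
  tab
}

#' Write candidate regions as BED
#'
#' BED uses 0-based half-open coordinates; the package's internal 1-based
#' inclusive regions are converted on output.
#'
#' @param regions data.frame from [call_candidate_region()].
#' @param path output file.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,
                    end = regions$end,
                    name = sprintf("region_%d", seq_len(nrow(regions))),
                    score = round(1000 * regions$peak_index))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read/write aligned protein FASTA
#'
#' @param path FASTA file.
#' @return named character vector of aligned sequences.
#' @export
read_alignment_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname read_alignment_fasta
#' @param set named character vector of aligned sequences.
#' @export
write_alignment_fasta <- function(set, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(set), path)
  invisible(path)
}
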