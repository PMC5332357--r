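BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a nucleotide string
#'
#' @param x character scalar over A/C/G/T/N.
#' @return the reverse complement, same case (uppercase assumed).
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- rev(strsplit(toupper(x), "", fixed = TRUE)[[1L]])
  bad <- setdiff(unique(chars), names(COMPLEMENT))
  if (length(bad) > 0L) {
    stop("revcomp(): invalid base(s): ", paste(bad, collapse = ", "))
  }
  paste(COMPLEMENT[chars], collapse = "")
}

complement_base <- function(b) unname(COMPLEMENT[b])

#' Derive a per-stage seed from a master seed
#'
#' One master seed controls every stochastic stage of the simulator; each
#' stage re-seeds from `stage_seed(seed, stage)` so any stage can be
#' regenerated independently of the others.  The derivation is a fixed
#' affine map kept inside 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param stage one of "genome", "ems", "bulk", "markers", "panel", "ct",
#'   "proteins".
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage = c("genome", "ems", "bulk", "markers",
                                       "panel", "ct", "proteins")) {
  stage <- match.arg(stage)
  offset <- c(genome = 1L, ems = 2L, bulk = 3L, markers = 4L,
              panel = 5L, ct = 6L, proteins = 7L)[[stage]]
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483587)
}

#' Express a ratio as a percentage
#'
#' Small convenience used for report tables (mutation frequency per genome,
#' marker polymorphism rates, trait-value ratios).
#'
#' @param numerator,denominator positive numbers.
#' @param digits decimals to round to; `NULL` for full precision.
#' @return `100 * numerator / denominator`, optionally rounded.
#' @export
percent_ratio <- function(numerator, denominator, digits = NULL) {
  stopifnot(is.numeric(numerator), is.numeric(denominator),
            all(denominator > 0))
  p <- 100 * numerator / denominator
  if (!is.null(digits)) p <- round(p, digits)
  p
}

#' Genome-wide mutation frequency from a SNP count
#'
#' @param n_snps number of induced SNPs detected.
#' @param genome_bp genome size in base pairs.
#' @return list with `percent` (mutated fraction of sites, in %) and
#'   `per_kb` (mutations per kb).
#' @export
mutation_frequency <- function(n_snps, genome_bp) {
  stopifnot(n_snps >= 0, genome_bp > 0)
  list(percent = 100 * n_snps / genome_bp,
       per_kb = n_snps / (genome_bp / 1000))
}

site_key <- function(chrom, pos) paste0(chrom, ":", pos)
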