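IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

iupac_match_base <- function(code, base) base %in% IUPAC_SETS[[code]]

# reverse complement of an IUPAC pattern (B<->V, D<->H, R<->Y, K<->M;
# S, W, N are self-complementary)
iupac_revcomp <- function(pattern) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", pattern)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Define a restriction enzyme
#'
#' @param name enzyme name.
#' @param pattern recognition sequence as an IUPAC string.
#' @param cut_offset bases from the pattern start to the top-strand cut
#'   (the enzyme cuts after `cut_offset` bases of the pattern; e.g. Dde I
#'   C^TNAG has offset 1).
#' @return a `restriction_enzyme` list.
#' @export
restriction_enzyme <- function(name, pattern, cut_offset) {
  pattern <- toupper(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% names(IUPAC_SETS))) {
    stop("pattern contains non-IUPAC characters")
  }
  stopifnot(cut_offset >= 0, cut_offset <= nchar(pattern))
  structure(list(name = name, pattern = pattern,
                 cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' Default enzyme library
#'
#' A small editable set of 5-6-cutters commonly used for CAPS/dCAPS
#' genotyping, including Dde I (C^TNAG).
#'
#' @return named list of [restriction_enzyme()] objects.
#' @export
default_enzymes <- function() {
  list(
    DdeI = restriction_enzyme("DdeI", "CTNAG", 1L),
    EcoRI = restriction_enzyme("EcoRI", "GAATTC", 1L),
    HindIII = restriction_enzyme("HindIII", "AAGCTT", 1L),
    HinfI = restriction_enzyme("HinfI", "GANTC", 1L),
    MseI = restriction_enzyme("MseI", "TTAA", 1L),
    AluI = restriction_enzyme("AluI", "AGCT", 2L),
    TaqI = restriction_enzyme("TaqI", "TCGA", 1L))
}

# All pattern match intervals on the forward strand of `seq`.
match_pattern_fwd <- function(seq, pattern) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                   Biostrings::DNAString(seq),
                                   fixed = FALSE)
  data.frame(start = BiocGenerics::start(hits),
             end = BiocGenerics::end(hits))
}

#' Scan a sequence for restriction sites
#'
#' Finds all matches of the enzyme's IUPAC recognition pattern on the
#' forward strand and on the reverse complement; each physical site is
#' reported once (palindromic patterns match both strands over the same
#' interval and are deduplicated).  The returned cut positions are
#' top-strand coordinates: a fragment boundary after base `p`.
#'
#' @param seq nucleotide string (A/C/G/T).
#' @param enzyme a [restriction_enzyme()].
#' @return sorted unique integer cut positions (0 < p < nchar(seq)).
#' @export
scan_sites <- function(seq, enzyme) {
  seq <- toupper(seq)
  if (grepl("[^ACGT]", seq)) stop("sequence contains invalid bases")
  L <- nchar(enzyme$pattern)
  n <- nchar(seq)
  fwd <- match_pattern_fwd(seq, enzyme$pattern)
  rev <- match_pattern_fwd(seq, iupac_revcomp(enzyme$pattern))
  cuts <- numeric(0)
  if (nrow(fwd) > 0L) {
    cuts <- c(cuts, fwd$start + enzyme$cut_offset - 1L)
  }
  if (nrow(rev) > 0L) {
    # drop reverse matches coinciding with a forward match interval
    # (palindromic pattern: same physical site)
    dup <- paste(rev$start, rev$end) %in% paste(fwd$start, fwd$end)
    rev <- rev[!dup, , drop = FALSE]
    if (nrow(rev) > 0L) {
      cuts <- c(cuts, rev$end - enzyme$cut_offset)
    }
  }
  cuts <- sort(unique(cuts))
  as.integer(cuts[cuts >= 1 & cuts < n])
}

#' In-silico restriction digest
#'
#' @param amplicon nucleotide string.
#' @param enzyme a [restriction_enzyme()].
#' @return integer fragment lengths, 5' to 3'; their sum equals the
#'   amplicon length.
#' @export
digest <- function(amplicon, enzyme) {
  if (nchar(amplicon) == 0L) stop("empty amplicon")
  cuts <- scan_sites(amplicon, enzyme)
  diff(c(0L, cuts, nchar(amplicon)))
}

# advisory Wallace 2+4 rule, no nearest-neighbor thermodynamics
primer_tm <- function(primer) {
  chars <- strsplit(primer, "", fixed = TRUE)[[1L]]
  2 * sum(chars %in% c("A", "T")) + 4 * sum(chars %in% c("G", "C"))
}

#' Design a CAPS or dCAPS assay for a SNP
#'
#' First checks for a natural CAPS: an enzyme in the library whose
#' digestion pattern already differs between the two alleles of the
#' amplicon.  Otherwise searches, for each enzyme and each placement of
#' its recognition pattern overlapping the SNP, for a forward primer whose
#' at most `max_mismatch` substitutions complete the recognition site on
#' exactly one allele (the classic dCAPS construction).  Mismatches are
#' restricted to the last five primer bases excluding the 3'-terminal
#' base.  Placements are verified by digesting both allele amplicons:
#' the cut allele must yield at least two fragments and the uncut allele
#' exactly one.  Both orientations of the template are searched.
#'
#' @param genome a `synthetic_genome` or named character vector of
#'   chromosome sequences.
#' @param snp list/one-row data.frame with chrom, pos, ref, alt.
#' @param enzymes list of [restriction_enzyme()]s
#'   (default [default_enzymes()]).
#' @param max_mismatch maximum engineered primer mismatches (default 1).
#' @param primer_len forward primer length (default 20).
#' @param amplicon_len total amplicon length (default 254).
#' @return a `dcaps_assay` (list with `found = TRUE`, type "CAPS" or
#'   "dCAPS", enzyme, primer, mismatch positions, per-allele fragments,
#'   advisory Tm) or a structured failure (`found = FALSE`, reason).
#' @export
design_dcaps <- function(genome, snp, enzymes = default_enzymes(),
                         max_mismatch = 1L, primer_len = 20L,
                         amplicon_len = 254L) {
  chromosomes <- if (inherits(genome, "synthetic_genome"))
    genome$chromosomes else genome
  seq <- chromosomes[[snp$chrom]]
  for (orient in c("fwd", "rev")) {
    if (orient == "fwd") {
      template <- seq
      snp_pos <- snp$pos
      ref <- toupper(snp$ref); alt <- toupper(snp$alt)
    } else {
      template <- revcomp(seq)
      snp_pos <- nchar(seq) - snp$pos + 1L
      ref <- complement_base(toupper(snp$ref))
      alt <- complement_base(toupper(snp$alt))
    }
    hit <- design_dcaps_oriented(template, snp_pos, ref, alt, enzymes,
                                 max_mismatch, primer_len, amplicon_len)
    if (hit$found) {
      hit$snp <- snp
      hit$orientation <- orient
      return(hit)
    }
  }
  list(found = FALSE,
       reason = paste0("no enzyme/placement yields an allele-specific ",
                       "digest with <= ", max_mismatch, " primer ",
                       "mismatch(es)"),
       snp = snp)
}

design_dcaps_oriented <- function(template, snp_pos, ref, alt, enzymes,
                                  max_mismatch, primer_len, amplicon_len) {
  if (substr(template, snp_pos, snp_pos) != ref) {
    stop("template base at the SNP does not match the stated ref allele")
  }
  p_end <- snp_pos - 1L                       # 3'-terminal primer base
  p_start <- p_end - primer_len + 1L
  a_start <- p_start
  a_end <- a_start + amplicon_len - 1L
  if (p_start < 1L || a_end > nchar(template)) {
    return(list(found = FALSE, reason = "insufficient flanking sequence"))
  }
  base_amp <- substr(template, a_start, a_end)
  snp_in_amp <- snp_pos - a_start + 1L
  amp_with <- function(amp, pos, base) {
    substr(amp, pos, pos) <- base
    amp
  }
  ref_amp0 <- amp_with(base_amp, snp_in_amp, ref)
  alt_amp0 <- amp_with(base_amp, snp_in_amp, alt)
  finish <- function(type, enz, ref_amp, alt_amp, mismatch_pos) {
    fr_ref <- digest(ref_amp, enz)
    fr_alt <- digest(alt_amp, enz)
    one_cut <- (length(fr_ref) >= 2L) != (length(fr_alt) >= 2L)
    if (!one_cut || identical(fr_ref, fr_alt)) return(NULL)
    if (min(length(fr_ref), length(fr_alt)) != 1L) return(NULL)
    primer <- substr(ref_amp, 1L, primer_len)
    structure(list(found = TRUE, type = type, enzyme = enz,
                   primer = primer,
                   primer_tm = primer_tm(primer),
                   mismatch_pos = mismatch_pos,
                   amplicon_len = amplicon_len,
                   fragments_ref = fr_ref, fragments_alt = fr_alt,
                   cut_allele = if (length(fr_ref) >= 2L) "ref" else "alt"),
              class = "dcaps_assay")
  }
  # 1) natural CAPS: zero mismatches
  for (enz in enzymes) {
    hit <- finish("CAPS", enz, ref_amp0, alt_amp0, integer(0))
    if (!is.null(hit)) return(hit)
  }
  # 2) dCAPS: engineer the recognition site over the SNP via primer
  # mismatches in the allowed window (last 5 primer bases minus the
  # 3'-terminal one)
  allowed <- seq(max(p_start, p_end - 4L), p_end - 1L)
  for (enz in enzymes) {
    L <- nchar(enz$pattern)
    pat <- strsplit(enz$pattern, "", fixed = TRUE)[[1L]]
    for (q in seq(snp_pos - L + 1L, snp_pos)) {      # placement start
      if (q < p_start) next
      if (q + L - 1L > a_end) next
      snp_k <- snp_pos - q + 1L                      # SNP within pattern
      ref_ok <- iupac_match_base(pat[snp_k], ref)
      alt_ok <- iupac_match_base(pat[snp_k], alt)
      if (ref_ok == alt_ok) next                     # not allele-specific
      # template positions of the pattern other than the SNP
      tpos <- setdiff(seq(q, q + L - 1L), snp_pos)
      tbase <- vapply(tpos, function(p) substr(template, p, p),
                      character(1))
      need_fix <- !mapply(iupac_match_base, pat[tpos - q + 1L], tbase)
      fix_pos <- tpos[need_fix]
      if (any(fix_pos > p_end)) next   # cannot engineer template side
      if (!all(fix_pos %in% allowed)) next
      if (length(fix_pos) > max_mismatch) next
      amp_ref <- ref_amp0
      amp_alt <- alt_amp0
      for (p in fix_pos) {
        k <- p - q + 1L
        newb <- IUPAC_SETS[[pat[k]]][1L]
        ai <- p - a_start + 1L
        amp_ref <- amp_with(amp_ref, ai, newb)
        amp_alt <- amp_with(amp_alt, ai, newb)
      }
      hit <- finish("dCAPS", enz, amp_ref, amp_alt,
                    as.integer(fix_pos - p_start + 1L))
      if (!is.null(hit)) return(hit)
    }
  }
  list(found = FALSE, reason = "no compatible enzyme/placement")
}

#' @export
print.dcaps_assay <- function(x, ...) {
  cat(sprintf("%s assay with %s (%s)\n", x$type, x$enzyme$name,
              x$enzyme$pattern))
  cat(sprintf("  primer (%d nt, Tm ~%d C): %s\n", nchar(x$primer),
              x$primer_tm, x$primer))
  if (length(x$mismatch_pos) > 0L) {
    cat("  engineered mismatch at primer position(s):",
        paste(x$mismatch_pos, collapse = ", "), "\n")
  }
  cat(sprintf("  amplicon %d bp; ref allele: %s | alt allele: %s (%s cut)\n",
              x$amplicon_len,
              paste(x$fragments_ref, collapse = " + "),
              paste(x$fragments_alt, collapse = " + "),
              x$cut_allele))
  invisible(x)
}
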