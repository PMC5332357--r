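# Independent oracles used to check implementation routes.

# Effect-annotation oracle: mutate the genome string, extract and
# translate the full ref and alt proteins with Biostrings, and classify
# the change from the protein diff.  Independent of the codon arithmetic
# in annotate_effect().
oracle_effect <- function(genome, gene, pos, alt) {
  chrom_seq <- genome$chromosomes[[gene$chrom]]
  in_cds <- any(pos >= gene$cds$start & pos <= gene$cds$end)
  in_exon <- any(pos >= gene$exons$start & pos <= gene$exons$end)
  if (!in_exon) return(list(region = "intronic"))
  if (!in_cds) return(list(region = "exonic_noncoding"))
  mut_seq <- chrom_seq
  substr(mut_seq, pos, pos) <- alt
  splice <- function(s) {
    parts <- substring(s, gene$cds$start, gene$cds$end)
    joined <- paste(parts, collapse = "")
    if (gene$strand == "-") revcomp(joined) else joined
  }
  tr <- function(nt) {
    as.character(Biostrings::translate(
      Biostrings::DNAString(nt), no.init.codon = TRUE,
      if.fuzzy.codon = "error"))
  }
  ref_prot <- tr(splice(chrom_seq))
  alt_prot <- tr(splice(mut_seq))
  ref_aa_vec <- strsplit(ref_prot, "")[[1L]]
  alt_aa_vec <- strsplit(alt_prot, "")[[1L]]
  diff <- which(ref_aa_vec != alt_aa_vec)
  if (length(diff) == 0L) {
    return(list(region = "coding", effect = "synonymous",
                codon_number = NA_integer_))
  }
  k <- diff[1L]
  effect <- if (k == 1L && ref_aa_vec[1L] == "M" &&
                substr(splice(chrom_seq), 1L, 3L) == "ATG" &&
                substr(splice(mut_seq), 1L, 3L) != "ATG") {
    "start_lost"
  } else if (alt_aa_vec[k] == "*") {
    "stop_gained"
  } else if (ref_aa_vec[k] == "*") {
    "stop_lost"
  } else {
    "missense"
  }
  list(region = "coding", effect = effect, codon_number = k,
       ref_aa = ref_aa_vec[k], alt_aa = alt_aa_vec[k])
}

# Brute-force dCAPS design oracle: enumerate every <=1-substitution
# variant of the amplicon (substitutions limited to the last five primer
# bases minus the 3'-terminal base) for both template orientations and
# check by direct digestion whether exactly one allele is cut.  No
# pattern-completion logic.
oracle_dcaps_found <- function(chrom_seq, snp_pos, ref, alt, enzymes,
                               primer_len = 20L, amplicon_len = 254L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  try_orient <- function(template, p, rf, al) {
    p_end <- p - 1L
    a_start <- p_end - primer_len + 1L
    a_end <- a_start + amplicon_len - 1L
    if (a_start < 1L || a_end > nchar(template)) return(FALSE)
    amp <- substr(template, a_start, a_end)
    snp_i <- p - a_start + 1L
    set_base <- function(s, i, b) { substr(s, i, i) <- b; s }
    ref_amp <- set_base(amp, snp_i, rf)
    alt_amp <- set_base(amp, snp_i, al)
    window <- seq(max(1L, primer_len - 4L), primer_len - 1L)
    variants <- list(list(ref_amp, alt_amp))
    for (w in window) for (b in c("A", "C", "G", "T")) {
      variants[[length(variants) + 1L]] <-
        list(set_base(ref_amp, w, b), set_base(alt_amp, w, b))
    }
    for (enz in enzymes) for (v in variants) {
      fr <- digest(v[[1L]], enz)
      fa <- digest(v[[2L]], enz)
      if ((length(fr) >= 2L) != (length(fa) >= 2L) &&
          min(length(fr), length(fa)) == 1L) {
        return(TRUE)
      }
    }
    FALSE
  }
  if (try_orient(chrom_seq, snp_pos, ref, alt)) return(TRUE)
  try_orient(revcomp(chrom_seq), nchar(chrom_seq) - snp_pos + 1L,
             comp[[ref]], comp[[alt]])
}

# Brute-force restriction scan: slide the IUPAC pattern over every
# offset on both strands with naive per-base matching, collapse the two
# orientations of a palindromic hit at the same interval, and derive cut
# positions.  Independent of Biostrings matching.
oracle_cut_positions <- function(seq, pattern, offset) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  matches_at <- function(pat, i) {
    codes <- strsplit(pat, "")[[1L]]
    bases <- strsplit(substr(seq, i, i + nchar(pat) - 1L), "")[[1L]]
    all(mapply(function(code, base) base %in% iupac[[code]],
               codes, bases))
  }
  comp_code <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                 H = "D", V = "B", N = "N")
  rc_pat <- paste(rev(comp_code[strsplit(pattern, "")[[1L]]]),
                  collapse = "")
  L <- nchar(pattern)
  n <- nchar(seq)
  cuts <- integer(0)
  for (i in seq_len(max(n - L + 1L, 0L))) {
    fwd <- matches_at(pattern, i)
    rev_ <- matches_at(rc_pat, i)
    if (fwd) cuts <- c(cuts, i + offset - 1L)
    if (rev_ && !fwd) cuts <- c(cuts, i + L - 1L - offset)
  }
  sort(unique(cuts[cuts >= 1L & cuts < n]))
}
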