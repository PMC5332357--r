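#' Default marker map for linkage simulations
#'
#' Linkage group 1 carries the trait locus at 0 cM with flanking markers
#' at the distances reported for a typical SSR framework map (8.9 and
#' 5.5 cM on one side, 1.1 cM on the other); group 2 is an unlinked pair.
#'
#' @return data.frame(marker, group, cm).
#' @export
default_marker_map <- function() {
  data.frame(
    marker = c("M_8.9", "M_5.5", "M_1.1", "U_a", "U_b"),
    group = c(1L, 1L, 1L, 2L, 2L),
    cm = c(-8.9, -5.5, 1.1, 0, 10),
    stringsAsFactors = FALSE)
}

# two parental-origin gametes (1 = mutant parent) for loci at sorted cM
# positions on one linkage group: a Markov chain of crossovers with
# per-interval recombination = inverse Kosambi of the cM gap
f2_gametes <- function(sorted_cm) {
  k <- length(sorted_cm)
  r_gap <- kosambi_r(diff(sorted_cm))
  gam <- vapply(1:2, function(g) {
    origin <- integer(k)
    origin[1L] <- stats::rbinom(1L, 1L, 0.5)
    if (k > 1L) {
      for (i in 2:k) {
        flip <- stats::rbinom(1L, 1L, r_gap[i - 1L])
        origin[i] <- if (flip == 1L) 1L - origin[i - 1L] else
          origin[i - 1L]
      }
    }
    origin
  }, integer(k))
  matrix(gam, nrow = k)
}

#' Simulate an F2 marker genotype and phenotype table
#'
#' F2 individuals are built from two parental gametes; each linkage group
#' is simulated as a Markov chain of crossovers whose per-interval
#' recombination fractions are the inverse-Kosambi of the cM gaps (the
#' trait locus sits at 0 cM in group 1).  Genotypes are coded A
#' (wild-parent homozygote), H (heterozygote), B (mutant-parent
#' homozygote); the phenotype is mutant iff the trait genotype is
#' homozygous recessive.
#'
#' @param config a [sim_config()] (uses `n_f2` and the master seed).
#' @param marker_map data.frame(marker, group, cm); group 1 contains the
#'   trait locus at 0 cM.  Negative cm = other side of the trait locus.
#' @return data.frame: id, phenotype ("mutant"/"normal"), one A/H/B
#'   column per marker.
#' @export
simulate_marker_table <- function(config, marker_map = default_marker_map()) {
  stopifnot(all(c("marker", "group", "cm") %in% names(marker_map)))
  if (any(!is.finite(marker_map$cm))) stop("marker cM must be finite")
  set.seed(stage_seed(config$seed, "markers"))
  n <- config$n_f2
  trait_group <- min(marker_map$group)
  groups <- split(marker_map, marker_map$group)
  geno <- matrix(NA_character_, n, nrow(marker_map),
                 dimnames = list(NULL, marker_map$marker))
  phenotype <- character(n)
  for (ind in seq_len(n)) {
    for (gm in groups) {
      with_trait <- gm$group[1L] == trait_group
      # lay out loci left to right; the trait locus is an extra locus
      # at 0 cM on its group
      loci <- gm$marker
      pos <- gm$cm
      if (with_trait) {
        loci <- c(loci, ".trait")
        pos <- c(pos, 0)
      }
      ord <- order(pos)
      gam <- f2_gametes(pos[ord])
      gsum <- rowSums(gam)                    # 0/1/2 mutant alleles
      names(gsum) <- loci[ord]
      if (with_trait) {
        phenotype[ind] <- if (gsum[[".trait"]] == 2L) "mutant" else
          "normal"
      }
      mk <- setdiff(names(gsum), ".trait")
      geno[ind, mk] <- c("A", "H", "B")[gsum[mk] + 1L]
    }
  }
  out <- data.frame(id = seq_len(n), phenotype = phenotype,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(geno, stringsAsFactors = FALSE))
}

#' Simulate a natural-panel genotype table
#'
#' Every panel line is homozygous for the wild-type allele at the causal
#' SNP and at every other EMS-induced site (induced mutations are private
#' to the mutant line); shared background variants segregate in the panel
#' at intermediate frequencies.  Optionally injects carrier lines at the
#' causal SNP as a negative control for the uniqueness screen.
#'
#' @param config a [sim_config()].
#' @param bulks result of [simulate_bulk_depths()] (defines the sites).
#' @param inject_carriers number of panel lines made heterozygous for the
#'   causal allele (default 0).
#' @return integer matrix lines x sites of alt-allele counts (0/1/2),
#'   columns named "chrom:pos", rows named line ids.
#' @export
simulate_panel <- function(config, bulks, inject_carriers = 0L) {
  set.seed(stage_seed(config$seed, "panel"))
  n <- config$n_panel
  mt <- bulks$mutant
  keys <- site_key(mt$chrom, mt$pos)
  panel <- matrix(0L, n, nrow(mt),
                  dimnames = list(sprintf("line%03d", seq_len(n)), keys))
  # shared background variants (alt allele present in the WT parent)
  # segregate in the panel; EMS-induced sites are private to the mutant
  wt_alt_keys <- site_key(bulks$wt$chrom, bulks$wt$pos)[
    bulks$wt$alt_depth > 0L]
  is_background <- keys %in% wt_alt_keys
  for (j in which(is_background)) {
    f <- stats::runif(1L, 0.1, 0.9)
    panel[, j] <- stats::rbinom(n, 2L, f)
  }
  if (inject_carriers > 0L) {
    causal_key <- site_key(bulks$causal$chrom, bulks$causal$pos)
    panel[seq_len(inject_carriers), causal_key] <- 1L
  }
  panel
}

#' Simulate a qPCR Ct table
#'
#' Ct = baseline - log2(true expression) + normal noise; the reference
#' gene has constant expression across all samples and conditions.  In
#' the "feedback" design the target's expression is multiplied by
#' `feedback_fold` in the wild type under treatment only (hormone
#' feedback represses the biosynthesis gene), while the mutant does not
#' respond.
#'
#' @param config a [sim_config()] (master seed).
#' @param organs sample names (default c("root", "stem", "leaf",
#'   "flower")).
#' @param target,reference gene names.
#' @param n_bio,n_tech biological and technical replicates (default 3
#'   and 3).
#' @param baseline_ct target Ct at expression 1 (default 24); the
#'   reference gene sits at `baseline_ct - 4`.
#' @param feedback_fold expression multiplier in WT under treatment
#'   (default 0.25, i.e. 4-fold repression).
#' @param bio_sd,tech_sd biological and technical Ct noise SDs (defaults
#'   0.2 and 0.1 cycles).
#' @return Ct data.frame (sample, condition, gene, bio_rep, tech_rep,
#'   ct) with conditions "WT:mock", "WT:BL", "mutant:mock", "mutant:BL".
#' @export
simulate_ct_table <- function(config,
                              organs = c("root", "stem", "leaf", "flower"),
                              target = "target", reference = "ref_gene",
                              n_bio = 3L, n_tech = 3L,
                              baseline_ct = 24, feedback_fold = 0.25,
                              bio_sd = 0.2, tech_sd = 0.1) {
  set.seed(stage_seed(config$seed, "ct"))
  conditions <- c("WT:mock", "WT:BL", "mutant:mock", "mutant:BL")
  rows <- list()
  for (organ in organs) {
    for (cond in conditions) {
      expr_target <- if (cond == "WT:BL") feedback_fold else 1
      for (b in seq_len(n_bio)) {
        bio_shift <- stats::rnorm(1L, 0, bio_sd)
        for (gene in c(target, reference)) {
          base <- if (gene == reference) baseline_ct - 4 else
            baseline_ct - log2(expr_target)
          truth <- base + if (gene == reference) 0 else bio_shift
          for (t in seq_len(n_tech)) {
            rows[[length(rows) + 1L]] <- data.frame(
              sample = organ, condition = cond, gene = gene,
              bio_rep = b, tech_rep = t,
              ct = truth + stats::rnorm(1L, 0, tech_sd),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a homolog protein family down a known tree
#'
#' Evolves a random root protein along a random (or supplied) tree by a
#' simple equal-rates substitution process: on a branch of length `b`
#' each site substitutes with probability `1 - exp(-b)` to a uniformly
#' drawn different residue.  No indels, so the sequences are trivially
#' aligned.  Used to exercise distance, NJ and bootstrap code with a
#' known generating topology.
#'
#' @param n_taxa number of sequences (default 16).
#' @param n_sites alignment length (default 300).
#' @param tree optional "phylo" tree with branch lengths; default
#'   [ape::rtree()] with branch lengths scaled by `scale`.
#' @param scale branch-length scale for the default random tree.
#' @param seed RNG seed.
#' @return list: `alignment` (named character vector), `tree` (the true
#'   "phylo").
#' @export
simulate_protein_family <- function(n_taxa = 16L, n_sites = 300L,
                                    tree = NULL, scale = 0.1, seed = 1L) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  if (is.null(tree)) {
    tree <- ape::rtree(n_taxa)
    tree$edge.length <- tree$edge.length * scale
  }
  n_nodes <- max(tree$edge)
  seqs <- vector("list", n_nodes)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  seqs[[root]] <- sample(aa, n_sites, replace = TRUE)
  # edges in preorder so parents are simulated before children
  ord <- order(match(tree$edge[, 1L], c(root, tree$edge[, 2L])))
  for (e in ord) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    p_sub <- 1 - exp(-tree$edge.length[e])
    s <- seqs[[parent]]
    hit <- stats::runif(n_sites) < p_sub
    if (any(hit)) {
      s[hit] <- vapply(s[hit], function(x) sample(setdiff(aa, x), 1L),
                       character(1))
    }
    seqs[[child]] <- s
  }
  tips <- seq_len(ape::Ntip(tree))
  alignment <- setNames(
    vapply(tips, function(i) paste(seqs[[i]], collapse = ""),
           character(1)),
    tree$tip.label)
  list(alignment = alignment, tree = tree)
}
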