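#' Run the full causal-SNP mapping pipeline on synthetic data
#'
#' Chains every stage of the bulked-segregant workflow: genome and gene
#' models, EMS mutations with one planted stop-gain, pooled bulk and
#' parent allele depths, mutant-specific site derivation, SNP-index
#' sliding windows, candidate-region calling, effect annotation, the
#' four-stage filter cascade on the top region, and the natural-panel
#' uniqueness screen of every cascade survivor.
#'
#' @param config a [sim_config()].
#' @param keep_genome if FALSE the (large) genome object is dropped from
#'   the result to save memory in repeated runs.
#' @return list with the intermediate products plus:
#'   `causal` (the planted site), `survivors` (cascade survivors with a
#'   `panel_verdict` column), `funnel`, `top_region`, and `recovered`
#'   (TRUE when the planted SNP is the unique cascade survivor and is
#'   flagged "unique" in the panel).
#' @export
run_mutmap_pipeline <- function(config, keep_genome = TRUE) {
  genome <- simulate_genome(config)
  mutations <- simulate_ems_mutations(genome, config)
  bulks <- simulate_bulk_depths(genome, mutations, config)
  panel <- simulate_panel(config, bulks)
  sites <- derive_mutant_specific_sites(bulks$mutant, bulks$wt)
  windows <- sliding_window(sites, k = config$window_size)
  regions <- call_candidate_region(windows,
                                   threshold = config$index_threshold)
  causal <- bulks$causal
  out <- list(config = config, mutations = mutations,
              causal = causal, sites = sites, windows = windows,
              regions = regions)
  if (keep_genome) out$genome <- genome
  if (nrow(regions) == 0L) {
    out$recovered <- FALSE
    out$survivors <- data.frame()
    return(out)
  }
  top_region <- regions[1L, ]
  in_region <- sites[sites$chrom == top_region$chrom &
                       sites$pos >= top_region$start &
                       sites$pos <= top_region$end, , drop = FALSE]
  # annotation is only needed for sites that can reach cascade stage 2
  effects <- annotate_effects(in_region, genome$genes, genome)
  casc <- filter_cascade(effects, top_region,
                         min_index = config$min_index,
                         min_alt_depth = config$min_alt_depth)
  # restore the true stage-1 count (sites genome-wide entering the
  # region filter), since annotation was restricted to the region
  casc$funnel$n[casc$funnel$stage == "input"] <- nrow(sites)
  survivors <- casc$survivors
  if (nrow(survivors) > 0L) {
    screens <- lapply(seq_len(nrow(survivors)), function(i) {
      panel_uniqueness_screen(survivors[i, ], panel)
    })
    survivors$panel_carriers <- vapply(screens, `[[`, numeric(1),
                                       "n_carriers")
    survivors$panel_verdict <- vapply(screens, `[[`, character(1),
                                      "verdict")
  }
  recovered <- nrow(survivors) == 1L &&
    nrow(causal) == 1L &&
    survivors$chrom[1L] == causal$chrom &&
    survivors$pos[1L] == causal$pos &&
    identical(survivors$panel_verdict[1L], "unique")
  out$top_region <- top_region
  out$effects <- effects
  out$funnel <- casc$funnel
  out$survivors <- survivors
  out$panel <- panel
  out$recovered <- recovered
  out
}
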