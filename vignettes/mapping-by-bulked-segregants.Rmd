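---
title: "Methods: mapping an EMS-induced recessive mutation by bulked-segregant SNP-index analysis"
author: "mutseek"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping by bulked segregants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutseek)
```

# The problem

A chemically mutagenized plant line segregates a recessive phenotype
(here, an extreme dwarf).  EMS produces almost exclusively G:C→A:T
transitions, scattered at a density of a few tenths of a mutation per
kb, and exactly one of them is causal.  The mapping strategy implemented
here chains seven classical steps:

1. **Segregation tests** — χ² goodness-of-fit of F2 phenotype counts
   against 3:1, and F3 progeny tests to infer F2 genotypes.
2. **Bulked-segregant SNP-index mapping** (the modified-MutMap design) —
   a bulk of homozygous-recessive F2 plants and the wild-type parent are
   both sequenced against the same public reference; sites where the
   bulk carries an alternate allele that the parent lacks are the
   induced candidates.  The *SNP index* of a site is the fraction of
   reads carrying the mutant allele; in a recessive bulk it is ~0.5 at
   unlinked sites and approaches 1 near the causal locus.
3. **Windowing and region calling** — indices are averaged over a moving
   window of five consecutive SNPs, shifted one SNP at a time, with each
   window plotted at the midpoint of its first and fifth member; maximal
   runs of windows above a threshold become candidate regions.
4. **Effect annotation and filtering** — candidates inside the region
   are mapped onto gene models (strand-aware, spliced coordinates),
   translated, and filtered in fixed order: in region → exonic →
   non-synonymous → homozygous in the pool.
5. **Natural-panel uniqueness** — an induced causal allele must be
   absent from a large panel of unrelated lines.
6. **Marker work** — dCAPS/CAPS design to genotype the SNP by
   allele-specific restriction digestion, plus F2 linkage mapping with
   the Kosambi function and LOD-based grouping.
7. **Downstream biology** — NJ phylogeny of the candidate's protein
   family with bootstrap support, and 2^-ΔΔCt expression contrasts that
   detect hormone-feedback repression.

Every step is a package function; the `analysis/` scripts are thin
narrative drivers, and `run_mutmap_pipeline()` chains steps 2–5.

# The synthetic study design

The sequencing data behind such a study is rarely deposited, so the
package ships a first-class generator whose defaults *are* the study
design, at desk scale:

| parameter | default | rationale |
|---|---|---|
| genome | 7 × 500 kb | multi-chromosome structure at ~1/700 physical scale |
| genetic map | 200 cM/Mb | preserves per-chromosome genetic length (~100 cM), see below |
| EMS rate | 0.3 /kb | the measured genome-wide transition density |
| causal lesion | stop-gain, codon 157 of a 1392-bp, 9-exon CDS | the cloned candidate gene's geometry (463 residues, TGG→TAG) |
| bulk | 42 plants, Poisson(30×) depth | pooled homozygous-recessive F2 plants |
| F2 population | 184 plants | the mapping population size |
| panel | 412 lines | the uniqueness screen |
| genes | 6 per chromosome, evenly spaced | see calibration below |

**Genetic scale.**  Shrinking a ~50-Mb chromosome to 500 kb while
keeping a literal ~3 cM/Mb would compress a whole chromosome into
1.5 cM: every site would be fully linked to the causal locus and the
SNP-index curve would be flat at 1 across the chromosome, which destroys
the phenomenon being emulated.  What matters for segregation structure
is the *genetic* length, so the generator fixes 200 cM/Mb, giving each
synthetic chromosome ~100 cM — the scale of a real plant chromosome.
Physical positions are mapped to recombination fractions through the
inverse Kosambi function.

**One lesion per causal gene.**  The generator plants exactly one
mutation (the stop-gain) in the designated gene's CDS and resamples any
random draw that lands there.  This mirrors the emulated situation — the
cloned mutant CDS differed from wild type at a single site — and it is
the condition under which the filter cascade can funnel to exactly one
survivor.

**Gene layout calibration.**  The generator must satisfy a designed-in
recovery property: with defaults, the planted SNP is the *unique*
cascade survivor in ≥95 of 100 seeded runs.  At 0.3 mutations/kb, a
neighboring gene at distance *d* contributes competing non-synonymous
survivors at a rate governed by P(snp_index ≥ 0.95) at its recombination
fraction; at 12.5 cM that probability is ~0.1 per site and measurably
erodes uniqueness, while at ~17 cM it is negligible and the 0.9-window
candidate region (~±12 cM) no longer reaches the neighbor.  Six evenly
spaced genes per 500-kb chromosome (~83 kb ≈ 17 cM spacing) therefore
implement the designed recovery rate; denser layouts emulate real gene
density better but deliberately trade away single-site resolution, as
real studies do when they report several surviving exonic SNPs and
resolve them with panel data.

**Sub-seeded stages.**  One master seed drives everything; each stage
(genome, mutations, depths, markers, panel, Ct, proteins) derives its
own seed via `stage_seed()`, so stages can be regenerated independently
and all outputs are bit-reproducible.

**What the generator does not emulate:** read-level errors, mapping
artifacts, indels and structural variants, copy-number variation,
segregation distortion, variable recombination landscapes, and gene
density realistic for a plant genome.  Passing tests therefore
demonstrate the *logic* of the pipeline under the stated statistical
model, not robustness to the full messiness of real resequencing data.

# Numerical and design choices

**"SNP index = 1" with finite depth.**  At Poisson(30) depth, a site
fixed in the bulk still shows index < 1 whenever a stray reference read
appears, so a literal equality filter is fragile.  The operational rule
is `snp_index ≥ 0.95 AND alt_depth ≥ 10` (both configurable; a strict
`== 1` mode exists).  This preserves the intent — the mutant allele is
fixed in the bulk — while keeping the filter stable under binomial
sampling.

**Uncorrected χ².**  Segregation tests use the plain Pearson statistic
with no Yates correction: the published P-values (0.16, 0.18) for the
two F2 populations are reproduced only by the uncorrected statistic
(χ² = 1.94 → P = 0.164; χ² = 1.73 → P = 0.188).  Ratios are accepted as
arbitrary positive weights so 15:1 or 9:3:3:1 designs reuse the same
code.

**Heterozygous parent calls.**  A site where the wild-type parent looks
heterozygous (alt fraction between 0.1 and 0.9) is treated as shared
background and removed — only the homozygous contrast defines a
mutant-specific site.  Sites with no parent coverage are likewise
dropped rather than guessed.

**Candidate-region ties.**  Regions are ranked by peak window index,
then length, then (chromosome, start) — a fixed ordering so repeated
runs produce identical reports.

**Linkage estimation.**  The trait locus is a fully penetrant recessive
scored by phenotype, so only mutant-class plants inform marker–trait
recombination: each of their 2n marker alleles is an independent
Bernoulli(r) recombinant, giving the closed-form MLE k/2n (truncated at
0.5) and a binomial LOD.  Marker–marker r uses an EM over the
phase-ambiguous double-heterozygote class.  Ordering within a linkage
group is exhaustive to 8 markers (adequate for SSR framework maps) and
greedy seriation beyond; orientation of a group is arbitrary.

**dCAPS search.**  Primer mismatches are restricted to the last five
primer bases excluding the 3′-terminal base (standard dCAPS practice, so
extension is not compromised), at most one by default.  A natural CAPS
(zero mismatches) is always preferred.  Every returned assay is verified
by in-silico digestion of both allele amplicons: the cut allele must
give ≥2 fragments, the uncut allele exactly one, and fragment lengths
must sum to the amplicon length.  Tm is reported by the advisory 2+4
rule only.  The default amplicon (254 bp) and the Dde I entry (C^TNAG,
cut offset 1) in the editable enzyme library match the scale of the
published assay (254 → 19 + 235 bp in the mutant).

**NJ details.**  Distances default to the p-distance with pairwise gap
deletion (the common default for protein NJ trees); Poisson correction
and complete deletion are selectable.  The Saitou–Nei Q-criterion is
minimized with a deterministic first-minimum tie-break; negative limb
estimates are clamped to zero with the deficit moved to the sibling limb
so pairwise path lengths are preserved, and the count of clamped limbs
is attached to the tree.  Bootstrap support resamples alignment columns
with replacement and counts identical leaf bipartitions.

**2^-ΔΔCt.**  Technical replicates are collapsed by arithmetic mean of
Ct; biological replicates are the unit of inference.  Amplification
efficiency is fixed at 100% (base 2).  Condition-level fold change is
computed from the mean ΔCt, which makes the calibrator's fold exactly 1
by construction.  Group comparisons are two-sided Welch t-tests on ΔCt
(approximately normal), not on folds, flagged at α = 0.01; no
multiple-testing correction is applied across organs, matching
per-contrast reporting (a BH option would be a one-line extension).

# Problem sizes

The shipped configuration runs one full pipeline pass (3.5 Mb genome,
~1050 mutations, 42-plant bulk, 412-line panel) in about a second, so
the recovery property is verified over 100 seeded runs in the test
suite.  Oracle checks use 50 random additive matrices (≤10 taxa), 1000
random SNP annotations against a translation-diff oracle, 200 replicate
recombination recoveries at n = 130, and exact ΔΔCt round-trips at zero
noise — all sizes chosen to give tight Monte-Carlo error at interactive
runtimes.

# Known limitations

- One transcript per gene; UTR and splice-site effects are not modeled
  (exonic-but-noncoding sites are labeled and fail the non-synonymous
  filter by design).
- Only substitution SNPs; no indels anywhere in the chain.
- The ΔSNP-index two-bulk design (QTL-seq) is out of scope.
- Dominant markers are not modeled in linkage estimation.
- The recovery guarantee is a property of the synthetic design, not a
  claim about arbitrary real data sets; with realistic gene density the
  cascade ends with a handful of survivors and the panel screen (or
  co-segregation) must finish the job, exactly as in practice.
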