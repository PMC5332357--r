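# mutseek

Forward-genetic mapping of EMS-induced recessive mutations from pooled
resequencing data, as an R package plus a scripted analysis workflow.

EMS mutagenesis scatters G:C→A:T transitions across a plant genome at a
few tenths of a mutation per kb; one of them causes the phenotype being
studied.  `mutseek` implements the computational chain that narrows
those thousands of candidates to a single nucleotide — for geneticists
running bulked-segregant / MutMap-style experiments and for method
developers who need a fully simulated, reproducible test bed.

The core statistic is the **SNP index** of a site in a bulk of
homozygous-recessive F2 plants,

    SNP index = alt_depth / (ref_depth + alt_depth),

which is ≈0.5 at sites unlinked to the causal locus and →1 as the
recombination fraction r → 0.  Indices are smoothed over a moving window
of five consecutive SNPs (plotted at the midpoint of the first and fifth
member), maximal runs of windows above a threshold define the candidate
region, and surviving sites are filtered in fixed order — in region →
exonic → non-synonymous → homozygous in the pool — then screened for
absence from a natural panel.  Around the core the package provides χ²
segregation tests, F3 progeny-test genotype inference, Kosambi linkage
mapping (d = 25 ln((1+2r)/(1−2r)) cM) with LOD grouping, dCAPS/CAPS
marker design with in-silico restriction digestion, neighbor-joining
protein phylogenies with bootstrap support, and 2^−ΔΔCt expression
analysis.  A synthetic-data module generates every input — genome, gene
models, mutations, pooled allele depths, marker/panel genotypes, protein
families, qPCR Ct tables — with the statistical structure of a recessive
bulked-segregant study.

## Worked example

```r
library(mutseek)

chi_square_ratio_test(c(448, 130))        # F2 counts vs 3:1
#> Segregation goodness-of-fit
#>   observed: 448 : 130
#>   expected: 433.5 : 144.5
#>   chi2 = 1.9400, df = 1, P = 0.1637 (0.16)

res <- run_mutmap_pipeline(sim_config(seed = 1))
res$funnel
#>                stage    n
#> 1              input 1052
#> 2          in_region   30
#> 3             exonic    1
#> 4     non_synonymous    1
#> 5 homozygous_in_pool    1
res$survivors[, c("chrom", "pos", "codon_number", "effect",
                  "snp_index", "panel_verdict")]
#>     chrom    pos codon_number      effect snp_index panel_verdict
#> 662  chr5 207581          157 stop_gained         1        unique

design_dcaps(res$genome, res$survivors[1, ])
#> dCAPS assay with DdeI (CTNAG)
#>   primer (20 nt, Tm ~54 C): TGCAAACCGACTTTATTCTT
#>   engineered mismatch at primer position(s): 19
#>   amplicon 254 bp; ref allele: 254 | alt allele: 18 + 236 (alt cut)
```

Reading the output: of 1052 mutant-specific SNPs, 30 fall inside the
candidate region called from the SNP-index curve on chr5; exactly one is
exonic, non-synonymous and fixed in the bulk — the planted G→A that
converts a TGG tryptophan codon at position 157 into a TAG stop — and no
line of the 412-line panel carries it.  The dCAPS design genotypes that
SNP: one engineered primer mismatch creates a Dde I site on the mutant
allele only, so the 254-bp amplicon digests into two fragments for the
mutant and stays intact for the wild type.

## The analysis workflow

Numbered drivers under `analysis/` run the whole study and write tables
under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates the full synthetic data set (FASTA, GFF3, VCFs, TSVs, CSV) |
| `02_segregation.R` | χ² tests of the F2 counts; F3 progeny tests |
| `03_mutmap.R` | SNP-index scan, candidate region, filter cascade, panel screen |
| `04_markers.R` | dCAPS assay, BSA marker screen, Kosambi linkage map |
| `05_phylo_expression.R` | NJ + bootstrap phylogeny, percent identity, ΔΔCt feedback report |

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

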