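# codonbias

Organism-scale codon usage bias profiling for prokaryotic genomes.

Synonymous codons are used unevenly among the genes of a genome. In
organisms under translational selection, highly expressed genes — well
proxied by the ribosomal-protein genes — are enriched for a specific set of
preferred codons, while weakly expressed genes are dominated by mutational
(GC) pressure. `codonbias` quantifies how strong that within-genome contrast
is for each organism, and provides the statistical layer to relate it to
lifestyle traits (pathogenicity, oxygen requirement, salinity, temperature
range, habitat breadth), growth rate and phylogeny. It is aimed at
comparative microbial genomics: the input is one CDS set per organism
(FASTA or GenBank), a phenotype annotation table and, optionally, a newick
tree.

## Measures

Per gene:

* **CAI** (Codon Adaptation Index, Sharp & Li): the geometric mean of
  relative-adaptiveness weights `w_c = f_c / f_max` over the gene's codons,
  where frequencies come from the pooled ribosomal-protein genes. Met, Trp
  and stop codons are excluded. CAI ∈ (0, 1]; 1 means every codon is the
  reference set's preferred codon.
* **Nc** (Wright's effective number of codons): per synonymous family the
  homozygosity `F̂ = (n·Σp² − 1)/(n − 1)` is estimated and class means are
  combined as `Nc = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆`, capped into
  [20, 61]. 20 = one codon per amino acid (maximal bias), 61 = uniform
  usage.

Per organism (`profile_genome()`):

* **CAI_ave** — mean CAI over all genes. *Low* CAI_ave marks a *biased*
  genome: preferred codons are confined to the highly expressed genes, so
  most genes score low against the ribosomal reference. High CAI_ave marks
  an unbiased genome.
* **cai_cv** — coefficient of variation of per-gene CAI (SD / CAI_ave).
* **Nc_diff** — `(Nc(all) − Nc(rib)) / Nc(all)`, the relative drop in
  effective codon number of the ribosomal genes versus the rest of the
  genome; large values mark strong bias.
* **codon_freq_diff** — mean absolute within-family codon frequency
  difference between ribosomal and non-ribosomal genes.
* **gc** — CDS GC content, used by `gc_filter()` to exclude organisms with
  extreme GC (outside 35–65%), which are structurally unbiased.

A bundled mutation–selection simulator (`simulate_genome()`) generates
prokaryote-like CDS sets with known ground truth: codons are drawn within
each family from `P(c) ∝ μ_c · exp(S · x_g · δ_c)`, with GC pressure
`μ_c = θ^gc(c) (1−θ)^(3−gc(c))`, selection strength `S`, per-gene expression
`x_g` and an organism-specific preferred-codon map (`δ_c = 1` for the
preferred codon). It produces biased and unbiased genome archetypes, GC
extremes, labelled cohorts and validation panels on demand.

## Worked example

```r
library(codonbias)

g0 <- simulate_genome(simulation_config(S = 0, theta = 0.5, seed = 11),
                      organism_id = "unbiased")
g4 <- simulate_genome(simulation_config(S = 4, theta = 0.5, seed = 12),
                      organism_id = "biased")
profiles <- rbind(as.data.frame(profile_genome(g0$genes, "unbiased")),
                  as.data.frame(profile_genome(g4$genes, "biased")))
profiles[, c("organism_id", "cai_ave", "cai_cv", "nc_rib", "nc_all",
             "nc_diff", "gc", "codon_freq_diff")]
#>  organism_id cai_ave  cai_cv nc_rib nc_all nc_diff    gc codon_freq_diff
#>     unbiased   0.928 0.00551   60.0   60.2 0.00276 0.469          0.0185
#>       biased   0.283 0.90567   21.7   51.5 0.57953 0.475          0.2499
```

Without selection (`S = 0`) every gene uses the same mutational codon
distribution: CAI_ave is high, its dispersion is negligible and the
ribosomal genes are indistinguishable from the rest (Nc_diff ≈ 0). Under
strong selection (`S = 4`) the ribosomal genes collapse onto the preferred
codons (Nc(rib) ≈ 21.7 versus Nc(all) ≈ 51.5, Nc_diff ≈ 0.58) while most
genes do not, so CAI_ave drops to 0.28 and the codon frequency difference
rises tenfold — the biased-genome archetype.

Downstream, `compare_trait_groups()` contrasts CAI_ave across phenotype
groups (Mann-Whitney for two groups, Kruskal-Wallis for more),
`partial_correlation()` disentangles growth rate, habitat breadth and bias,
and `bias_distance_correlation()` relates pairwise |ΔCAI_ave| to patristic
distances on a tree.

A thin command-line wrapper is installed at
`system.file("cli", "codonbias.R", package = "codonbias")` with subcommands
`profile`, `simulate`, `compare` and `phylo`.

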