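---
title: "Measuring organism-scale codon usage bias: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring organism-scale codon usage bias: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

## The question and the measures

An organism is *biased* in its codon usage when the synonymous-codon
distribution of its highly expressed genes differs from that of the rest of
its genes — the signature of translational selection. It is *unbiased* when
all genes share one codon distribution, whether because selection is absent
or because extreme GC content leaves little synonymous freedom. `codonbias`
summarises each genome by the contrast between its ribosomal-protein genes
(the standard proxy for high expression) and everything else.

**CAI.** The relative adaptiveness of codon *c* in family *a* is
$w_c = f_c / \max_{c' \in a} f_{c'}$, with frequencies taken from the codon
counts pooled over the ribosomal genes. A gene's CAI is the geometric mean
of $w_c$ over its codon occurrences. Conventions (all configurable):

* Met, Trp and stop codons are excluded — single-codon families carry no
  synonymous-choice signal.
* Reference-absent codons get a pseudo-weight of 0.01 rather than 0, which
  would send the geometric mean of any gene using them to exactly 0. A
  family entirely absent from the reference set has all its codons set to
  the pseudo-weight, with a warning.
* The mean is computed in log space; long genes would underflow a direct
  product of sub-unity weights.

**Nc.** Wright's estimator treats each synonymous family like a locus and
its codons like alleles. For a family with $n \ge 2$ counted codons and
proportions $p_i$, the codon homozygosity is
$\hat F = (n \sum_i p_i^2 - 1)/(n - 1)$; class means $\bar F_k$ over the
families of degeneracy $k$ give
$N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$.
Decisions where the estimator needs completing:

* Families with $\hat F \le 0$ or $n < 2$ are excluded from their class
  mean.
* The sole 3-fold family (Ile) often yields no estimate in short genes;
  $\bar F_3$ is then imputed as $(\bar F_2 + \bar F_4)/2$ (Wright's
  recommendation). A missing 6-fold class is imputed as $\bar F_4$, the
  symmetric extension. If the 2-fold or 4-fold class is missing the gene's
  Nc is undefined.
* The 6-fold families (Leu, Ser, Arg) are kept as one degeneracy class
  contributing $3/\bar F_6$, not split into 2+4 sub-families.
* Sampling noise inflates the raw estimate above the theoretical maximum of
  61 (a gene using all 61 sense codons 100 times each scores ≈ 61.4), so
  results are capped into [20, 61]. Genes with fewer than 30 codons in
  degenerate families are reported as undefined: the estimator is too noisy
  below that.

**Organism measures.** `profile_genome()` reports the mean and median CAI
over *all* genes (`cai_ave`, `cai_median`), the coefficient of variation of
CAI (sample SD, $n-1$ denominator, divided by `cai_ave`), the mean Nc of the
ribosomal genes (`nc_rib`) and of the *non-ribosomal* genes (`nc_all`), and
`nc_diff = (nc_all - nc_rib)/nc_all`. Note the deliberate asymmetry:
`cai_ave` averages over all genes while `nc_all` averages over the rest of
the genome only; both follow the conventional definitions of these
organism-scale measures. GC content is computed over the concatenated
retained CDS — not the whole chromosome; for prokaryotes, whose genomes are
mostly coding, the difference is small.

**Codon frequency difference.** For each sense codon of a degenerate family
present in both gene sets, the codon's within-family frequency is computed
once in the ribosomal genes and once in the rest; the statistic is the mean
*absolute* difference over those codons. A signed mean would cancel exactly
within every family (the differences of a family sum to zero), so a
magnitude measure is the only informative reading. Codons of families
missing from either side are skipped rather than counted as zero-frequency,
which would manufacture signal from sparse families.

## Statistical layer

Group contrasts of organism measures use rank tests: Mann-Whitney for two
groups (exact null distribution when both groups are ≤ 8 and tie-free,
otherwise the tie-corrected normal approximation with continuity
correction), Kruskal-Wallis above two. All tests are two-sided by default.
When every observation is tied the Kruskal-Wallis statistic is 0 and p = 1
by convention (the tie-corrected statistic is 0/0). Trait interdependence
uses the Pearson chi-square without continuity correction; expected cell
counts below 5 trigger a warning rather than an error.

Correlations are Pearson; a binary trait such as the habitat code
(0 = multiple habitats, 1 = specialized) enters as a 0/1 numeric, i.e. the
point-biserial correlation. First-order partial correlations use
$r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}$
with a t test on $n-3$ degrees of freedom — the standard inference for a
single controlled variable.

Phylogenetic distance between two organisms is the patristic distance: the
path length through their most recent common ancestor, computed from the
tree's branch lengths. `bias_distance_correlation()` correlates pairwise
|ΔCAI_ave| with patristic distance over all unordered pairs; absence of
correlation argues that bias tracks lifestyle, not ancestry. Trees without
branch lengths get unit lengths (with a warning) so topology-only trees
remain usable. For redundancy-reduced robustness subsets,
`select_remote_taxa()` applies a greedy maximin rule on patristic distance
with an optional distance floor — a deterministic, documented stand-in for
"phylogenetically remote" subset choices whose original selection rules are
rarely reported.

## The simulator: what it emulates

`simulate_genome()` draws each gene's amino acids i.i.d. (uniform over the
20 by default) and each codon within its family from

$$P(c) \;\propto\; \theta^{g(c)} (1-\theta)^{3-g(c)} \;
  e^{S\, x_g\, \delta_c},$$

where $g(c)$ is the codon's G+C count, $\theta \in (0,1)$ the mutational GC
pressure, $S \ge 0$ the genome's translational selection strength,
$x_g \in [0,1]$ the gene's expression level and $\delta_c$ indicates the
family's preferred codon, one per family, drawn uniformly per genome
(preferred codons are organism-specific in nature, tracking the tRNA pool).
ATG/TAA are added as start/stop.

Defaults, chosen once as a desk-scale stand-in for a prokaryotic genome:

* `n_genes = 300`, `n_ribosomal = 40`: far fewer genes than a real genome
  (~2,000–4,000), but enough that organism measures are stable, while a
  40-gene ribosomal set matches the size of real ribosomal-protein
  complements (~50) and estimates the weight table well.
* Gene lengths log-normal with median 300 codons (sdlog 0.5, clipped to
  [60, 2000]) — the shape of prokaryotic CDS length distributions.
* Expression: ribosomal genes pinned at $x = 1$; other genes draw
  $x \sim \mathrm{Beta}(1, 4)$ (mean 0.2, right-skewed). Only a small group
  of genes being highly expressed is the premise that makes a selected
  genome *look* biased: if most genes were highly expressed, all genes
  would adopt the preferred codons and CAI_ave would stay high.
* A single preferred codon per family rather than graded preferences — the
  simplest model producing the biased/unbiased contrast; graded maps are a
  configuration extension.

The model reproduces the qualitative genome-scale phenomenology: CAI_ave
decreases and Nc_diff, the CAI coefficient of variation and the codon
frequency difference all increase with $S$; and at extreme $\theta$ the
mutational term dominates the selection term for every gene, so genomes are
compressed into a narrow, high CAI_ave band regardless of $S$ — the
mechanism behind excluding extreme-GC organisms before lifestyle
comparisons.

What it does **not** emulate: amino-acid composition differences between
genes, operon and strand structure, within-genome GC heterogeneity,
horizontal transfer, phylogenetic correlation between genomes (each genome
is independent), and any direct coupling between lifestyle and selection
strength — cohort labels in the validation tests are assigned by
construction. Passing tests therefore show that the measures recover a
known selection gradient and that the statistics are calibrated, not that
real lifestyle effects are of any particular size.

## Validation design and problem sizes

The test suite checks, at fixed seeds chosen in advance:

* analytic bounds (CAI = 1 for an all-preferred-codon gene; Nc = 20 for a
  one-codon-per-family gene; Nc = 61 capped for uniform usage);
* agreement of `nc()` with an independently coded homozygosity oracle on
  1,000 random genes (≤ 1e-9, pre-cap) and of `cai()` with a direct-product
  geometric mean on 100 short genes (≤ 1e-12) — the direct product is exact
  in double precision at 30 codons, making it an independent route to the
  log-space implementation;
* parameter recovery on a 40-genome panel with $S$ evenly spaced over
  [0, 5] at $\theta = 0.5$: Spearman(CAI_ave, S) ≤ −0.9,
  Spearman(Nc_diff, S) ≥ 0.9, and Pearson couplings CAI_ave–Nc_diff ≤ −0.7,
  CAI_ave–CV ≤ −0.6, CAI_ave–codon_freq_diff ≤ −0.7;
* GC compression: a $\theta = 0.9$ panel has a higher minimum and narrower
  range of CAI_ave than the $\theta = 0.5$ panel on the same $S$ grid;
* cohort direction: 20 genomes at $S = 0$ versus 20 at $S = 4$ give
  Mann-Whitney p < 0.01 with the selected cohort's median CAI_ave lower;
* a null phylogeny check: CAI_ave assigned independently of a 50-leaf
  random tree gives |r| < 0.15 between pairwise |ΔCAI_ave| and patristic
  distance (1,225 pairs);
* calibration: Mann-Whitney and Kruskal-Wallis type-I error within
  [0.03, 0.07] at α = 0.05 over 1,000 null replicates, and partial
  correlation recovering |r| < 0.05 when x ⊥ y | z by construction
  (n = 2,000).

Panel genomes use the simulator defaults (300 genes); smaller module-level
checks use 60–100 genes, the minimum at which organism profiles are stable.
These sizes keep the whole suite at a few minutes on one core while leaving
each correlation threshold far from its observed value.

## Degenerate inputs and edge behaviour

Genes failing validation (length not a multiple of 3, ambiguous codons
exceeding 10%) are excluded from all metrics and never repaired; codons
containing ambiguity codes are skipped and tallied. A gene with no codon
from a degenerate family has undefined CAI; undefined Nc arises from short
genes or missing essential degeneracy classes, and such genes are dropped
from the genome averages (not zero-filled). `profile_genome()` refuses to
run with fewer than 50 valid genes or fewer than 20 flagged ribosomal genes
— below that the weight table and the rib/rest contrast are unreliable.
Ribosomal-gene flagging by product text uses a case-insensitive
"ribosomal protein" match with an exclusion list for modification enzymes;
the exact curation rule behind published ribosomal reference sets is rarely
stated, so an explicit id list can always override the patterns.

## Known limitations

* CAI weights come solely from the ribosomal-gene proxy; expression-based
  reference sets are not implemented.
* No alternative bias measures (RSCU, tAI, CBI) and no multiple-testing
  layer across trait comparisons — comparisons are reported individually.
* The GenBank reader is a minimal flat-file parser (CDS features, join and
  complement locations, product qualifiers); it does not resolve
  cross-record references or fuzzy locations.
* Subspecies deduplication is out of scope: genome lists are assumed
  pre-deduplicated.
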