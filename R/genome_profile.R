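#' Organism-scale codon usage bias profile
#'
#' Computes the genome-level codon bias summary of one organism from its gene
#' table. The relative-adaptiveness weight table is built from the codon
#' counts pooled over the flagged ribosomal-protein genes (the proxy for
#' highly expressed genes); every valid gene (ribosomal included) then gets a
#' CAI, and every gene an Nc. The organism measures are:
#'
#' * `cai_ave` — mean CAI over all genes; low values mark *biased* genomes
#'   (preferred codons confined to highly expressed genes), high values
#'   unbiased genomes.
#' * `cai_median`, `cai_cv` — median CAI and coefficient of variation of the
#'   per-gene CAI values (sample SD divided by `cai_ave`).
#' * `nc_rib`, `nc_all` — mean Nc over ribosomal genes and over the *rest* of
#'   the genome (non-ribosomal genes), each over genes with defined Nc.
#' * `nc_diff` — `(nc_all - nc_rib) / nc_all`: the relative drop in effective
#'   codon number of the ribosomal genes; large values mark strong bias.
#' * `nc_avg_genome` — mean Nc over all genes.
#' * `gc` — GC fraction over all retained CDS, concatenated.
#' * `codon_freq_diff` — mean absolute within-family codon frequency
#'   difference between ribosomal and non-ribosomal genes
#'   ([codon_frequency_difference()]).
#'
#' @param records A gene table with `is_ribosomal` set (see
#'   [flag_ribosomal_genes()] or [simulate_genome()]).
#' @param organism_id Identifier written into the profile row.
#' @param pseudo Pseudo-weight for reference-absent codons.
#' @param min_ribosomal Minimum flagged ribosomal genes (default 20).
#' @param min_genes Minimum valid genes (default 50).
#' @param nc_min_codons Passed to [nc()].
#' @return A one-row data frame of class `genome_profile` with the columns
#'   above plus `n_genes` and `n_ribosomal`. The per-gene score table is
#'   attached as attribute `gene_scores`.
#' @export
profile_genome <- function(records, organism_id = "genome",
                           pseudo = 0.01, min_ribosomal = 20L,
                           min_genes = 50L, nc_min_codons = 30L) {
  records <- validate_genes(records)
  keep <- records[records$valid, , drop = FALSE]
  if (nrow(keep) < min_genes) {
    stopf("only %d valid genes (minimum %d)", nrow(keep), min_genes)
  }
  n_rib <- sum(keep$is_ribosomal)
  if (n_rib == 0L) stopf("no ribosomal genes flagged")
  if (n_rib < min_ribosomal) {
    stopf("only %d ribosomal genes flagged (minimum %d)", n_rib,
          min_ribosomal)
  }
  counts <- codon_count_matrix(keep$sequence)
  rib <- keep$is_ribosomal
  rib_counts <- colSums(counts[rib, , drop = FALSE])
  rest_counts <- colSums(counts[!rib, , drop = FALSE])
  weights <- reference_weights(rib_counts, pseudo = pseudo)

  cai_vals <- cai_matrix(counts, weights)
  nc_vals <- as.numeric(apply(counts, 1L, nc, min_codons = nc_min_codons))
  cai_def <- cai_vals[!is.na(cai_vals)]
  if (length(cai_def) == 0L) stopf("CAI undefined for every gene")
  cai_ave <- mean(cai_def)

  mean_def <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  nc_rib <- mean_def(nc_vals[rib])
  nc_all <- mean_def(nc_vals[!rib])
  nc_diff <- if (is.na(nc_rib) || is.na(nc_all)) NA_real_ else {
    (nc_all - nc_rib) / nc_all
  }
  if (is.na(nc_rib) || is.na(nc_all)) {
    warnf("Nc undefined for all genes of a gene class; nc_diff is NA")
  }

  profile <- data.frame(
    organism_id = organism_id,
    cai_ave = cai_ave,
    cai_median = stats::median(cai_def),
    cai_cv = stats::sd(cai_def) / cai_ave,
    nc_rib = nc_rib,
    nc_all = nc_all,
    nc_diff = nc_diff,
    nc_avg_genome = mean_def(nc_vals),
    gc = gc_content(keep$sequence),
    codon_freq_diff = codon_frequency_difference(rib_counts, rest_counts),
    n_genes = nrow(keep),
    n_ribosomal = n_rib,
    stringsAsFactors = FALSE
  )
  class(profile) <- c("genome_profile", "data.frame")
  attr(profile, "gene_scores") <- data.frame(
    gene_id = keep$gene_id,
    cai = cai_vals,
    nc = nc_vals,
    codons_used = as.integer(rowSums(counts)),
    is_ribosomal = rib,
    stringsAsFactors = FALSE
  )
  profile
}

#' Codon frequency difference between ribosomal and other genes
#'
#' For each sense codon of a degenerate family represented (family total
#' \eqn{\ge 1}) in *both* gene sets, computes the codon's frequency out of
#' the total codons encoding its amino acid, once in the ribosomal genes and
#' once in the rest, and returns the mean absolute difference over those
#' codons. Organisms under strong translational selection use different
#' codons in their highly expressed genes and therefore score high.
#'
#' @param rib_counts Pooled codon counts of the ribosomal genes.
#' @param rest_counts Pooled codon counts of the remaining genes.
#' @return Mean absolute within-family frequency difference (\eqn{\ge 0}).
#' @export
codon_frequency_difference <- function(rib_counts, rest_counts) {
  code <- genetic_code()
  fams <- code$families[code$degeneracy >= 2L]
  diffs <- numeric(0)
  for (fam in fams) {
    a <- setNames(numeric(length(fam)), fam)
    b <- a
    ha <- intersect(fam, names(rib_counts))
    hb <- intersect(fam, names(rest_counts))
    a[ha] <- as.numeric(rib_counts[ha])
    b[hb] <- as.numeric(rest_counts[hb])
    if (sum(a) < 1 || sum(b) < 1) next
    diffs <- c(diffs, abs(a / sum(a) - b / sum(b)))
  }
  if (length(diffs) == 0L) {
    stopf("no synonymous family is represented in both gene sets")
  }
  mean(diffs)
}

#' Filter genome profiles by GC content
#'
#' Retains organisms whose CDS GC content lies strictly between `lo` and
#' `hi`. Organisms with extreme GC content cannot attain low CAI_ave (their
#' nucleotide repertoire restricts ribosomal and other genes to the same
#' codons), so they are excluded before lifestyle comparisons.
#'
#' @param profiles A data frame of genome profiles with a `gc` column.
#' @param lo,hi Exclusive GC bounds (defaults 0.35 and 0.65).
#' @return The retained rows.
#' @export
gc_filter <- function(profiles, lo = 0.35, hi = 0.65) {
  stopifnot(is.data.frame(profiles), "gc" %in% names(profiles))
  keep <- profiles$gc > lo & profiles$gc < hi
  message(sprintf("GC filter (%g, %g): retained %d of %d genomes",
                  lo, hi, sum(keep), length(keep)))
  if (!any(keep)) warnf("GC filter removed every genome")
  profiles[keep, , drop = FALSE]
}
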