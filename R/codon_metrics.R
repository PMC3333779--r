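#' Count codons in a coding sequence
#'
#' Splits a validated coding sequence into consecutive non-overlapping
#' triplets starting at position 1 and counts each of the 64 codons. Triplets
#' containing characters other than A/C/G/T (ambiguity codes) are skipped and
#' tallied in the `skipped` attribute: neither CAI nor Nc is defined over
#' ambiguous codons.
#'
#' @param sequence A single DNA string whose length is a multiple of 3.
#' @return A named integer vector of length 64 (codon counts) with attribute
#'   `skipped` (number of ambiguous triplets ignored).
#' @export
#' @examples
#' count_codons("ATGATG")
count_codons <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stopf("`sequence` must be a single DNA string")
  }
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) stopf("empty sequence")
  if (n %% 3L != 0L) stopf("sequence length (%d) is not a multiple of 3", n)
  m <- codon_count_matrix(sequence)
  counts <- m[1L, ]
  attr(counts, "skipped") <- as.integer(n / 3L - sum(counts))
  counts
}

# Codon-count matrix (one row per sequence, 64 columns) for a character
# vector of in-frame CDS. Ambiguous triplets are not counted.
codon_count_matrix <- function(sequences) {
  dss <- Biostrings::DNAStringSet(toupper(sequences))
  m <- Biostrings::trinucleotideFrequency(dss, step = 3L)
  storage.mode(m) <- "integer"
  m
}

#' Pool codon counts over a set of genes
#'
#' @param counts_list A non-empty list of codon-count vectors as produced by
#'   [count_codons()] (any named integer vectors over the same codon set).
#' @return A single pooled codon-count vector (elementwise sum).
#' @export
pool_counts <- function(counts_list) {
  if (!is.list(counts_list) || length(counts_list) == 0L) {
    stopf("`counts_list` must be a non-empty list of codon-count vectors")
  }
  out <- Reduce(`+`, lapply(counts_list, function(x) {
    v <- setNames(integer(64L), all_codons())
    v[names(x)] <- v[names(x)] + as.integer(x)
    v
  }))
  attr(out, "skipped") <- sum(vapply(counts_list, function(x) {
    as.integer(attr(x, "skipped") %||% 0L)
  }, integer(1)))
  out
}

#' Relative-adaptiveness weights from a highly-expressed reference set
#'
#' Derives the CAI weight table from codon counts pooled over a reference set
#' of highly expressed genes (conventionally the ribosomal-protein genes).
#' Within each synonymous family the weight of a codon is its count divided
#' by the count of the family's most frequent codon, so every family's
#' maximal weight is 1. Codons never observed in the reference set receive a
#' small pseudo-weight instead of 0, which would otherwise annihilate the
#' geometric mean of any gene using them. Single-codon families (Met, Trp)
#' are assigned weight 1; they are excluded from CAI in any case.
#'
#' @param ref_counts Pooled codon counts of the reference set.
#' @param pseudo Pseudo-weight for reference-absent codons (default 0.01).
#' @return An object of class `weight_table`: a named numeric vector over the
#'   61 sense codons, all weights in (0, 1].
#' @export
reference_weights <- function(ref_counts, pseudo = 0.01) {
  assert_scalar_number(pseudo, "pseudo", lo = .Machine$double.eps, hi = 1)
  code <- genetic_code()
  w <- setNames(numeric(length(code$sense_codons)), code$sense_codons)
  absent <- character(0)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    cts <- setNames(numeric(length(fam)), fam)
    have <- intersect(fam, names(ref_counts))
    cts[have] <- as.numeric(ref_counts[have])
    if (length(fam) == 1L) {
      w[fam] <- 1
      next
    }
    tot <- sum(cts)
    if (tot == 0) {
      w[fam] <- pseudo
      absent <- c(absent, aa)
      next
    }
    wf <- cts / max(cts)
    wf[cts == 0] <- pseudo
    w[fam] <- wf
  }
  if (length(absent) > 0L) {
    warnf("families absent from the reference set get pseudo-weights: %s",
          paste(absent, collapse = ", "))
  }
  structure(w, class = "weight_table", pseudo = pseudo)
}

#' Codon Adaptation Index of a gene
#'
#' The CAI of a gene is the geometric mean of the relative-adaptiveness
#' weights of its codons (Sharp & Li convention): codons from single-codon
#' families (Met, Trp) and stop codons carry no synonymous-choice signal and
#' are excluded. The mean is computed in log space so long genes do not
#' underflow. CAI ranges in (0, 1]; 1 means every codon is its family's most
#' preferred codon in the reference set.
#'
#' @param gene_counts Codon counts of one gene ([count_codons()]).
#' @param weights A [reference_weights()] table.
#' @return CAI in (0, 1], or `NA` if the gene has no codon from a degenerate
#'   family.
#' @export
cai <- function(gene_counts, weights) {
  if (!inherits(weights, "weight_table")) {
    stopf("`weights` must be a weight_table from reference_weights()")
  }
  code <- genetic_code()
  elig <- code$cai_codons
  cts <- setNames(numeric(length(elig)), elig)
  have <- intersect(elig, names(gene_counts))
  cts[have] <- as.numeric(gene_counts[have])
  n <- sum(cts)
  if (n == 0) {
    return(NA_real_)
  }
  exp(sum(cts * log(weights[elig])) / n)
}

# Vectorised CAI over a codon-count matrix (rows = genes).
cai_matrix <- function(counts, weights) {
  code <- genetic_code()
  elig <- code$cai_codons
  m <- counts[, elig, drop = FALSE]
  n <- rowSums(m)
  out <- as.numeric(m %*% log(as.numeric(weights[elig]))) / n
  out[n == 0] <- NA_real_
  exp(out)
}

#' Wright's effective number of codons (Nc) of a gene
#'
#' Estimates how many codon types a gene effectively uses, from 20 (one codon
#' per amino acid, maximal bias) to 61 (uniform synonymous usage). For each
#' synonymous family with at least two counted codons the codon homozygosity
#' is estimated as \deqn{\hat F = (n \sum_i p_i^2 - 1) / (n - 1)} where
#' \eqn{p_i} are the within-family codon proportions and \eqn{n} the family's
#' codon total. Families with \eqn{\hat F \le 0} or \eqn{n < 2} are excluded.
#' The \eqn{\hat F} values are averaged within each degeneracy class
#' (2-, 3-, 4-, 6-fold) and combined as
#' \deqn{Nc = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6.}
#'
#' Missing classes are handled as follows (all are logged via attributes):
#' if the sole 3-fold family (Ile) yields no estimate, \eqn{\bar F_3} is
#' imputed as \eqn{(\bar F_2 + \bar F_4)/2} (Wright's recommendation); if the
#' 6-fold class is missing it is imputed as \eqn{\bar F_4}; if the 2-fold or
#' 4-fold class is missing the gene's Nc is undefined. Sampling noise can
#' push the raw estimate above 61, so the result is capped into [20, 61].
#' Genes with fewer than `min_codons` codons in degenerate families are
#' reported as undefined rather than unstable.
#'
#' @param gene_counts Codon counts of one gene.
#' @param cap Cap the estimate into [20, 61]? (default `TRUE`; `FALSE`
#'   returns the raw estimator, used for cross-checks).
#' @param min_codons Minimum number of codons in degenerate families for the
#'   estimate to be reported (default 30).
#' @return Nc in [20, 61] (or the raw value if `cap = FALSE`), or `NA` when
#'   undefined.
#' @export
nc <- function(gene_counts, cap = TRUE, min_codons = 30L) {
  code <- genetic_code()
  fams <- code$families[code$degeneracy >= 2L]
  ks <- code$degeneracy[names(fams)]
  informative <- 0
  f_hat <- rep(NA_real_, length(fams))
  for (i in seq_along(fams)) {
    fam <- fams[[i]]
    cts <- numeric(length(fam))
    have <- intersect(fam, names(gene_counts))
    cts[match(have, fam)] <- as.numeric(gene_counts[have])
    n_aa <- sum(cts)
    informative <- informative + n_aa
    if (n_aa < 2) next
    p <- cts / n_aa
    f <- (n_aa * sum(p^2) - 1) / (n_aa - 1)
    if (f > 0) f_hat[i] <- f
  }
  if (informative < min_codons) {
    return(NA_real_)
  }
  fbar <- function(k) {
    v <- f_hat[ks == k]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  f2 <- fbar(2L)
  f3 <- fbar(3L)
  f4 <- fbar(4L)
  f6 <- fbar(6L)
  if (is.na(f2) || is.na(f4)) {
    return(NA_real_)
  }
  if (is.na(f3)) f3 <- (f2 + f4) / 2
  if (is.na(f6)) f6 <- f4
  raw <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  if (!cap) {
    return(raw)
  }
  min(61, max(20, raw))
}

#' GC content of a sequence set
#'
#' Fraction of G and C over all nucleotides of the supplied sequences
#' (typically all retained CDS of a genome, concatenated).
#'
#' @param sequences Character vector of DNA sequences.
#' @return GC fraction in [0, 1].
#' @export
gc_content <- function(sequences) {
  if (length(sequences) == 0L || all(nchar(sequences) == 0L)) {
    stopf("no sequence supplied")
  }
  dss <- Biostrings::DNAStringSet(toupper(sequences))
  gc <- sum(Biostrings::letterFrequency(dss, letters = c("G", "C")))
  gc / sum(Biostrings::width(dss))
}

#' Per-gene bias scores for a set of genes
#'
#' Convenience wrapper computing CAI, Nc and GC content for every valid gene
#' in a gene table, under a given weight table.
#'
#' @param records A gene table (see [read_cds_fasta()]).
#' @param weights A [reference_weights()] table.
#' @param nc_min_codons Passed to [nc()].
#' @return A data frame: gene_id, cai, nc, gc, codons_used, is_ribosomal.
#' @export
gene_bias_scores <- function(records, weights, nc_min_codons = 30L) {
  records <- validate_genes(records)
  keep <- records[records$valid, , drop = FALSE]
  if (nrow(keep) == 0L) stopf("no valid genes")
  counts <- codon_count_matrix(keep$sequence)
  nc_vals <- apply(counts, 1L, nc, min_codons = nc_min_codons)
  data.frame(
    gene_id = keep$gene_id,
    cai = cai_matrix(counts, weights),
    nc = as.numeric(nc_vals),
    gc = vapply(keep$sequence, function(s) gc_content(s), numeric(1),
                USE.NAMES = FALSE),
    codons_used = as.integer(rowSums(counts)),
    is_ribosomal = keep$is_ribosomal,
    stringsAsFactors = FALSE
  )
}
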