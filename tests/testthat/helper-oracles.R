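# Independent reference implementations used to cross-check the package.
# Each oracle is written straight from the defining formula, on a different
# representation (codon vectors rather than count vectors) where possible.

# Synonymous families derived directly from the Biostrings codon table,
# independently of the package's genetic_code() object.
oracle_families <- local({
  tab <- Biostrings::getGeneticCode("11")
  sense <- names(tab)[tab != "*"]
  split(sense, as.character(tab[sense]))
})

# Wright's Nc computed from a vector of codons (not counts), one family at a
# time, straight from the homozygosity formula. Returns the raw (uncapped)
# estimate; NA when the 2- or 4-fold class has no usable family.
oracle_nc <- function(codons) {
  fams <- oracle_families[lengths(oracle_families) >= 2]
  f_by_class <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (aa in names(fams)) {
    fam <- fams[[aa]]
    obs <- codons[codons %in% fam]
    n <- length(obs)
    if (n < 2) next
    p <- as.numeric(table(factor(obs, levels = fam))) / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f <= 0) next
    k <- as.character(length(fam))
    f_by_class[[k]] <- c(f_by_class[[k]], f)
  }
  fb <- vapply(f_by_class, function(v) if (length(v)) mean(v) else NA_real_,
               numeric(1))
  if (is.na(fb["2"]) || is.na(fb["4"])) return(NA_real_)
  if (is.na(fb["3"])) fb["3"] <- (fb["2"] + fb["4"]) / 2
  if (is.na(fb["6"])) fb["6"] <- fb["4"]
  2 + 9 / fb["2"] + 1 / fb["3"] + 5 / fb["4"] + 3 / fb["6"]
}

# Per-family homozygosity, straight from the formula; for spot checks.
oracle_homozygosity <- function(counts_in_family) {
  n <- sum(counts_in_family)
  p <- counts_in_family / n
  (n * sum(p^2) - 1) / (n - 1)
}

# CAI as a direct product of weights over codon occurrences (no log space):
# for short genes the double-precision product is exact to ~1e-15 relative.
oracle_cai <- function(codons, w) {
  excluded <- c("ATG", "TGG", "TAA", "TAG", "TGA")
  use <- codons[!codons %in% excluded]
  prod(as.numeric(w[use]))^(1 / length(use))
}

# Exact two-sided Mann-Whitney p-value by exhaustive label permutation.
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  m <- length(a)
  u_stat <- function(x, y) {
    sum(vapply(x, function(xi) sum(xi > y) + 0.5 * sum(xi == y), numeric(1)))
  }
  mu <- m * length(b) / 2
  obs <- abs(u_stat(a, b) - mu)
  labelings <- utils::combn(n, m)
  hits <- 0
  for (j in seq_len(ncol(labelings))) {
    ia <- labelings[, j]
    u <- u_stat(pooled[ia], pooled[-ia])
    if (abs(u - mu) >= obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(labelings)
}

# First-order partial correlation via regression residuals (the package
# uses the closed-form recursion instead).
oracle_partial_r <- function(x, y, z) {
  stats::cor(stats::resid(stats::lm(x ~ z)), stats::resid(stats::lm(y ~ z)))
}
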