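test_that("count_codons splits in frame, skips ambiguity, rejects bad length", {
  cts <- count_codons("ATGATG")
  expect_equal(unname(cts["ATG"]), 2L)
  expect_equal(sum(cts), 2L)

  cts <- count_codons("AAAAAG")
  expect_equal(unname(cts[c("AAA", "AAG")]), c(1L, 1L))

  expect_error(count_codons("AAAAAGA"), "not a multiple of 3")
  expect_error(count_codons(""), "empty")

  cts <- count_codons("ATGNNNAAA")
  expect_equal(sum(cts), 2L)
  expect_equal(attr(cts, "skipped"), 1L)
})

test_that("pool_counts sums elementwise and rejects empty input", {
  a <- count_codons("AAA")
  b <- count_codons("AAAAAAAAG")
  pooled <- pool_counts(list(a, b))
  expect_equal(unname(pooled[c("AAA", "AAG")]), c(3L, 1L))
  expect_equal(unname(pool_counts(list(a))[["AAA"]]), 1L)
  expect_error(pool_counts(list()), "non-empty")
})

test_that("reference weights are within-family count ratios with pseudo floor", {
  base <- setNames(integer(64L), all_codons())
  # Healthy reference usage for every family, so no absent-family warnings.
  code <- genetic_code()
  for (fam in code$families) base[fam] <- 5L

  ref <- base
  ref[c("AAA", "AAG")] <- c(30L, 10L)
  w <- reference_weights(ref)
  expect_identical(unname(w["AAA"]), 1)
  expect_equal(unname(w["AAG"]), 1 / 3)

  ref[c("AAA", "AAG")] <- c(10L, 10L)
  w <- reference_weights(ref)
  expect_equal(unname(w[c("AAA", "AAG")]), c(1, 1))

  ref[c("AAA", "AAG")] <- c(30L, 0L)
  w <- reference_weights(ref)
  expect_equal(unname(w["AAG"]), 0.01)

  # Every family's maximum weight is exactly 1; all weights in (0, 1].
  for (fam in code$families) {
    expect_identical(max(unname(w[fam])), 1)
  }
  expect_true(all(w > 0 & w <= 1))

  absent <- base
  absent[code$families[["K"]]] <- 0L
  expect_warning(w2 <- reference_weights(absent), "pseudo")
  expect_equal(unname(w2[c("AAA", "AAG")]), c(0.01, 0.01))
})

test_that("CAI matches its definition and the direct-product oracle", {
  code <- genetic_code()
  ref <- setNames(integer(64L), all_codons())
  for (fam in code$families) {
    ref[fam] <- c(40L, rep(10L, length(fam) - 1L))
  }
  w <- reference_weights(ref)

  # Gene built from each family's maximal-weight codon: geometric mean of 1s.
  best <- vapply(code$families[code$degeneracy >= 2L], `[[`, character(1), 1L)
  gene <- setNames(integer(64L), all_codons())
  gene[best] <- 11L
  expect_identical(cai(gene, w), 1)

  # Two occurrences with w = 1 and w = 0.25.
  w2 <- w
  w2["AAG"] <- 0.25
  class(w2) <- "weight_table"
  two <- setNames(integer(64L), all_codons())
  two[c("AAA", "AAG")] <- 1L
  expect_equal(cai(two, w2), 0.5)

  # 100 random 30-codon genes against the direct-product oracle.
  set.seed(11)
  for (i in 1:100) {
    g <- random_gene(30L)
    expect_equal(cai(g$counts, w), oracle_cai(g$codons, w),
                 tolerance = 1e-12)
  }
})

test_that("CAI is scale-invariant and monotone in synonymous replacement", {
  code <- genetic_code()
  ref <- setNames(integer(64L), all_codons())
  for (fam in code$families) ref[fam] <- seq(10L, by = 7L,
                                             length.out = length(fam))
  w <- reference_weights(ref)
  set.seed(12)
  for (i in 1:20) {
    g <- random_gene(60L)$counts
    expect_equal(cai(g * 7L, w), cai(g, w), tolerance = 1e-12)
  }
  # Moving one Lys occurrence to the higher-weight codon never lowers CAI.
  g <- random_gene(60L)$counts
  g[c("AAA", "AAG")] <- c(3L, 3L)
  lo <- which.min(w[c("AAA", "AAG")])
  g2 <- g
  g2[c("AAA", "AAG")] <- if (lo == 1L) c(2L, 4L) else c(4L, 2L)
  expect_gte(cai(g2, w), cai(g, w))
})

test_that("Nc matches the homozygosity formula and the brute-force oracle", {
  # Hand-checkable family homozygosity: Lys {AAA:3, AAG:1}.
  expect_equal(oracle_homozygosity(c(3, 1)), (4 * 0.625 - 1) / 3)
  expect_equal(oracle_homozygosity(c(3, 1)), 0.5)

  # 200 random genes, 100-1000 codons: raw estimates agree to 1e-9.
  set.seed(13)
  for (i in 1:200) {
    g <- random_gene(sample(100:1000, 1L))
    expect_equal(nc(g$counts, cap = FALSE), unname(oracle_nc(g$codons)),
                 tolerance = 1e-9)
  }
})

test_that("Nc attains its bounds and stays within [20, 61] after capping", {
  expect_identical(nc(one_codon_per_family_counts(10L)), 20)
  # Uniform usage: raw estimate exceeds 61 by finite-sample inflation.
  expect_gt(nc(uniform_usage_counts(100L), cap = FALSE), 61)
  expect_identical(nc(uniform_usage_counts(100L)), 61)

  set.seed(14)
  vals <- replicate(50, nc(random_gene(sample(100:500, 1L))$counts))
  expect_true(all(vals >= 20 & vals <= 61))
})

test_that("Nc is undefined for short genes and missing essential classes", {
  expect_true(is.na(nc(one_codon_per_family_counts(1L))))  # 18 codons < 30
  # Only 2-fold families present: the 4-fold class mean is missing.
  code <- genetic_code()
  two_only <- setNames(integer(64L), all_codons())
  for (fam in code$families[code$degeneracy == 2L]) two_only[fam] <- 10L
  expect_true(is.na(nc(two_only)))
})

test_that("gc_content is the G+C fraction over all nucleotides", {
  expect_identical(gc_content("GGCC"), 1)
  expect_identical(gc_content("ATAT"), 0)
  expect_identical(gc_content("ATGC"), 0.5)
  expect_equal(gc_content(c("GG", "AT")), 0.5)
  expect_error(gc_content(character(0)), "no sequence")
})

test_that("the bacterial code has the expected family structure", {
  code <- genetic_code()
  expect_length(code$sense_codons, 61L)
  expect_equal(as.vector(table(code$degeneracy)[c("1", "2", "3", "4", "6")]),
               c(2L, 9L, 1L, 5L, 3L))
  expect_identical(sort(code$families[["I"]]), c("ATA", "ATC", "ATT"))
})
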