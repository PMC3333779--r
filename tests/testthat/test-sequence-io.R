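test_that("CDS FASTA ingestion validates records and round-trips", {
  path <- write_fasta_text(c("g1", "g2"), c("ATGAAAGAA", "ATGAAAGAACTG"))
  rec <- read_cds_fasta(path)
  expect_equal(nrow(rec), 2L)
  expect_equal(nchar(rec$sequence), c(9L, 12L))
  expect_false(any(rec$is_ribosomal))
  expect_true(all(rec$valid))

  # A length-10 record is flagged invalid, not repaired.
  path <- write_fasta_text(c("ok", "bad"), c("ATGAAAGAA", "ATGAAAGAAC"))
  expect_warning(rec <- read_cds_fasta(path), "failed validation")
  expect_equal(rec$valid, c(TRUE, FALSE))
  expect_match(rec$invalid_reason[2], "multiple of 3")

  empty <- tempfile(fileext = ".fasta")
  file.create(empty)
  expect_error(read_cds_fasta(empty), "no records")

  allbad <- write_fasta_text(c("a", "b"), c("ATGA", "CCCC"))
  expect_error(read_cds_fasta(allbad), "all 2 records")

  # Round trip: ids, sequences and order survive.
  path <- write_fasta_text(c("g1", "g2"), c("ATGAAAGAA", "ATGAAAGAACTG"))
  rec <- read_cds_fasta(path)
  out <- tempfile(fileext = ".fasta")
  write_cds_fasta(rec, out)
  rec2 <- read_cds_fasta(out)
  expect_identical(rec2[c("gene_id", "sequence")],
                   rec[c("gene_id", "sequence")])
})

test_that("genes with excess ambiguity are excluded from metrics", {
  rec <- data.frame(gene_id = c("a", "b"),
                    sequence = c(paste(rep("AAA", 20), collapse = ""),
                                 paste(c(rep("AAA", 17), "ANA", "NNN", "ANN"),
                                       collapse = "")),
                    stringsAsFactors = FALSE)
  rec <- validate_genes(rec)
  expect_equal(rec$valid, c(TRUE, FALSE))
  expect_match(rec$invalid_reason[2], "ambiguous")
})

test_that("GenBank CDS extraction honours strand, join and qualifiers", {
  path <- genbank_fixture()
  rec <- read_genbank_cds(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$gene_id, c("t0001", "t0002", "t0003"))
  # Forward and complement CDS encode the same peptide here by construction.
  expect_identical(rec$sequence[1], "ATGAAAGAACTGGGT")
  expect_identical(rec$sequence[2], rec$sequence[1])
  expect_identical(rec$sequence[3], "ATGCGTGCAACC")
  expect_identical(rec$product[1], "50S ribosomal protein L2")
  expect_match(rec$product[3], "wrapped product line")
  # Double reverse-complement is the identity.
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_identical(rc(rc(rec$sequence[2])), rec$sequence[2])
  # Stop-free by construction: translation has no internal stops.
  expect_false(any(grepl("\\*", substr(
    as.character(Biostrings::translate(
      Biostrings::DNAStringSet(rec$sequence))), 1, 4))))

  nocds <- tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       X 6 bp DNA linear BCT 01-JAN-2000",
               "FEATURES             Location/Qualifiers",
               "     source          1..6",
               "ORIGIN",
               "        1 atgaaa",
               "//"), nocds)
  expect_warning(rec <- read_genbank_cds(nocds), "no CDS")
  expect_equal(nrow(rec), 0L)
})

test_that("ribosomal-gene flagging follows product patterns and exclusions", {
  rec <- data.frame(
    gene_id = c("a", "b", "c"),
    sequence = "ATGAAA",
    product = c("30S ribosomal protein S4", "DNA gyrase subunit A",
                "ribosomal protein L11 methyltransferase"),
    stringsAsFactors = FALSE
  )
  out <- flag_ribosomal_genes(rec, min_count = 1L)
  expect_equal(out$is_ribosomal, c(TRUE, FALSE, FALSE))

  # Idempotent and order-independent.
  expect_equal(flag_ribosomal_genes(out, min_count = 1L)$is_ribosomal,
               out$is_ribosomal)
  perm <- flag_ribosomal_genes(rec[c(3, 1, 2), ], min_count = 1L)
  expect_equal(perm$is_ribosomal[perm$gene_id == "a"], TRUE)
  expect_equal(perm$is_ribosomal[perm$gene_id %in% c("b", "c")], c(FALSE, FALSE))

  expect_error(flag_ribosomal_genes(rec, min_count = 20L),
               "explicit reference gene list")
  byid <- flag_ribosomal_genes(rec, gene_ids = c("b", "c"), min_count = 2L)
  expect_equal(byid$is_ribosomal, c(FALSE, TRUE, TRUE))
})

test_that("phenotype tables are validated and habitat is coded 0/1", {
  tab <- data.frame(
    organism_id = c("o1", "o2", "o3"),
    habitat = c("Multiple", "Specialized", ""),
    oxygen = c("Aerobic", "weird", "Facultative"),
    temperature = c("Mesophilic", "Thermophilic", "Hyperthermophilic"),
    growth_rate = c("1.4", "", "0.2"),
    stringsAsFactors = FALSE
  )
  path <- write_phenotype_fixture(tab)
  expect_warning(ann <- read_phenotype_table(path), "unrecognised 'oxygen'")
  expect_equal(ann$habitat_code, c(0L, 1L, NA_integer_))
  expect_equal(ann$oxygen, c("aerobic", NA, "facultative"))
  expect_equal(ann$growth_rate, c(1.4, NA, 0.2))

  noid <- write_phenotype_fixture(data.frame(x = 1))
  expect_error(read_phenotype_table(noid), "organism_id")
})

test_that("newick reading validates structure and branch lengths", {
  path <- tempfile(fileext = ".nwk")
  writeLines("((A:1,B:2):3,C:4);", path)
  tree <- read_newick_tree(path)
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, c("A", "B", "C"))

  writeLines("((A,B),C);", path)
  expect_warning(tree <- read_newick_tree(path), "unit lengths")
  expect_true(all(tree$edge.length == 1))

  writeLines("((A,B,C;", path)
  expect_error(read_newick_tree(path), "malformed newick")
})
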