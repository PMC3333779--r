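# Fixtures are generated in code; expensive simulation panels are built once
# per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# The standard validation panel: 40 genomes, selection strength evenly
# spaced over [0, 5], at the given GC pressure, with fixed seeds.
cached_panel_profiles <- function(theta, seed) {
  key <- sprintf("panel_theta%s", theta)
  hit <- get0(key, envir = .fixture_cache)
  if (!is.null(hit)) return(hit)
  panel <- selection_grid_panel(n = 40L, s_range = c(0, 5), theta = theta,
                                seed = seed)
  profiles <- profile_panel(panel)
  assign(key, profiles, envir = .fixture_cache)
  profiles
}

panel_theta05 <- function() cached_panel_profiles(theta = 0.5, seed = 2001L)
panel_theta09 <- function() cached_panel_profiles(theta = 0.9, seed = 2002L)

# Random codon counts (uniform over the 61 sense codons); returns both the
# codon vector (for the oracles) and the count vector (for the package).
random_gene <- function(n_codons) {
  sense <- genetic_code()$sense_codons
  codons <- sample(sense, n_codons, replace = TRUE)
  counts <- setNames(integer(64L), all_codons())
  tb <- table(codons)
  counts[names(tb)] <- as.integer(tb)
  list(codons = codons, counts = counts)
}

# Codon counts with exactly one codon per amino-acid family, each `per_aa`
# times: the maximally biased gene (every family homozygosity is 1).
one_codon_per_family_counts <- function(per_aa = 10L) {
  code <- genetic_code()
  chosen <- vapply(code$families, `[[`, character(1), 1L)
  counts <- setNames(integer(64L), all_codons())
  counts[chosen] <- per_aa
  counts
}

# Uniform usage: all 61 sense codons at the same count.
uniform_usage_counts <- function(per_codon = 100L) {
  counts <- setNames(integer(64L), all_codons())
  counts[genetic_code()$sense_codons] <- per_codon
  counts
}

# A small genome of identical genes (first n_rib flagged ribosomal); the
# shared gene uses one codon from every amino-acid family so the reference
# weight table covers all families.
identical_gene_genome <- function(n_genes = 60L, n_rib = 20L) {
  one_per_family <- vapply(genetic_code()$families, `[[`, character(1), 1L)
  seq1 <- paste(rep(one_per_family, 3L), collapse = "")
  data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    sequence = seq1,
    is_ribosomal = seq_len(n_genes) <= n_rib,
    product = NA_character_,
    stringsAsFactors = FALSE
  )
}

write_fasta_text <- function(ids, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

# A minimal two-gene GenBank record: one forward CDS, one complement CDS,
# plus a join() CDS; constructed stop-free so extraction can be checked by
# translation.
genbank_fixture <- function() {
  genome <- paste0(
    "ATGAAAGAACTGGGT",        # 1..15  fwd CDS (ATG AAA GAA CTG GGT)
    "TTTTT",                  # 16..20 spacer
    "ACCCAGTTCTTTCAT",        # 21..35 revcomp is ATGAAAGAACTGGGT
    "GG",                     # 36..37 spacer
    "ATGCGT", "AAAAA", "GCAACC"  # join(38..43,49..54)
  )
  lines <- c(
    "LOCUS       TESTREC                 54 bp    DNA     linear   BCT 01-JAN-2000",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..54",
    "                     /organism=\"synthetic construct\"",
    "     CDS             1..15",
    "                     /locus_tag=\"t0001\"",
    "                     /product=\"50S ribosomal protein L2\"",
    "     CDS             complement(21..35)",
    "                     /locus_tag=\"t0002\"",
    "                     /product=\"DNA gyrase subunit A\"",
    "     CDS             join(38..43,49..54)",
    "                     /locus_tag=\"t0003\"",
    "                     /product=\"hypothetical protein with a long",
    "                     wrapped product line\"",
    "ORIGIN",
    paste0("        1 ", tolower(genome)),
    "//"
  )
  path <- tempfile(fileext = ".gbk")
  writeLines(lines, path)
  path
}

write_phenotype_fixture <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
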