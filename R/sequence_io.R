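#' Read a CDS FASTA file into a gene table
#'
#' Reads a FASTA file with one record per protein-coding gene and validates
#' each record for codon analysis: the sequence must be non-empty, its length
#' a multiple of 3, and at most 10% of its codons may contain ambiguity
#' codes. Invalid records are retained in the table with `valid = FALSE` and
#' a reason, and are excluded from all downstream metrics (never repaired).
#'
#' @param path Path to a FASTA file.
#' @return A gene table: data frame with columns `gene_id`, `sequence`
#'   (upper-case), `is_ribosomal` (initialised `FALSE`), `product`
#'   (`NA` — FASTA carries no feature annotation), `valid`, `invalid_reason`.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  dss <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stopf("unreadable FASTA '%s': %s",
                                            path, conditionMessage(e)))
  if (length(dss) == 0L) stopf("no records in FASTA file '%s'", path)
  ids <- sub("\\s.*$", "", names(dss))
  records <- data.frame(
    gene_id = ids,
    sequence = toupper(as.character(dss)),
    is_ribosomal = FALSE,
    product = NA_character_,
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  records <- validate_genes(records)
  n_bad <- sum(!records$valid)
  if (n_bad == nrow(records)) {
    stopf("all %d records in '%s' failed validation", n_bad, path)
  }
  if (n_bad > 0L) {
    warnf("%d of %d records failed validation and are excluded from metrics",
          n_bad, nrow(records))
  }
  records
}

#' Validate a gene table for codon analysis
#'
#' Adds/refreshes `valid` and `invalid_reason` columns: a gene is valid when
#' its sequence is non-empty, has length divisible by 3, and fewer than 10%
#' of its codons contain non-A/C/G/T characters.
#'
#' @param records A gene table.
#' @param max_ambiguous_frac Maximum tolerated fraction of ambiguous codons.
#' @return The gene table with `valid`/`invalid_reason` columns.
#' @export
validate_genes <- function(records, max_ambiguous_frac = 0.10) {
  stopifnot(is.data.frame(records),
            all(c("gene_id", "sequence") %in% names(records)))
  seqs <- toupper(records$sequence)
  len <- nchar(seqs)
  reason <- rep(NA_character_, nrow(records))
  reason[len == 0L] <- "empty sequence"
  bad_frame <- is.na(reason) & len %% 3L != 0L
  reason[bad_frame] <- "length not a multiple of 3"
  chk <- is.na(reason)
  if (any(chk)) {
    n_cod <- len[chk] / 3L
    clean <- vapply(seqs[chk], function(s) {
      sum(codon_count_matrix(s))
    }, numeric(1), USE.NAMES = FALSE)
    frac_amb <- (n_cod - clean) / n_cod
    idx <- which(chk)[frac_amb > max_ambiguous_frac]
    reason[idx] <- sprintf("ambiguous codons exceed %d%% of gene",
                           round(100 * max_ambiguous_frac))
  }
  records$sequence <- seqs
  records$valid <- is.na(reason)
  records$invalid_reason <- reason
  records
}

#' Write a gene table to FASTA
#'
#' @param records A gene table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("gene_id", "sequence") %in% names(records)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0(">", records$gene_id, "\n", records$sequence), con)
  invisible(path)
}

#' Extract CDS features from a GenBank flat file
#'
#' Minimal parser for GenBank flat files as distributed for prokaryotic
#' genomes: one gene table row per `CDS` feature. Locations are interpreted
#' per GenBank convention (1-based inclusive); `join(...)` segments are
#' concatenated in the stated order and `complement(...)` features are
#' reverse-complemented, so every returned sequence reads 5'→3' on the coding
#' strand. The `/product` qualifier is captured for ribosomal-gene flagging;
#' gene identity is taken from `/locus_tag`, falling back to `/gene`,
#' `/protein_id` and finally a positional id.
#'
#' @param path Path to a GenBank flat file (one or more records).
#' @return A gene table (see [read_cds_fasta()]); empty (0 rows) with a
#'   warning if the file has no CDS features.
#' @export
read_genbank_cds <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stopf("empty GenBank file '%s'", path)
  rec_ends <- grep("^//\\s*$", lines)
  rec_starts <- c(1L, head(rec_ends, -1L) + 1L)
  if (length(rec_ends) == 0L) {
    rec_starts <- 1L
    rec_ends <- length(lines)
  }
  out <- list()
  for (r in seq_along(rec_starts)) {
    rec <- lines[rec_starts[r]:rec_ends[r]]
    out[[r]] <- .parse_genbank_record(rec, r)
  }
  records <- do.call(rbind, out)
  if (is.null(records) || nrow(records) == 0L) {
    warnf("no CDS features found in '%s'", path)
    return(data.frame(gene_id = character(0), sequence = character(0),
                      is_ribosomal = logical(0), product = character(0),
                      valid = logical(0), invalid_reason = character(0),
                      stringsAsFactors = FALSE))
  }
  rownames(records) <- NULL
  validate_genes(records)
}

.parse_genbank_record <- function(rec, rec_index) {
  feat_start <- grep("^FEATURES", rec)
  origin <- grep("^ORIGIN", rec)
  if (length(feat_start) == 0L || length(origin) == 0L) {
    return(NULL)
  }
  seq_lines <- rec[(origin[1L] + 1L):length(rec)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  genome <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  feats <- rec[(feat_start[1L] + 1L):(origin[1L] - 1L)]
  # Feature keys sit at column 6; continuations are indented to column 22.
  key_idx <- grep("^ {5}\\S", feats)
  if (length(key_idx) == 0L) {
    return(NULL)
  }
  blocks <- Map(function(from, to) feats[from:to],
                key_idx, c(key_idx[-1L] - 1L, length(feats)))
  rows <- list()
  cds_n <- 0L
  for (blk in blocks) {
    key <- sub("^ {5}(\\S+).*$", "\\1", blk[1L])
    if (key != "CDS") next
    cds_n <- cds_n + 1L
    body <- sub("^ {5}\\S+\\s*", "", blk[1L])
    rest <- trimws(blk[-1L])
    # Location may continue over lines until the first qualifier.
    qual_at <- which(startsWith(rest, "/"))
    loc_extra <- if (length(qual_at) > 0L && qual_at[1L] > 1L) {
      rest[seq_len(qual_at[1L] - 1L)]
    } else if (length(qual_at) == 0L) rest else character(0)
    location <- paste0(body, paste(loc_extra, collapse = ""))
    quals <- if (length(qual_at) > 0L) rest[qual_at[1L]:length(rest)] else character(0)
    product <- .genbank_qualifier(quals, "product")
    id <- .genbank_qualifier(quals, "locus_tag") %||%
      .genbank_qualifier(quals, "gene") %||%
      .genbank_qualifier(quals, "protein_id") %||%
      sprintf("record%d_CDS%d", rec_index, cds_n)
    seq <- tryCatch(.extract_location(genome, location),
                    error = function(e) NA_character_)
    if (is.na(seq)) {
      warnf("skipping CDS '%s': cannot interpret location '%s'", id, location)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = id, sequence = seq, is_ribosomal = FALSE,
      product = product %||% NA_character_, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) NULL else do.call(rbind, rows)
}

# First value of a qualifier (joining multi-line quoted values), or NULL.
.genbank_qualifier <- function(quals, name) {
  hit <- grep(paste0("^/", name, "="), quals)
  if (length(hit) == 0L) {
    return(NULL)
  }
  val <- sub(paste0("^/", name, "="), "", quals[hit[1L]])
  if (startsWith(val, "\"") && !grepl("\"$", sub("^\"", "", val))) {
    i <- hit[1L]
    while (i < length(quals) && !grepl("\"\\s*$", val)) {
      i <- i + 1L
      val <- paste(val, quals[i])
    }
  }
  gsub("^\"|\"$", "", val)
}

# Extract a (possibly join()ed / complement()ed) GenBank location from the
# record sequence; 1-based inclusive coordinates, partial markers (<, >)
# tolerated.
.extract_location <- function(genome, location) {
  loc <- gsub("[<>[:space:]]", "", location)
  comp <- grepl("^complement\\(", loc)
  if (comp) loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  join <- grepl("^join\\(", loc)
  if (join) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  segs <- vapply(parts, function(p) {
    inner_comp <- grepl("^complement\\(", p)
    if (inner_comp) p <- sub("^complement\\((.*)\\)$", "\\1", p)
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1L]]
    if (length(m) == 3L) {
      from <- as.integer(m[2L]); to <- as.integer(m[3L])
    } else if (grepl("^\\d+$", p)) {
      from <- to <- as.integer(p)
    } else {
      stopf("unparseable location segment '%s'", p)
    }
    if (from < 1L || to > nchar(genome) || from > to) {
      stopf("location %d..%d outside record of length %d", from, to,
            nchar(genome))
    }
    s <- substr(genome, from, to)
    if (inner_comp) s <- .revcomp(s)
    s
  }, character(1))
  out <- paste(segs, collapse = "")
  if (comp) out <- .revcomp(out)
  out
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Flag ribosomal-protein genes by product annotation
#'
#' Marks genes whose product annotation identifies a ribosomal protein, for
#' use as the highly-expressed CAI/Nc reference set. A gene is flagged when
#' its product matches any inclusion pattern (case-insensitive) and no
#' exclusion pattern; the default exclusions reject ribosomal-protein
#' *modification* enzymes (methyltransferases, pseudouridine synthases,
#' acetyltransferases, kinases), which are not themselves highly expressed.
#' Alternatively an explicit `gene_ids` reference list overrides patterns.
#'
#' @param records A gene table.
#' @param include Inclusion patterns (regex, case-insensitive).
#' @param exclude Exclusion patterns.
#' @param gene_ids Optional explicit vector of reference gene ids (overrides
#'   the pattern rules).
#' @param min_count Minimum acceptable number of flagged genes (default 20):
#'   fewer is an error instructing the caller to supply an explicit list.
#' @return The gene table with `is_ribosomal` set.
#' @export
flag_ribosomal_genes <- function(records,
                                 include = "ribosomal protein",
                                 exclude = c("methyltransferase",
                                             "pseudouridine",
                                             "acetyltransferase",
                                             "kinase"),
                                 gene_ids = NULL,
                                 min_count = 20L) {
  stopifnot(is.data.frame(records))
  if (!is.null(gene_ids)) {
    flag <- records$gene_id %in% gene_ids
  } else {
    if (!"product" %in% names(records) || all(is.na(records$product))) {
      stopf(paste("records carry no product annotations;",
                  "supply `gene_ids` explicitly"))
    }
    prod <- ifelse(is.na(records$product), "", records$product)
    inc <- Reduce(`|`, lapply(include, grepl, x = prod, ignore.case = TRUE))
    exc <- if (length(exclude) > 0L) {
      Reduce(`|`, lapply(exclude, grepl, x = prod, ignore.case = TRUE))
    } else {
      rep(FALSE, nrow(records))
    }
    flag <- inc & !exc
  }
  if (sum(flag) < min_count) {
    stopf(paste("only %d ribosomal genes identified (minimum %d);",
                "supply an explicit reference gene list via `gene_ids`"),
          sum(flag), min_count)
  }
  records$is_ribosomal <- flag
  records
}

# Canonical phenotype vocabularies (lifestyle annotation categories).
.phenotype_levels <- list(
  pathogenicity = c("pathogenic", "non-pathogenic"),
  oxygen = c("aerobic", "anaerobic", "facultative", "microaerophilic"),
  salinity = c("extreme-halophilic", "mesophilic", "moderate-halophilic",
               "non-halophilic"),
  temperature = c("hyperthermophilic", "mesophilic", "psychrophilic",
                  "thermophilic"),
  habitat = c("multiple", "specialized")
)

#' Read a phenotype annotation table
#'
#' Reads a TSV of organism lifestyle annotations: pathogenicity, oxygen
#' requirement, salinity, temperature range, habitat breadth and (optionally)
#' growth rate. Category tokens are normalised (case- and separator-
#' insensitive) and validated against the controlled vocabulary; unknown
#' tokens become missing with a warning. A numeric `habitat_code` is derived:
#' 0 for organisms living in multiple habitats, 1 for specialized organisms,
#' so it can enter correlations as a 0/1 variable.
#'
#' @param path Path to a TSV with header; must contain `organism_id`.
#' @return A data frame with validated factor-like character columns,
#'   optional numeric `growth_rate`, and derived `habitat_code`.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"organism_id" %in% names(tab)) {
    stopf("phenotype table must contain an 'organism_id' column")
  }
  norm <- function(x) gsub("[ _]+", "-", tolower(trimws(x)))
  for (trait in names(.phenotype_levels)) {
    if (!trait %in% names(tab)) {
      tab[[trait]] <- NA_character_
      next
    }
    v <- norm(as.character(tab[[trait]]))
    v[v == "" | v == "na" | v == "missing"] <- NA_character_
    bad <- !is.na(v) & !v %in% .phenotype_levels[[trait]]
    if (any(bad)) {
      warnf("%d unrecognised '%s' values set to missing (e.g. '%s')",
            sum(bad), trait, v[bad][1L])
      v[bad] <- NA_character_
    }
    tab[[trait]] <- v
  }
  if ("growth_rate" %in% names(tab)) {
    gr <- suppressWarnings(as.numeric(tab$growth_rate))
    gr[!is.na(gr) & gr <= 0] <- NA_real_
    tab$growth_rate <- gr
  } else {
    tab$growth_rate <- NA_real_
  }
  tab$habitat_code <- ifelse(is.na(tab$habitat), NA_integer_,
                             ifelse(tab$habitat == "multiple", 0L, 1L))
  tab
}

#' Read a phylogenetic tree from a newick file
#'
#' Parses a newick tree (via \pkg{ape}) and checks it for use in patristic
#' distance analyses: unique leaf labels and non-negative branch lengths.
#' Trees without branch lengths are given unit lengths with a warning, so
#' topology-only trees remain usable.
#'
#' @param path Path to a newick file.
#' @return An \pkg{ape} `phylo` object.
#' @export
read_newick_tree <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (open != close || !grepl(";", txt, fixed = TRUE)) {
    stopf(paste("malformed newick in '%s': %d '(' vs %d ')' before the",
                "terminating ';' (near character %d)"),
          path, open, close, nchar(txt))
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stopf("newick parse error in '%s': %s",
                                             path, conditionMessage(e)))
  if (is.null(tree)) stopf("newick parse error in '%s'", path)
  if (anyDuplicated(tree$tip.label)) {
    stopf("duplicate leaf labels in tree")
  }
  if (is.null(tree$edge.length)) {
    warnf("tree has no branch lengths; using unit lengths")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) stopf("negative branch lengths in tree")
  tree
}

#' Write / read tab-separated result tables
#'
#' Plain TSV writers/readers used for per-gene scores, genome profiles and
#' comparison results.
#'
#' @param x A data frame.
#' @param path File path.
#' @return `path` (writer) or a data frame (reader).
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
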