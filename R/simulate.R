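#' Configuration for the mutation-selection genome simulator
#'
#' Bundles and validates the parameters of [simulate_genome()]. The simulator
#' draws, for each codon position of each gene, a synonymous codon from
#' \deqn{P(c) \propto \mu_c \exp(S \, x_g \, \delta_c)} within the amino
#' acid's family, where the mutational weight
#' \eqn{\mu_c = \theta^{g(c)} (1-\theta)^{3-g(c)}} depends on the codon's
#' G+C count \eqn{g(c)}, \eqn{S \ge 0} is the genome's translational
#' selection strength, \eqn{x_g \in [0,1]} the gene's expression level and
#' \eqn{\delta_c = 1} only for the family's preferred codon. Ribosomal genes
#' are pinned at \eqn{x = 1}; other genes draw \eqn{x \sim}
#' Beta(`expression_shape1`, `expression_shape2`), right-skewed by default so
#' only a small group of genes is highly expressed — the premise under which
#' a selected genome shows low CAI_ave.
#'
#' @param S Selection strength (>= 0).
#' @param theta GC pressure in (0, 1): the stationary G+C probability of the
#'   mutational process.
#' @param n_genes Number of genes (>= 50; default 300).
#' @param n_ribosomal Number of ribosomal (highly expressed, x = 1) genes
#'   (>= 20, < `n_genes`; default 40).
#' @param seed Mandatory RNG seed: every simulation is reproducible.
#' @param length_meanlog,length_sdlog Log-normal gene length (in codons)
#'   parameters; defaults give a median of 300 codons.
#' @param length_min,length_max Length clip bounds in codons (60, 2000).
#' @param expression_shape1,expression_shape2 Beta parameters of non-
#'   ribosomal expression levels (default Beta(1, 4)).
#' @param aa_frequencies Optional named probability vector over the 20
#'   amino-acid letters (default uniform).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(S = 0, theta = 0.5, n_genes = 300L,
                              n_ribosomal = 40L, seed,
                              length_meanlog = log(300), length_sdlog = 0.5,
                              length_min = 60L, length_max = 2000L,
                              expression_shape1 = 1, expression_shape2 = 4,
                              aa_frequencies = NULL) {
  if (missing(seed)) stopf("`seed` is mandatory: simulations must be reproducible")
  assert_scalar_number(seed, "seed")
  assert_scalar_number(S, "S", lo = 0)
  assert_scalar_number(theta, "theta", lo = 1e-6, hi = 1 - 1e-6)
  assert_scalar_number(n_genes, "n_genes", lo = 50)
  assert_scalar_number(n_ribosomal, "n_ribosomal", lo = 20)
  if (n_ribosomal >= n_genes) stopf("`n_ribosomal` must be < `n_genes`")
  assert_scalar_number(length_min, "length_min", lo = 1)
  assert_scalar_number(length_max, "length_max", lo = length_min)
  assert_scalar_number(expression_shape1, "expression_shape1", lo = 1e-9)
  assert_scalar_number(expression_shape2, "expression_shape2", lo = 1e-9)
  aas <- sort(names(genetic_code()$families))
  if (is.null(aa_frequencies)) {
    aa_frequencies <- setNames(rep(1 / length(aas), length(aas)), aas)
  } else {
    if (!all(sort(names(aa_frequencies)) == aas) || any(aa_frequencies < 0) ||
        abs(sum(aa_frequencies) - 1) > 1e-8) {
      stopf("`aa_frequencies` must be a probability vector over the 20 amino acids")
    }
    aa_frequencies <- aa_frequencies[aas]
  }
  structure(
    list(S = S, theta = theta, n_genes = as.integer(n_genes),
         n_ribosomal = as.integer(n_ribosomal), seed = as.integer(seed),
         length_meanlog = length_meanlog, length_sdlog = length_sdlog,
         length_min = as.integer(length_min),
         length_max = as.integer(length_max),
         expression_shape1 = expression_shape1,
         expression_shape2 = expression_shape2,
         aa_frequencies = aa_frequencies),
    class = "simulation_config"
  )
}

#' Draw a preferred-codon map
#'
#' Chooses one preferred codon per degenerate synonymous family, uniformly at
#' random (or weighted towards GC-rich codons via `gc_lean`). Preferred
#' codons vary between organisms in nature (they track the organism's tRNA
#' pool), so each simulated genome draws its own map. Uses the current RNG
#' state; call inside a seeded context.
#'
#' @param code A [genetic_code()] object.
#' @param gc_lean Optional weight multiplier per G/C nucleotide: sampling
#'   weight for codon c is `gc_lean^gc(c)` (default 1 = uniform).
#' @return Named character vector: family amino-acid letter -> codon.
#' @export
sample_preferred_codons <- function(code = genetic_code(), gc_lean = 1) {
  fams <- code$families[code$degeneracy >= 2L]
  vapply(fams, function(fam) {
    w <- gc_lean^codon_gc_count(fam)
    if (length(fam) == 1L) fam else sample(fam, 1L, prob = w / sum(w))
  }, character(1))
}

# Number of G/C nucleotides in each codon.
codon_gc_count <- function(codons) {
  vapply(strsplit(codons, ""), function(x) sum(x %in% c("G", "C")),
         integer(1))
}

# Per-family codon-choice probabilities for one gene.
codon_choice_probs <- function(fam, S, x_g, theta, preferred) {
  g <- codon_gc_count(fam)
  mu <- theta^g * (1 - theta)^(3 - g)
  w <- mu * exp(S * x_g * as.numeric(fam == preferred))
  w / sum(w)
}

#' Simulate one protein-coding gene
#'
#' Draws `length` amino acids i.i.d. from the configured amino-acid
#' frequencies and, for each, a synonymous codon from the mutation-selection
#' distribution (see [simulation_config()]). A start codon ATG is prepended
#' and a stop codon TAA appended. Uses the current RNG state.
#'
#' @param length Gene length in codons (excluding start/stop).
#' @param x_g Expression level in [0, 1].
#' @param config A `simulation_config`.
#' @param preferred Preferred-codon map ([sample_preferred_codons()]).
#' @return The gene's DNA sequence (character scalar).
#' @export
simulate_gene <- function(length, x_g, config, preferred) {
  stopifnot(inherits(config, "simulation_config"))
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stopf("invalid gene length")
  code <- genetic_code()
  aas <- names(config$aa_frequencies)
  aa_seq <- sample(aas, length, replace = TRUE, prob = config$aa_frequencies)
  codons <- character(length)
  for (aa in unique(aa_seq)) {
    fam <- code$families[[aa]]
    idx <- which(aa_seq == aa)
    if (length(fam) == 1L) {
      codons[idx] <- fam
    } else {
      p <- codon_choice_probs(fam, config$S, x_g, config$theta,
                              preferred[[aa]])
      codons[idx] <- sample(fam, length(idx), replace = TRUE, prob = p)
    }
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

#' Simulate a prokaryote-like genome with known ground truth
#'
#' Generates a CDS set under the mutation-selection codon-choice model: the
#' first `n_ribosomal` genes are the ribosomal (highly expressed, x = 1)
#' reference set; the rest draw expression levels from the configured Beta
#' distribution. With `S = 0` the genome is *unbiased* (synonymous choice is
#' purely mutational and identical across genes); with large `S` the genome
#' is *biased*: highly expressed genes converge on the preferred codons while
#' weakly expressed genes remain mutation-dominated, which lowers CAI_ave and
#' raises Nc_diff, the CAI coefficient of variation and the ribosomal-versus-
#' rest codon frequency difference.
#'
#' @param config A [simulation_config()].
#' @param organism_id Identifier used in gene ids and the truth table.
#' @return A list of class `simulated_genome`: `genes` (a gene table directly
#'   usable by [profile_genome()]; ribosomal gene ids carry the prefix
#'   `RIB_`, others `GEN_`) and `truth` (per-gene data frame with `gene_id`,
#'   `x_g`, `is_ribosomal`, `length_codons`; attributes `S`, `theta`,
#'   `preferred`, `organism_id`, `seed`). Fully reproducible from the seed.
#' @export
simulate_genome <- function(config, organism_id = "sim") {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    preferred <- sample_preferred_codons()
    n <- config$n_genes
    n_rib <- config$n_ribosomal
    lens <- round(stats::rlnorm(n, config$length_meanlog, config$length_sdlog))
    lens <- pmin(pmax(lens, config$length_min), config$length_max)
    x <- c(rep(1, n_rib),
           stats::rbeta(n - n_rib, config$expression_shape1,
                        config$expression_shape2))
    is_rib <- seq_len(n) <= n_rib
    ids <- ifelse(is_rib,
                  sprintf("RIB_%04d", seq_len(n)),
                  sprintf("GEN_%04d", seq_len(n)))
    seqs <- character(n)
    for (i in seq_len(n)) {
      seqs[i] <- simulate_gene(lens[i], x[i], config, preferred)
    }
    genes <- data.frame(
      gene_id = ids, sequence = seqs, is_ribosomal = is_rib,
      product = ifelse(is_rib, "ribosomal protein (simulated)",
                       NA_character_),
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      gene_id = ids, x_g = x, is_ribosomal = is_rib,
      length_codons = as.integer(lens), stringsAsFactors = FALSE
    )
    attr(truth, "S") <- config$S
    attr(truth, "theta") <- config$theta
    attr(truth, "preferred") <- preferred
    attr(truth, "organism_id") <- organism_id
    attr(truth, "seed") <- config$seed
    structure(list(genes = genes, truth = truth, config = config,
                   organism_id = organism_id),
              class = "simulated_genome")
  })
}

#' Simulate a panel of genomes over a configuration grid
#'
#' One genome per configuration, e.g. spanning a grid of selection strengths
#' at fixed GC pressure for parameter-recovery and correlation studies.
#'
#' @param configs A list of at least two [simulation_config()] objects.
#' @param organism_ids Optional identifiers (default `sim_01`, `sim_02`, ...).
#' @return A list of class `simulated_panel`: `genomes` (list of
#'   `simulated_genome`) and `grid` (data frame of organism_id, S, theta,
#'   seed).
#' @export
simulate_panel <- function(configs, organism_ids = NULL) {
  if (!is.list(configs) || length(configs) < 2L) {
    stopf("need at least 2 configurations")
  }
  ok <- vapply(configs, inherits, logical(1), what = "simulation_config")
  if (!all(ok)) stopf("all elements must be simulation_config objects")
  organism_ids <- organism_ids %||%
    sprintf("sim_%02d", seq_along(configs))
  genomes <- Map(simulate_genome, configs, organism_ids)
  grid <- data.frame(
    organism_id = organism_ids,
    S = vapply(configs, `[[`, numeric(1), "S"),
    theta = vapply(configs, `[[`, numeric(1), "theta"),
    seed = vapply(configs, `[[`, integer(1), "seed"),
    stringsAsFactors = FALSE
  )
  structure(list(genomes = genomes, grid = grid), class = "simulated_panel")
}

#' Profile every genome of a simulated panel
#'
#' Runs [profile_genome()] on each simulated genome and joins the ground-
#' truth selection strength and GC pressure, giving the substrate for
#' parameter-recovery checks (CAI_ave decreasing in S, Nc_diff increasing in
#' S, and the coupling between CAI_ave, the CAI coefficient of variation and
#' the codon frequency difference).
#'
#' @param panel A [simulate_panel()] result.
#' @param ... Passed to [profile_genome()].
#' @return A data frame: one profile row per genome plus `S` and `theta`.
#' @export
profile_panel <- function(panel, ...) {
  stopifnot(inherits(panel, "simulated_panel"))
  profs <- lapply(panel$genomes, function(g) {
    p <- profile_genome(g$genes, organism_id = g$organism_id, ...)
    attr(p, "gene_scores") <- NULL
    as.data.frame(p)
  })
  out <- do.call(rbind, profs)
  merge(out, panel$grid[, c("organism_id", "S", "theta")],
        by = "organism_id", sort = FALSE)
}

#' A selection-strength grid panel at fixed GC pressure
#'
#' Convenience constructor for the standard validation panel: `n` genomes
#' with selection strengths evenly spaced over `s_range` at a common `theta`,
#' with per-genome seeds derived from `seed`.
#'
#' @param n Number of genomes (>= 2).
#' @param s_range Selection-strength range (default 0 to 5).
#' @param theta GC pressure (default 0.5).
#' @param seed Base seed; genome i uses `seed + i`.
#' @param ... Passed to [simulation_config()] (e.g. `n_genes`).
#' @return A `simulated_panel`.
#' @export
selection_grid_panel <- function(n = 40L, s_range = c(0, 5), theta = 0.5,
                                 seed, ...) {
  if (missing(seed)) stopf("`seed` is mandatory")
  s_values <- seq(s_range[1L], s_range[2L], length.out = n)
  configs <- lapply(seq_len(n), function(i) {
    simulation_config(S = s_values[i], theta = theta, seed = seed + i, ...)
  })
  simulate_panel(configs)
}
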