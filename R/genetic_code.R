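#' The standard bacterial genetic code and its synonymous-family structure
#'
#' Builds the codon table for NCBI translation table 11 (the bacterial,
#' archaeal and plant plastid code) together with the structures that codon
#' bias measures operate on: the synonymous families (one per amino acid) and
#' their degeneracy classes. Under this code there are 61 sense codons, two
#' single-codon families (Met, Trp), nine two-fold families, one three-fold
#' family (Ile), five four-fold families and three six-fold families
#' (Leu, Ser, Arg).
#'
#' @return An object of class `genetic_code`: a list with elements
#'   `codon_aa` (named character vector mapping the 64 codons to amino-acid
#'   letters, `"*"` for stops), `sense_codons`, `stop_codons`, `families`
#'   (list of codon vectors keyed by amino-acid letter), `degeneracy`
#'   (named integer vector of family sizes), and `cai_codons` (the sense
#'   codons of degenerate families, i.e. excluding Met and Trp, over which
#'   the Codon Adaptation Index is defined).
#' @export
#' @examples
#' code <- genetic_code()
#' code$degeneracy[c("I", "L", "K")]
genetic_code <- function() {
  cached <- get0("code", envir = .codonbias_cache)
  if (!is.null(cached)) {
    return(cached)
  }
  codon_aa <- Biostrings::getGeneticCode("11")
  attributes(codon_aa) <- list(names = names(codon_aa))
  sense <- names(codon_aa)[codon_aa != "*"]
  families <- split(sense, codon_aa[sense])
  degeneracy <- lengths(families)
  code <- structure(
    list(
      codon_aa = codon_aa,
      sense_codons = sense,
      stop_codons = names(codon_aa)[codon_aa == "*"],
      families = families,
      degeneracy = degeneracy,
      cai_codons = unlist(families[degeneracy >= 2L], use.names = FALSE)
    ),
    class = "genetic_code"
  )
  assign("code", code, envir = .codonbias_cache)
  code
}

.codonbias_cache <- new.env(parent = emptyenv())

#' All 64 codons in Biostrings order
#' @return Character vector of length 64.
#' @keywords internal
all_codons <- function() names(genetic_code()$codon_aa)

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code (translation table 11):",
      length(x$sense_codons), "sense codons,",
      length(x$families), "amino-acid families\n")
  cat("Degeneracy classes:",
      paste(sprintf("%d-fold x %d", sort(unique(x$degeneracy)),
                    table(x$degeneracy)), collapse = ", "), "\n")
  invisible(x)
}
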