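#' Genetic code tables and synonymous families
#'
#' Builds a genetic-code object from an NCBI translation table. The object
#' defines the synonymous families over which all codon-use probabilities in
#' this package are normalized. Table 1 (standard) has 61 sense codons; table
#' 4 (TGA read as tryptophan, used by Mollicutes among others) has 62.
#'
#' @param table NCBI translation table identifier (1 or 4 are the tables this
#'   package is routinely used with; any id known to
#'   \code{\link[Biostrings]{getGeneticCode}} is accepted).
#' @return An object of class \code{genetic_code}: a list with
#'   \describe{
#'     \item{table_id}{the translation table identifier}
#'     \item{codon_to_aa}{named character vector over all 64 codons
#'       (\code{"*"} marks stop)}
#'     \item{sense_codons}{ordered character vector of non-stop codons}
#'     \item{aa_of}{amino acid (one-letter) per sense codon}
#'     \item{families}{named list: amino acid -> its synonymous codons}
#'   }
#' @examples
#' code <- genetic_code(1)
#' length(code$sense_codons)  # 61
#' code$families$C            # "TGC" "TGT"
#' @export
genetic_code <- function(table = 1) {
  tab <- Biostrings::getGeneticCode(as.character(table))
  codons <- sort(names(tab))
  codon_to_aa <- tab[codons]
  sense <- codons[codon_to_aa != "*"]
  aa_of <- codon_to_aa[sense]
  families <- split(sense, aa_of)
  structure(
    list(
      table_id = table,
      codon_to_aa = codon_to_aa,
      sense_codons = sense,
      aa_of = aa_of,
      families = families
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code (translation table ", x$table_id, "): ",
      length(x$sense_codons), " sense codons, ",
      length(x$families), " amino acids\n", sep = "")
  invisible(x)
}

is_genetic_code <- function(x) inherits(x, "genetic_code")

# Normalize codon input: uppercase, RNA -> DNA alphabet.
normalize_codons <- function(codons) {
  chartr("u", "T", chartr("U", "T", toupper(codons)))
}

# Validate a vector of codons against the 64-codon table; named error
# identifying the first offending codon.
check_codons <- function(codons) {
  ok <- grepl("^[ACGT]{3}$", codons)
  if (!all(ok)) {
    bad <- codons[!ok][1]
    stop("invalid codon: '", bad, "' (expected three characters over A/C/G/T/U)",
         call. = FALSE)
  }
  invisible(codons)
}
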