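#' Nitrogen atom counts per nucleotide, base pair and amino-acid side chain
#'
#' The elemental bookkeeping the whole package rests on. Purines carry five
#' nitrogen atoms, cytosine three, thymine/uracil two; a base pair therefore
#' carries 7 (A:T) or 8 (G:C). Side-chain counts follow standard amino-acid
#' chemistry (arginine 3, histidine 2, lysine/asparagine/glutamine/tryptophan
#' 1, all others 0). The same tables ship as editable TSV configs under
#' \code{system.file("extdata", package = "codonN")} so that alternative
#' element tables (e.g. carbon) can be swapped in.
#'
#' @return A list with components \code{per_nucleotide}, \code{per_basepair}
#'   and \code{per_sidechain}, each a named integer vector of atom counts.
#' @examples
#' nitrogen_table()$per_nucleotide["A"]  # 5
#' @export
nitrogen_table <- function() {
  list(
    per_nucleotide = c(A = 5L, G = 5L, C = 3L, T = 2L, U = 2L),
    per_basepair = c(AT = 7L, GC = 8L),
    per_sidechain = c(
      A = 0L, C = 0L, D = 0L, E = 0L, F = 0L, G = 0L, H = 2L, I = 0L,
      K = 1L, L = 0L, M = 0L, N = 1L, P = 0L, Q = 1L, R = 3L, S = 0L,
      T = 0L, V = 0L, W = 1L, Y = 0L
    )
  )
}

#' Nitrogen atoms in a codon's mRNA (single-stranded) form
#'
#' Sums the per-nucleotide nitrogen content over the three codon positions.
#' T and U are equivalent. Values range from 6 (TTT) to 15 (e.g. GGG).
#'
#' @param codons character vector of trinucleotides over A/C/G/T/U
#'   (case-insensitive).
#' @return integer vector of nitrogen atom counts, one per codon.
#' @examples
#' nitrogen_mrna(c("TGC", "GGG", "TTT"))  # 10 15 6
#' @export
nitrogen_mrna <- function(codons) {
  codons <- normalize_codons(codons)
  check_codons(codons)
  unname(.codon_n_lookup()[codons])
}

# per-codon nitrogen over all 64 codons, built once per session
.codon_cache <- new.env(parent = emptyenv())
.codon_n_lookup <- function() {
  if (is.null(.codon_cache$n64)) {
    nts <- c("A", "C", "G", "T")
    codons <- as.vector(outer(outer(nts, nts, paste0), nts, paste0))
    per_nt <- nitrogen_table()$per_nucleotide
    .codon_cache$n64 <- vapply(strsplit(codons, "", fixed = TRUE),
                               function(nt) sum(per_nt[nt]), integer(1))
    names(.codon_cache$n64) <- codons
  }
  .codon_cache$n64
}

#' Nitrogen atoms in a codon's double-stranded DNA form
#'
#' Counts both strands: each A or T position contributes an A:T pair
#' (7 atoms), each G or C position a G:C pair (8 atoms). Values range from
#' 21 (all A:T) to 24 (all G:C).
#'
#' @inheritParams nitrogen_mrna
#' @return integer vector of nitrogen atom counts per double-stranded codon.
#' @examples
#' nitrogen_dsdna(c("AAA", "GCG", "ATG"))  # 21 24 22
#' @export
nitrogen_dsdna <- function(codons) {
  codons <- normalize_codons(codons)
  check_codons(codons)
  bp <- nitrogen_table()$per_basepair
  at <- at_count(codons)
  as.integer(bp[["AT"]] * at + bp[["GC"]] * (3L - at))
}

# Number of A/T nucleotides in each codon (assumed normalized).
at_count <- function(codons) {
  nchar(codons) - nchar(gsub("[AT]", "", codons))
}

#' Nitrogen atoms in an amino-acid side chain
#'
#' @param aa character vector of one-letter amino-acid codes (the 20 standard
#'   residues).
#' @return integer vector of side-chain nitrogen atom counts.
#' @examples
#' nitrogen_sidechain(c("R", "G", "H"))  # 3 0 2
#' @export
nitrogen_sidechain <- function(aa) {
  aa <- toupper(aa)
  per_sc <- nitrogen_table()$per_sidechain
  bad <- !(aa %in% names(per_sc))
  if (any(bad)) {
    stop("unknown amino acid residue: '", aa[bad][1], "'", call. = FALSE)
  }
  unname(per_sc[aa])
}

#' Total nitrogen content of an RNA or DNA sequence
#'
#' Sums per-nucleotide nitrogen over every position; additive over
#' concatenation, so a per-ribosome total is the sum over the constituent
#' rRNA molecules. Gap characters (\code{-}) are ignored.
#'
#' @param sequence a single character string over A/C/G/T/U (case-insensitive,
#'   gaps allowed).
#' @return integer atom count (0 for an empty sequence).
#' @examples
#' rna_total_nitrogen("ACGU")  # 15
#' @export
rna_total_nitrogen <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  s <- gsub("-", "", chartr("Uu", "TT", toupper(sequence)), fixed = TRUE)
  if (nchar(s) == 0L) return(0L)
  nt <- strsplit(s, "", fixed = TRUE)[[1]]
  per_nt <- nitrogen_table()$per_nucleotide
  bad <- !(nt %in% names(per_nt))
  if (any(bad)) {
    pos <- which(bad)[1]
    stop("invalid character '", nt[pos], "' at position ", pos, call. = FALSE)
  }
  sum(per_nt[nt])
}

#' Mean nitrogen per codon for a gene
#'
#' Arithmetic mean of per-codon nitrogen content over a list of codons, in
#' either single-stranded (mRNA) or double-stranded (dsDNA) accounting.
#'
#' @param codons character vector of codons.
#' @param mode \code{"mRNA"} or \code{"dsDNA"}.
#' @return mean nitrogen atoms per codon (numeric scalar).
#' @examples
#' mean_nitrogen_per_codon(c("TGC", "TGT"))           # 9.5
#' mean_nitrogen_per_codon("GCG", mode = "dsDNA")     # 24
#' @export
mean_nitrogen_per_codon <- function(codons, mode = c("mRNA", "dsDNA")) {
  mode <- match.arg(mode)
  if (length(codons) == 0L) {
    stop("empty codon list: mean nitrogen per codon is undefined", call. = FALSE)
  }
  if (mode == "mRNA") mean(nitrogen_mrna(codons)) else mean(nitrogen_dsdna(codons))
}
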