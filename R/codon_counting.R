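#' Count sense codons in a set of coding sequences
#'
#' Reads in-frame CDS and tallies sense-codon use per gene and pooled across
#' genes. Validation policy: a gene whose length is not a multiple of three
#' is dropped (logged, not fatal); a terminal stop codon is discarded; a gene
#' with an internal stop is dropped; individual codons containing characters
#' other than A/C/G/T/U are skipped. Counts are therefore defined over the
#' sense codons of the active genetic code only.
#'
#' @param cds a named character vector of nucleotide sequences, a
#'   \code{\link[Biostrings]{DNAStringSet}}, or the path to a (multi-)FASTA
#'   file. FASTA headers are parsed up to the first whitespace as gene ids.
#' @param code a \code{\link{genetic_code}}.
#' @param species_id optional label carried through to downstream tables.
#' @return An object of class \code{codon_counts}: list with
#'   \describe{
#'     \item{species_id}{label}
#'     \item{per_gene}{integer matrix, genes x sense codons}
#'     \item{pooled}{named integer vector over sense codons}
#'     \item{n_genes}{number of genes retained}
#'     \item{dropped}{data.frame (gene, reason) of excluded genes}
#'     \item{summary}{list: kept, dropped, codons_skipped}
#'   }
#' @examples
#' code <- genetic_code(1)
#' cc <- count_codons(c(g1 = "ATGTGCTGTTGTTAA"), code)
#' cc$pooled[c("ATG", "TGC", "TGT")]  # 1 1 2
#' @export
count_codons <- function(cds, code = genetic_code(1), species_id = NA_character_) {
  stopifnot(is_genetic_code(code))
  if (is.character(cds) && length(cds) == 1L && file.exists(cds)) {
    cds <- Biostrings::readDNAStringSet(cds)
  }
  if (inherits(cds, "XStringSet")) {
    cds <- stats::setNames(as.character(cds), names(cds))
  }
  if (length(cds) == 0L) stop("empty CDS input", call. = FALSE)
  ids <- names(cds)
  if (is.null(ids)) ids <- paste0("gene", seq_along(cds))
  ids <- sub("\\s.*$", "", ids)
  seqs <- chartr("Uu", "TT", toupper(cds))

  sense <- code$sense_codons
  stops <- setdiff(names(code$codon_to_aa), sense)
  per_gene <- matrix(0L, nrow = length(seqs), ncol = length(sense),
                     dimnames = list(ids, sense))
  dropped <- character(0); dropped_reason <- character(0)
  skipped <- 0L
  keep <- logical(length(seqs))

  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    if (nchar(s) %% 3L != 0L) {
      dropped <- c(dropped, ids[i])
      dropped_reason <- c(dropped_reason, "length not a multiple of 3")
      next
    }
    cod <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    if (length(cod) == 0L) {
      dropped <- c(dropped, ids[i])
      dropped_reason <- c(dropped_reason, "empty sequence")
      next
    }
    # terminal stop discarded
    if (cod[length(cod)] %in% stops) cod <- cod[-length(cod)]
    if (any(cod %in% stops)) {
      dropped <- c(dropped, ids[i])
      dropped_reason <- c(dropped_reason, "internal stop codon")
      next
    }
    valid <- grepl("^[ACGT]{3}$", cod)
    skipped <- skipped + sum(!valid)
    cod <- cod[valid]
    tab <- table(factor(cod, levels = sense))
    per_gene[i, ] <- as.integer(tab)
    keep[i] <- TRUE
  }

  per_gene <- per_gene[keep, , drop = FALSE]
  structure(
    list(
      species_id = species_id,
      per_gene = per_gene,
      pooled = colSums(per_gene)[sense],
      n_genes = nrow(per_gene),
      code = code,
      dropped = data.frame(gene = dropped, reason = dropped_reason,
                           stringsAsFactors = FALSE),
      summary = list(kept = sum(keep), dropped = length(dropped),
                     codons_skipped = skipped)
    ),
    class = "codon_counts"
  )
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("Codon counts", if (!is.na(x$species_id)) paste0(" [", x$species_id, "]"),
      ": ", x$n_genes, " genes, ", sum(x$pooled), " sense codons (",
      x$summary$dropped, " genes dropped, ", x$summary$codons_skipped,
      " codons skipped)\n", sep = "")
  invisible(x)
}

# Coerce counts input (codon_counts object or named numeric vector) to a
# pooled vector aligned with code$sense_codons.
pooled_counts <- function(counts, code) {
  if (inherits(counts, "codon_counts")) counts <- counts$pooled
  if (is.null(names(counts))) {
    stop("counts must be named by codon", call. = FALSE)
  }
  out <- stats::setNames(numeric(length(code$sense_codons)), code$sense_codons)
  known <- intersect(names(counts), code$sense_codons)
  out[known] <- counts[known]
  out
}

#' Empirical codon-use probabilities
#'
#' Converts pooled codon counts to per-family codon-use probabilities: within
#' every synonymous family, probability = codon count / family total. A family
#' with zero total count is given uniform probabilities with a warning, so
#' that downstream likelihoods stay defined on sparse inputs.
#'
#' @param counts a \code{codon_counts} object or named numeric vector of
#'   pooled counts.
#' @param code a \code{\link{genetic_code}} (taken from \code{counts} when it
#'   carries one).
#' @return A \code{codon_prob_table}: named numeric vector of probabilities
#'   over sense codons with the code attached as attribute \code{code}.
#' @examples
#' code <- genetic_code(1)
#' p <- empirical_probs(c(TGC = 1, TGT = 3), code)
#' p[c("TGC", "TGT")]  # 0.25 0.75
#' @export
empirical_probs <- function(counts, code = NULL) {
  if (is.null(code)) {
    code <- if (inherits(counts, "codon_counts")) counts$code else genetic_code(1)
  }
  cnt <- pooled_counts(counts, code)
  probs <- stats::setNames(numeric(length(cnt)), names(cnt))
  zero_fams <- character(0)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    tot <- sum(cnt[fam])
    if (tot > 0) {
      probs[fam] <- cnt[fam] / tot
    } else {
      probs[fam] <- 1 / length(fam)
      zero_fams <- c(zero_fams, aa)
    }
  }
  if (length(zero_fams) > 0) {
    warning("zero-count synonymous families set to uniform probabilities: ",
            paste(zero_fams, collapse = ", "), call. = FALSE)
  }
  new_codon_prob_table(probs, code)
}

new_codon_prob_table <- function(probs, code) {
  structure(probs, code = code, class = "codon_prob_table")
}

#' @export
print.codon_prob_table <- function(x, ...) {
  cat("Codon-use probability table over", length(x), "sense codons\n")
  print(unclass(x)[seq_len(min(6, length(x)))])
  if (length(x) > 6) cat("...\n")
  invisible(x)
}

#' Write codon counts to TSV
#'
#' @param counts a \code{codon_counts} object.
#' @param per_gene_path,pooled_path output paths (either may be NULL to skip).
#' @return invisibly, the long-format per-gene data.frame.
#' @export
write_codon_counts <- function(counts, per_gene_path = NULL, pooled_path = NULL) {
  stopifnot(inherits(counts, "codon_counts"))
  pg <- counts$per_gene
  long <- data.frame(
    gene = rep(rownames(pg), times = ncol(pg)),
    codon = rep(colnames(pg), each = nrow(pg)),
    count = as.vector(pg),
    stringsAsFactors = FALSE
  )
  long <- long[long$count > 0, ]
  if (!is.null(per_gene_path)) {
    utils::write.table(long, per_gene_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(pooled_path)) {
    pooled <- data.frame(codon = names(counts$pooled),
                         count = as.integer(counts$pooled))
    utils::write.table(pooled, pooled_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(long)
}
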