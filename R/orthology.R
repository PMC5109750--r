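#' Filter orthogroups to single-copy groups with per-group coverage
#'
#' Retains orthogroups in which every represented species contributes exactly
#' one gene and every nitrogen-availability group is represented by at least
#' \code{min_per_group} species.
#'
#' @param membership data.frame with columns \code{orthogroup_id},
#'   \code{species_id}, \code{gene_id}, or path to such a TSV.
#' @param groups data.frame with columns \code{species_id}, \code{group}, or
#'   path to a TSV; every species in \code{membership} must be labelled.
#' @param min_per_group minimum species per group (default 3).
#' @return character vector of retained orthogroup ids.
#' @export
filter_orthogroups <- function(membership, groups, min_per_group = 3L) {
  if (is.character(membership)) {
    membership <- utils::read.delim(membership, stringsAsFactors = FALSE)
  }
  if (is.character(groups)) {
    groups <- utils::read.delim(groups, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("orthogroup_id", "species_id", "gene_id") %in%
                  names(membership)),
            all(c("species_id", "group") %in% names(groups)))
  unknown <- setdiff(membership$species_id, groups$species_id)
  if (length(unknown) > 0) {
    stop("species without a group label: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  grp <- stats::setNames(groups$group, groups$species_id)
  all_groups <- unique(groups$group)
  keep <- vapply(split(membership, membership$orthogroup_id), function(og) {
    per_species <- table(og$species_id)
    if (any(per_species > 1)) return(FALSE)  # single-copy rule
    cov <- table(factor(grp[og$species_id], levels = all_groups))
    all(cov >= min_per_group)
  }, logical(1))
  names(keep)[keep]
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Re-threads each species' coding sequence through its aligned amino-acid
#' row: every residue is replaced by its source codon and every gap becomes a
#' triple gap. The CDS must translate exactly to the ungapped protein row
#' under the active code (a terminal stop codon on the CDS is tolerated);
#' any mismatch is a named error citing species, position and the
#' expected/observed residues.
#'
#' @param protein_rows named character vector of aligned amino-acid rows
#'   (equal lengths; \code{-} for gaps), one per species/gene.
#' @param cds named character vector of coding sequences, names matching
#'   \code{protein_rows}.
#' @param code a \code{\link{genetic_code}}.
#' @param orthogroup_id optional id carried through to the result.
#' @return an \code{orthogroup_alignment}: list with \code{orthogroup_id},
#'   \code{codon_rows} (matrix: rows = species, columns = aligned codon
#'   positions, entries = codons or \code{"---"}) and \code{n_columns}.
#' @export
backtranslate_alignment <- function(protein_rows, cds,
                                    code = genetic_code(1),
                                    orthogroup_id = NA_character_) {
  stopifnot(!is.null(names(protein_rows)), all(names(protein_rows) %in%
                                                 names(cds)))
  widths <- nchar(protein_rows)
  if (length(unique(widths)) != 1) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  ncol_aln <- widths[[1]]
  stops <- setdiff(names(code$codon_to_aa), code$sense_codons)
  rows <- matrix("---", nrow = length(protein_rows), ncol = ncol_aln,
                 dimnames = list(names(protein_rows), NULL))
  for (sp in names(protein_rows)) {
    aa <- strsplit(toupper(protein_rows[[sp]]), "", fixed = TRUE)[[1]]
    s <- chartr("Uu", "TT", toupper(cds[[sp]]))
    if (nchar(s) %% 3L != 0L) {
      stop("CDS length of '", sp, "' is not a multiple of 3", call. = FALSE)
    }
    cod <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    if (length(cod) > 0 && cod[length(cod)] %in% stops) {
      cod <- cod[-length(cod)]
    }
    residues <- which(aa != "-")
    if (length(cod) != length(residues)) {
      stop("back-translation mismatch for '", sp, "': ", length(residues),
           " aligned residues but ", length(cod), " codons", call. = FALSE)
    }
    translated <- unname(code$codon_to_aa[cod])
    bad <- which(translated != aa[residues])
    if (length(bad) > 0) {
      stop("back-translation mismatch for '", sp, "' at alignment position ",
           residues[bad[1]], ": expected '", aa[residues][bad[1]],
           "', CDS encodes '", translated[bad[1]], "'", call. = FALSE)
    }
    rows[sp, residues] <- cod
  }
  structure(list(orthogroup_id = orthogroup_id, codon_rows = rows,
                 n_columns = ncol_aln),
            class = "orthogroup_alignment")
}

#' Filter alignment columns by gaps and column score
#'
#' Keeps columns that are gap-free in every row AND have a column score
#' strictly greater than the threshold. External column scores (e.g. from an
#' alignment-merging tool) are consumed when given; otherwise a fallback
#' score — the fraction of rows matching the column's modal codon-encoded
#' residue — is computed. The fallback is a plain conservation proxy, not
#' equivalent to an externally computed alignment score.
#'
#' @param aln an \code{orthogroup_alignment}.
#' @param scores numeric vector, one score per alignment column, or
#'   \code{NULL} for the fallback score.
#' @param threshold retain columns with score strictly above this (default
#'   0.75).
#' @param code a \code{\link{genetic_code}} (used by the fallback score).
#' @return the alignment with columns subset to those kept; attribute
#'   \code{kept_columns} gives their original 1-based indices.
#' @export
filter_columns <- function(aln, scores = NULL, threshold = 0.75,
                           code = genetic_code(1)) {
  stopifnot(inherits(aln, "orthogroup_alignment"))
  rows <- aln$codon_rows
  gap_free <- colSums(rows == "---") == 0
  if (is.null(scores)) {
    scores <- vapply(seq_len(ncol(rows)), function(j) {
      if (!gap_free[j]) return(0)
      res <- unname(code$codon_to_aa[rows[, j]])
      max(table(res)) / length(res)
    }, numeric(1))
  }
  if (length(scores) != ncol(rows)) {
    stop("score vector length (", length(scores),
         ") does not match alignment columns (", ncol(rows), ")",
         call. = FALSE)
  }
  keep <- gap_free & scores > threshold
  out <- structure(list(orthogroup_id = aln$orthogroup_id,
                        codon_rows = rows[, keep, drop = FALSE],
                        n_columns = sum(keep)),
                   class = "orthogroup_alignment")
  attr(out, "kept_columns") <- which(keep)
  out
}

#' Paired per-gene nitrogen table over filtered orthogroups
#'
#' For every retained orthogroup and species, computes the mean nitrogen per
#' codon (mRNA and dsDNA accounting) over the kept alignment columns, plus
#' the aggregate number of orthologous codon columns compared (reported both
#' as columns and as columns summed over species). Orthogroups with zero kept
#' columns are excluded and logged.
#'
#' @param alignments list of filtered \code{orthogroup_alignment}s.
#' @param groups data.frame (\code{species_id}, \code{group}) or TSV path.
#' @return list with \code{table} (data.frame: orthogroup_id, species_id,
#'   group, n_codons, mean_n_mrna, mean_n_dsdna),
#'   \code{n_codon_columns}, \code{n_codons_total} (columns x species) and
#'   \code{excluded} (orthogroups with no kept columns).
#' @export
paired_nitrogen_table <- function(alignments, groups) {
  if (is.character(groups)) {
    groups <- utils::read.delim(groups, stringsAsFactors = FALSE)
  }
  grp <- stats::setNames(groups$group, groups$species_id)
  rows <- list(); excluded <- character(0)
  n_cols <- 0L; n_total <- 0L
  for (aln in alignments) {
    if (aln$n_columns == 0) {
      excluded <- c(excluded, aln$orthogroup_id)
      next
    }
    n_cols <- n_cols + aln$n_columns
    n_total <- n_total + aln$n_columns * nrow(aln$codon_rows)
    for (sp in rownames(aln$codon_rows)) {
      cod <- aln$codon_rows[sp, ]
      rows[[length(rows) + 1L]] <- data.frame(
        orthogroup_id = aln$orthogroup_id, species_id = sp,
        group = if (sp %in% names(grp)) grp[[sp]] else NA_character_,
        n_codons = length(cod),
        mean_n_mrna = mean_nitrogen_per_codon(cod, "mRNA"),
        mean_n_dsdna = mean_nitrogen_per_codon(cod, "dsDNA"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    stop("no orthogroup retained any alignment columns", call. = FALSE)
  }
  list(table = do.call(rbind, rows), n_codon_columns = n_cols,
       n_codons_total = n_total, excluded = excluded)
}

#' Per-orthogroup group means for paired tests
#'
#' Collapses a paired nitrogen table to one value per orthogroup per group
#' (the mean over that group's species), yielding the paired observations a
#' signed-rank test between two groups consumes.
#'
#' @param nitrogen_table the \code{table} component of
#'   \code{\link{paired_nitrogen_table}}.
#' @param value column to aggregate (\code{"mean_n_mrna"} or
#'   \code{"mean_n_dsdna"}).
#' @return data.frame: one row per orthogroup, one column per group.
#' @export
group_pair_means <- function(nitrogen_table, value = "mean_n_mrna") {
  stopifnot(value %in% names(nitrogen_table))
  agg <- stats::aggregate(nitrogen_table[[value]],
                          by = list(orthogroup_id = nitrogen_table$orthogroup_id,
                                    group = nitrogen_table$group),
                          FUN = mean)
  wide <- stats::reshape(agg, idvar = "orthogroup_id", timevar = "group",
                         direction = "wide")
  names(wide) <- sub("^x\\.", "", names(wide))
  wide
}

#' Total rRNA nitrogen per ribosome
#'
#' Sums the nitrogen content of a species' rRNA molecules. If any required
#' molecule is missing the species is flagged NF (not found) rather than
#' failing.
#'
#' @param seqs named character vector of rRNA sequences (or a FASTA path);
#'   names identify the molecules.
#' @param molecules character vector of required molecule names; default all
#'   names present in \code{seqs}.
#' @return list with \code{total} (atom count, \code{NA} when flagged),
#'   \code{status} (\code{"ok"} or \code{"NF"}), \code{missing},
#'   \code{per_molecule}.
#' @export
ribosome_nitrogen <- function(seqs, molecules = NULL) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs)) {
    x <- Biostrings::readBStringSet(seqs)
    seqs <- stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  }
  if (is.null(molecules)) molecules <- names(seqs)
  missing <- setdiff(molecules, names(seqs))
  per <- vapply(intersect(molecules, names(seqs)), function(m) {
    rna_total_nitrogen(seqs[[m]])
  }, integer(1))
  if (length(missing) > 0 || length(molecules) == 0) {
    return(list(total = NA_integer_, status = "NF", missing = missing,
                per_molecule = per))
  }
  list(total = sum(per), status = "ok", missing = character(0),
       per_molecule = per)
}
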