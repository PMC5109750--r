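#' Simulate a coding sequence from a codon-probability table
#'
#' Each residue of an amino-acid sequence is independently assigned a codon
#' drawn from its synonymous family's probabilities, so the translation of
#' the output equals the input by construction.
#'
#' @param aa_sequence amino-acid string (one-letter codes) or character
#'   vector of residues.
#' @param probs a \code{codon_prob_table} (from \code{\link{codon_probs}} or
#'   \code{\link{empirical_probs}}).
#' @param code a \code{\link{genetic_code}} (defaults to the table attached
#'   to \code{probs}).
#' @return character vector of codons, one per residue.
#' @examples
#' code <- genetic_code(1)
#' p <- codon_probs(model_params(mut_m = 3, variant = "mutation_only"), code)
#' set.seed(1); paste(simulate_cds("MCC", p), collapse = "")
#' @export
simulate_cds <- function(aa_sequence, probs, code = attr(probs, "code")) {
  stopifnot(is_genetic_code(code))
  aa <- if (length(aa_sequence) == 1L && nchar(aa_sequence) > 1L) {
    strsplit(aa_sequence, "", fixed = TRUE)[[1]]
  } else {
    as.character(aa_sequence)
  }
  bad <- !(aa %in% names(code$families))
  if (any(bad)) {
    stop("residue '", aa[bad][1], "' has no codon family in translation table ",
         code$table_id, call. = FALSE)
  }
  out <- character(length(aa))
  for (res in unique(aa)) {
    fam <- code$families[[res]]
    pos <- which(aa == res)
    if (length(fam) == 1L) {
      out[pos] <- fam
    } else {
      out[pos] <- sample(fam, length(pos), replace = TRUE, prob = probs[fam])
    }
  }
  out
}

#' Configuration and ground truth for a synthetic multi-species dataset
#'
#' Describes the study conditions the generator emulates: a set of species in
#' named nitrogen-availability groups, each species a collection of
#' single-copy orthologous CDS whose codons are drawn from the
#' selection-mutation model at the group's parameters. Defaults mirror a
#' Mollicute-style design: three groups (L_N, M_N, H_N) with selection biases
#' -0.24 / -0.15 / -0.13 and mutation bias 3.5, four species per group, 300
#' orthogroups, log-normal gene lengths with mean 630 codons, uniform
#' amino-acid frequencies.
#'
#' @param groups named list of \code{\link{model_params}}, one per group.
#' @param n_species_per_group species per group.
#' @param n_orthogroups number of single-copy orthogroups.
#' @param mean_length mean gene length in codons.
#' @param sdlog log-scale standard deviation of the log-normal length
#'   distribution.
#' @param aa_frequencies named probability vector over residues (must sum to
#'   1); default uniform over the 20 standard amino acids.
#' @param code a \code{\link{genetic_code}}.
#' @param seed integer seed recorded in (and used by) the generator.
#' @return a \code{synthetic_truth} list.
#' @export
synthetic_truth <- function(
    groups = list(
      L_N = model_params(sel_n = -0.24, mut_m = 3.5),
      M_N = model_params(sel_n = -0.15, mut_m = 3.5),
      H_N = model_params(sel_n = -0.13, mut_m = 3.5)
    ),
    n_species_per_group = 4L,
    n_orthogroups = 300L,
    mean_length = 630,
    sdlog = 0.45,
    aa_frequencies = NULL,
    code = genetic_code(1),
    seed = 1L) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)),
            n_species_per_group >= 1)
  if (n_orthogroups < 1) stop("need at least one orthogroup", call. = FALSE)
  if (is.null(aa_frequencies)) {
    aas <- setdiff(names(code$families), "*")
    aa_frequencies <- stats::setNames(rep(1 / length(aas), length(aas)), aas)
  }
  if (abs(sum(aa_frequencies) - 1) > 1e-8) {
    stop("aa_frequencies must sum to 1", call. = FALSE)
  }
  structure(
    list(groups = groups, n_species_per_group = as.integer(n_species_per_group),
         n_orthogroups = as.integer(n_orthogroups), mean_length = mean_length,
         sdlog = sdlog, aa_frequencies = aa_frequencies, code = code,
         seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' Generate a synthetic multi-species orthologous-CDS dataset
#'
#' For each orthogroup one shared amino-acid sequence is drawn (length from a
#' log-normal distribution, residues from the configured frequencies); each
#' species' CDS is then simulated under its group's model parameters. The
#' output is sufficient to run the whole downstream pipeline (counting,
#' fitting, orthology filtering, paired nitrogen comparison, classification)
#' end to end with known ground truth.
#'
#' @param truth a \code{\link{synthetic_truth}}.
#' @param dir optional output directory; when given, writes one CDS FASTA per
#'   species, \code{orthogroups.tsv} (orthogroup_id, species_id, gene_id),
#'   \code{groups.tsv} (species_id, group) and \code{truth.json}.
#' @return list with \code{cds} (named list: species -> named character
#'   vector of CDS), \code{proteins} (orthogroup -> amino-acid string),
#'   \code{orthogroups} and \code{groups} data.frames, and \code{truth}.
#' @export
generate_synthetic_dataset <- function(truth, dir = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  set.seed(truth$seed)
  code <- truth$code
  aas <- names(truth$aa_frequencies)

  meanlog <- log(truth$mean_length) - truth$sdlog^2 / 2
  lens <- pmax(1L, round(stats::rlnorm(truth$n_orthogroups, meanlog,
                                       truth$sdlog)))
  og_ids <- sprintf("OG%04d", seq_len(truth$n_orthogroups))
  proteins <- stats::setNames(lapply(lens, function(L) {
    sample(aas, L, replace = TRUE, prob = truth$aa_frequencies)
  }), og_ids)

  group_probs <- lapply(truth$groups, codon_probs, code = code)
  species <- unlist(lapply(names(truth$groups), function(g) {
    paste0(g, "_sp", seq_len(truth$n_species_per_group))
  }))
  group_of <- rep(names(truth$groups), each = truth$n_species_per_group)
  names(group_of) <- species

  cds <- stats::setNames(vector("list", length(species)), species)
  membership <- vector("list", length(species))
  for (i in seq_along(species)) {
    sp <- species[i]
    p <- group_probs[[group_of[[sp]]]]
    genes <- vapply(og_ids, function(og) {
      paste(simulate_cds(proteins[[og]], p, code), collapse = "")
    }, character(1))
    names(genes) <- paste0(sp, "|", og_ids)
    cds[[sp]] <- genes
    membership[[i]] <- data.frame(orthogroup_id = og_ids, species_id = sp,
                                  gene_id = names(genes),
                                  stringsAsFactors = FALSE)
  }
  orthogroups <- do.call(rbind, membership)
  groups <- data.frame(species_id = species, group = unname(group_of),
                       stringsAsFactors = FALSE)
  out <- list(cds = cds,
              proteins = lapply(proteins, paste, collapse = ""),
              orthogroups = orthogroups, groups = groups, truth = truth)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (sp in species) {
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(cds[[sp]]),
        file.path(dir, paste0(sp, ".cds.fasta")))
    }
    utils::write.table(orthogroups, file.path(dir, "orthogroups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(groups, file.path(dir, "groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(seed = truth$seed,
           n_species_per_group = truth$n_species_per_group,
           n_orthogroups = truth$n_orthogroups,
           mean_length = truth$mean_length, sdlog = truth$sdlog,
           table_id = code$table_id,
           groups = lapply(truth$groups, function(p) {
             p[c("sel_n", "mut_m", "sel_tai", "variant")]
           })),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Kernel density summary of per-gene mean nitrogen values
#'
#' Wraps \code{\link[stats]{density}} so that distributions of per-gene mean
#' nitrogen per codon can be reported as probability density functions whose
#' area integrates to one.
#'
#' @param values numeric vector (at least two distinct values).
#' @param ... passed to \code{\link[stats]{density}}.
#' @return list with \code{grid}, \code{density}, and the trapezoidal
#'   \code{integral} (close to 1).
#' @export
nitrogen_density_summary <- function(values, ...) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    stop("need at least two values for a density summary", call. = FALSE)
  }
  if (diff(range(values)) == 0) {
    stop("constant input: density is a degenerate spike", call. = FALSE)
  }
  d <- stats::density(values, ...)
  integral <- sum(diff(d$x) * (utils::head(d$y, -1) + utils::tail(d$y, -1)) / 2)
  list(grid = d$x, density = d$y, integral = integral)
}
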