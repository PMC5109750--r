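#' Paired Wilcoxon signed-rank test between two groups of per-gene means
#'
#' Orthologous genes present in two species (or group averages) are paired
#' observations; the test asks whether the paired differences are symmetric
#' around zero (two-tailed). Zero differences are dropped before testing.
#'
#' @param a,b numeric vectors of equal length (paired per-gene means).
#' @return list with \code{statistic}, \code{p_value}, \code{n_pairs}
#'   (pairs with nonzero difference) and \code{median_difference} (b - a).
#' @export
paired_wilcoxon <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- b - a
  keep <- is.finite(d) & d != 0
  if (!any(keep)) {
    stop("all paired differences are zero: signed-rank test undefined",
         call. = FALSE)
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a[keep], b[keep], paired = TRUE, exact = FALSE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_pairs = sum(keep), median_difference = stats::median(d[keep]))
}

#' Permutation test for selection on codon nitrogen content
#'
#' Tests whether the nitrogen values of codons carry real signal: the
#' per-codon nitrogen contents are globally shuffled across all sense codons,
#' the model is refitted with the shuffled values, and the maximized
#' log-likelihood is recorded. If selection genuinely acts on nitrogen, the
#' real assignment should fit better than shuffled ones.
#' p = (1 + #\{permuted logLik >= observed\}) / (n_perm + 1).
#'
#' @param counts pooled codon counts (\code{codon_counts} or named vector).
#' @param variant model variant; must include selection on nitrogen.
#' @param n_perm number of permutations (>= 1).
#' @param code a \code{\link{genetic_code}}.
#' @param tai a \code{tai_table} if the variant needs one.
#' @param grid a \code{\link{grid_spec}}.
#' @param seed optional integer seed for the shuffles.
#' @return list with \code{p_value}, \code{observed_loglik},
#'   \code{null_logliks} (length \code{n_perm}) and \code{n_perm}.
#' @export
permutation_test_selection <- function(counts, variant = "selection+mutation",
                                       n_perm = 1000L,
                                       code = genetic_code(1), tai = NULL,
                                       grid = grid_spec(), seed = NULL) {
  if (!("sel_n" %in% free_params(variant))) {
    stop("variant must include selection on nitrogen content", call. = FALSE)
  }
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nitrogen <- nitrogen_mrna(code$sense_codons)
  obs <- fit_codon_model(counts, variant, code, tai, grid)$loglik
  null_ll <- vapply(seq_len(n_perm), function(i) {
    fit_codon_model(counts, variant, code, tai, grid,
                    nitrogen = sample(nitrogen))$loglik
  }, numeric(1))
  list(p_value = (1 + sum(null_ll >= obs)) / (n_perm + 1),
       observed_loglik = obs, null_logliks = null_ll,
       n_perm = as.integer(n_perm))
}

#' Accuracy of model codon-use probabilities against empirical ones
#'
#' Squared Pearson correlation (R^2) across all sense codons of the paired
#' probabilities expressed as percentages. Symmetric in its arguments.
#'
#' @param model,empirical \code{codon_prob_table}s over the same codon set.
#' @return R^2 (numeric scalar).
#' @export
model_accuracy <- function(model, empirical) {
  if (!setequal(names(model), names(empirical))) {
    stop("codon sets of the two probability tables differ", call. = FALSE)
  }
  ord <- names(model)
  stats::cor(100 * as.numeric(model[ord]), 100 * as.numeric(empirical[ord]))^2
}

#' Classify a species into a nitrogen-availability group by likelihood
#'
#' Evaluates the log-likelihood of a species' pooled codon counts under each
#' candidate group's fitted model parameters; the group with the highest
#' likelihood is assigned. Exact ties are flagged rather than silently
#' broken.
#'
#' @param counts the species' codon counts.
#' @param group_fits named list of \code{codon_fit} (or \code{model_params})
#'   per candidate group; at least two.
#' @param code a \code{\link{genetic_code}}.
#' @param tai a \code{tai_table} if any group's variant needs one.
#' @return list with \code{logliks} (named), \code{assigned}, \code{tie}.
#' @export
classify_species <- function(counts, group_fits, code = genetic_code(1),
                             tai = NULL) {
  if (length(group_fits) < 2) {
    stop("need at least two candidate groups", call. = FALSE)
  }
  cnt <- pooled_counts(counts, code)
  if (sum(cnt) == 0) stop("empty codon counts", call. = FALSE)
  ll <- vapply(group_fits, function(gf) {
    p <- if (inherits(gf, "codon_fit")) gf$params else gf
    log_likelihood(p, cnt, code, tai)
  }, numeric(1))
  top <- max(ll)
  winners <- names(ll)[ll == top]
  list(logliks = ll, assigned = winners[1], tie = length(winners) > 1)
}

#' Per-gene selection bias with mutation bias held fixed
#'
#' Fits the selection parameter gene by gene while holding the mutation bias
#' at a supplied genome-wide estimate (mutation is a genome-level process).
#' Genes with fewer sense codons than \code{min_codons} are skipped.
#'
#' @param counts a \code{codon_counts} object (per-gene matrix required).
#' @param mut_m fixed genome-wide mutation bias.
#' @param code a \code{\link{genetic_code}}.
#' @param min_codons minimum sense-codon count per gene (default 100).
#' @param sel_grid candidate selection values.
#' @return data.frame (gene, n_codons, sel_n); skipped genes are reported in
#'   attribute \code{skipped}.
#' @export
per_gene_selection <- function(counts, mut_m, code = genetic_code(1),
                               min_codons = 100L,
                               sel_grid = seq(-1, 1, by = 0.01)) {
  stopifnot(inherits(counts, "codon_counts"))
  pg <- counts$per_gene
  n_cod <- rowSums(pg)
  use <- n_cod >= min_codons
  if (!any(use)) {
    stop("all genes fall below the minimum codon count (", min_codons, ")",
         call. = FALSE)
  }
  g <- grid_spec(sel_n = sel_grid, mut_m = mut_m, zoom = 1L)
  sel <- vapply(which(use), function(i) {
    fit_codon_model(pg[i, ], "selection+mutation", code, grid = g)$params$sel_n
  }, numeric(1))
  out <- data.frame(gene = rownames(pg)[use], n_codons = n_cod[use],
                    sel_n = sel, row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "skipped") <- rownames(pg)[!use]
  out
}

#' Correlation between per-gene selection bias and mRNA abundance
#'
#' Spearman rank correlation plus ordinary least-squares slope of sel_n on
#' log10 abundance, matching genes by id.
#'
#' @param sel data.frame with columns \code{gene} and \code{sel_n}.
#' @param abundance data.frame with columns \code{gene_id} (or \code{gene})
#'   and \code{abundance}, or path to such a TSV.
#' @return list with \code{rho}, \code{p_value}, \code{slope},
#'   \code{n_genes}.
#' @export
expression_correlation <- function(sel, abundance) {
  if (is.character(abundance)) {
    abundance <- utils::read.delim(abundance, stringsAsFactors = FALSE)
  }
  if (!"gene" %in% names(abundance) && "gene_id" %in% names(abundance)) {
    names(abundance)[names(abundance) == "gene_id"] <- "gene"
  }
  m <- merge(sel, abundance, by = "gene")
  m <- m[is.finite(m$sel_n) & is.finite(m$abundance) & m$abundance > 0, ]
  if (nrow(m) < 3) stop("fewer than three matched genes", call. = FALSE)
  if (diff(range(m$abundance)) == 0) {
    stop("abundance is constant: correlation undefined", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(m$sel_n, log10(m$abundance), method = "spearman")
  )
  fit <- stats::lm(sel_n ~ log10(abundance), data = m)
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2]), n_genes = nrow(m))
}

#' Nitrogen savings between two mean per-codon costs
#'
#' Given mean nitrogen per codon in a cheaper (a) and a dearer (b) condition,
#' reports how many codons it takes to save one nitrogen atom
#' (1 / (mean_b - mean_a)) and the percentage saving
#' ((mean_b - mean_a) / mean_b * 100).
#'
#' @param mean_a,mean_b mean nitrogen atoms per codon, \code{mean_b > mean_a}
#'   for a saving.
#' @return list with \code{saving} (logical), \code{codons_per_atom},
#'   \code{percent}.
#' @examples
#' nitrogen_savings_summary(11.00, 11.0667)$codons_per_atom  # ~15
#' @export
nitrogen_savings_summary <- function(mean_a, mean_b) {
  if (mean_b <= mean_a) {
    return(list(saving = FALSE, codons_per_atom = NA_real_,
                percent = NA_real_))
  }
  d <- mean_b - mean_a
  list(saving = TRUE, codons_per_atom = 1 / d, percent = d / mean_b * 100)
}

#' One-way ANOVA across groups of per-species selection estimates
#'
#' Thin summary over per-species fits: tests whether the distribution of
#' fitted selection biases differs between nitrogen-availability groups.
#'
#' @param sel_n numeric vector of per-species selection estimates.
#' @param group factor or character vector of group labels.
#' @return list with \code{f_statistic}, \code{p_value}, \code{df}.
#' @export
anova_selection <- function(sel_n, group) {
  stopifnot(length(sel_n) == length(group))
  av <- stats::aov(sel_n ~ factor(group))
  s <- summary(av)[[1]]
  list(f_statistic = s[["F value"]][1], p_value = s[["Pr(>F)"]][1],
       df = s[["Df"]])
}
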