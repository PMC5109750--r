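#' Model parameters for synonymous codon use
#'
#' The model has up to three composite free parameters: \code{sel_n}, the
#' selection bias 2Ng.s acting per nitrogen atom in a codon's mRNA (negative
#' values favour nitrogen-poor codons); \code{mut_m}, the mutation bias m
#' towards A/T (m > 1 favours AT, m < 1 favours GC); and \code{sel_tai}, the
#' translational selection bias 2Ng.sigma acting per unit of codon
#' adaptiveness (tAI). The \code{variant} names which parameters are free;
#' parameters outside the variant are held at their neutral values
#' (\code{sel_n = 0}, \code{mut_m = 1}, \code{sel_tai = 0}).
#'
#' @param sel_n selection bias on codon nitrogen content (2Ng.s).
#' @param mut_m mutation bias towards AT (m > 0).
#' @param sel_tai translational selection bias (2Ng.sigma).
#' @param variant one of \code{"mutation_only"}, \code{"selection_only"},
#'   \code{"tai_only"}, \code{"selection+mutation"}, \code{"mutation+tai"},
#'   \code{"selection+mutation+tai"}.
#' @return an object of class \code{model_params}.
#' @examples
#' model_params(sel_n = -0.09, mut_m = 0.67, variant = "selection+mutation")
#' @export
model_params <- function(sel_n = 0, mut_m = 1, sel_tai = 0,
                         variant = "selection+mutation") {
  variant <- match.arg(variant, model_variants())
  if (!is.numeric(mut_m) || mut_m <= 0) {
    stop("mutation bias m must be > 0", call. = FALSE)
  }
  free <- free_params(variant)
  if (!("sel_n" %in% free)) sel_n <- 0
  if (!("mut_m" %in% free)) mut_m <- 1
  if (!("sel_tai" %in% free)) sel_tai <- 0
  structure(list(sel_n = sel_n, mut_m = mut_m, sel_tai = sel_tai,
                 variant = variant),
            class = "model_params")
}

#' @rdname model_params
#' @export
model_variants <- function() {
  c("mutation_only", "selection_only", "tai_only",
    "selection+mutation", "mutation+tai", "selection+mutation+tai")
}

#' @rdname model_params
#' @export
free_params <- function(variant) {
  switch(variant,
    "mutation_only" = "mut_m",
    "selection_only" = "sel_n",
    "tai_only" = "sel_tai",
    "selection+mutation" = c("sel_n", "mut_m"),
    "mutation+tai" = c("mut_m", "sel_tai"),
    "selection+mutation+tai" = c("sel_n", "mut_m", "sel_tai"),
    stop("unknown model variant: ", variant, call. = FALSE)
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("Model params [", x$variant, "]: 2Ng.s = ", x$sel_n,
      ", m = ", signif(x$mut_m, 4), ", 2Ng.sigma = ", x$sel_tai, "\n", sep = "")
  invisible(x)
}

#' Selection bias towards a codon from its nitrogen content
#'
#' alpha(C) = exp(sel_n * N_mRNA(C)), where N_mRNA is the codon's
#' single-stranded nitrogen atom count.
#'
#' @param codons character vector of codons.
#' @param sel_n selection bias 2Ng.s.
#' @return positive numeric vector of selection weights.
#' @examples
#' selection_bias("TGC", -0.1)  # exp(-1)
#' @export
selection_bias <- function(codons, sel_n) {
  exp(sel_n * nitrogen_mrna(codons))
}

#' Equilibrium A/T probability from mutation bias
#'
#' delta = m / (m + 1): the probability a site is A or T at compositional
#' equilibrium under mutation bias m towards AT.
#'
#' @param mut_m mutation bias m (> 0).
#' @return delta in (0, 1), strictly increasing in m.
#' @examples
#' mutation_delta(3)  # 0.75
#' @export
mutation_delta <- function(mut_m) {
  if (any(!is.finite(mut_m)) || any(mut_m <= 0)) {
    stop("mutation bias m must be > 0", call. = FALSE)
  }
  mut_m / (mut_m + 1)
}

#' Mutation bias towards a codon
#'
#' beta(C) = delta^AT * (1 - delta)^GC, with AT and GC the number of A/T and
#' G/C nucleotides in the codon and delta = m/(m+1).
#'
#' @param codons character vector of codons.
#' @param mut_m mutation bias m (> 0).
#' @return positive numeric vector of mutation weights.
#' @examples
#' mutation_bias(c("TGC", "TGT"), 3)  # 0.046875 0.140625
#' @export
mutation_bias <- function(codons, mut_m) {
  delta <- mutation_delta(mut_m)
  codons <- normalize_codons(codons)
  check_codons(codons)
  at <- at_count(codons)
  delta^at * (1 - delta)^(3L - at)
}

#' tRNA adaptation weights per codon
#'
#' Computes the absolute adaptiveness omega(C) of each sense codon as the sum
#' over recognizing tRNA isoacceptors of (1 - s_ij) * tGCN_ij, where tGCN_ij
#' is the genomic copy number of the j-th recognizing tRNA and s_ij the
#' selective constraint of the codon-anticodon coupling class. Recognition
#' follows standard wobble rules between the codon third base and the
#' anticodon 34 position; the default coupling constants are the widely used
#' optimized values (Watson-Crick pairs 0; G:U 0.41, I:C 0.28, I:A 0.9999,
#' U:G 0.68) shipped as an editable TSV in \code{extdata/wobble_s.tsv}.
#'
#' @param tgcn data.frame with columns \code{anticodon} (DNA alphabet,
#'   5'->3') and \code{count} (non-negative integer gene copy numbers), or
#'   path to such a TSV.
#' @param sij data.frame with columns \code{codon3}, \code{anticodon34},
#'   \code{s} (each s in [0,1]), or path to a TSV; \code{NULL} loads the
#'   shipped defaults.
#' @param code a \code{\link{genetic_code}}.
#' @return a \code{tai_table}: named numeric vector of omega over sense
#'   codons, with attribute \code{unrecognized} naming codons with omega 0.
#' @export
tai_omega <- function(tgcn, sij = NULL, code = genetic_code(1)) {
  if (is.character(tgcn)) tgcn <- utils::read.delim(tgcn, stringsAsFactors = FALSE)
  if (is.null(sij)) {
    sij <- system.file("extdata", "wobble_s.tsv", package = "codonN")
  }
  if (is.character(sij)) sij <- utils::read.delim(sij, stringsAsFactors = FALSE)
  stopifnot(all(c("anticodon", "count") %in% names(tgcn)),
            all(c("codon3", "anticodon34", "s") %in% names(sij)))
  if (any(tgcn$count < 0)) stop("negative tRNA gene copy number", call. = FALSE)
  if (any(sij$s < 0 | sij$s > 1)) stop("s_ij must lie in [0, 1]", call. = FALSE)
  anticodons <- normalize_codons(tgcn$anticodon)
  check_codons(anticodons)
  copy <- stats::setNames(tgcn$count, anticodons)

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  sense <- code$sense_codons
  omega <- stats::setNames(numeric(length(sense)), sense)
  for (ci in sense) {
    nt <- strsplit(ci, "", fixed = TRUE)[[1]]
    rules <- sij[sij$codon3 == nt[3], , drop = FALSE]
    for (j in seq_len(nrow(rules))) {
      # anticodon 5'->3': position 34 pairs the codon third base
      anti <- paste0(rules$anticodon34[j], comp[nt[2]], comp[nt[1]])
      if (anti %in% names(copy)) {
        omega[ci] <- omega[ci] + (1 - rules$s[j]) * copy[[anti]]
      }
    }
  }
  unrec <- names(omega)[omega == 0]
  if (length(unrec) > 0) {
    warning("codons recognized by no tRNA (omega = 0): ",
            paste(unrec, collapse = ", "), call. = FALSE)
  }
  structure(omega, unrecognized = unrec, class = "tai_table")
}

needs_tai <- function(variant) grepl("tai", variant, fixed = TRUE)

# omega vector aligned to sense codons (zeros when tai not in variant)
omega_vector <- function(params_or_variant, tai, code) {
  variant <- if (inherits(params_or_variant, "model_params")) {
    params_or_variant$variant
  } else {
    params_or_variant
  }
  if (!needs_tai(variant)) {
    return(stats::setNames(numeric(length(code$sense_codons)),
                           code$sense_codons))
  }
  if (is.null(tai)) {
    stop("variant '", variant, "' requires a tai_table (see tai_omega())",
         call. = FALSE)
  }
  w <- unclass(tai)[code$sense_codons]
  if (anyNA(w)) stop("tai_table missing codons of the active code", call. = FALSE)
  stats::setNames(w, code$sense_codons)
}

#' Codon-use probabilities under the selection-mutation-translation model
#'
#' For each synonymous family the probability of codon C is its model weight
#' divided by the family's total weight, where the weight is the product of
#' the variant's active biases: selection alpha(C) = exp(sel_n * N_mRNA),
#' mutation beta(C) = delta^AT (1-delta)^GC, and translational selection
#' eta(C) = exp(sel_tai * omega(C)). Probabilities sum to one within every
#' family.
#'
#' @param params a \code{\link{model_params}}.
#' @param code a \code{\link{genetic_code}}.
#' @param tai a \code{tai_table} (required iff the variant includes
#'   translational selection).
#' @param nitrogen optional numeric vector overriding the per-codon nitrogen
#'   values (aligned to \code{code$sense_codons}); used by the permutation
#'   test, which shuffles nitrogen values across codons.
#' @return a \code{codon_prob_table} over the code's sense codons.
#' @examples
#' code <- genetic_code(1)
#' p <- codon_probs(model_params(mut_m = 3, variant = "mutation_only"), code)
#' p[c("TGC", "TGT")]  # 0.25 0.75
#' @export
codon_probs <- function(params, code = genetic_code(1), tai = NULL,
                        nitrogen = NULL) {
  stopifnot(inherits(params, "model_params"), is_genetic_code(code))
  sense <- code$sense_codons
  if (is.null(nitrogen)) nitrogen <- nitrogen_mrna(sense)
  alpha <- exp(params$sel_n * nitrogen)
  beta <- mutation_bias(sense, params$mut_m)
  w <- omega_vector(params, tai, code)
  eta <- exp(params$sel_tai * w)
  weight <- stats::setNames(alpha * beta * eta, sense)
  probs <- weight
  for (fam in code$families) {
    probs[fam] <- weight[fam] / sum(weight[fam])
  }
  new_codon_prob_table(probs, code)
}

#' Log-likelihood of codon counts under the model
#'
#' log L = sum over sense codons of N_C * ln p(C | theta). Families with a
#' single codon contribute zero. A codon observed with probability zero
#' yields -Inf with a warning.
#'
#' @param params a \code{\link{model_params}}.
#' @param counts a \code{codon_counts} object or named numeric vector of
#'   pooled counts.
#' @inheritParams codon_probs
#' @return the log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(params, counts, code = genetic_code(1), tai = NULL,
                           nitrogen = NULL) {
  cnt <- pooled_counts(counts, code)
  p <- codon_probs(params, code, tai, nitrogen)
  pos <- cnt > 0
  if (any(pos & p == 0)) {
    warning("codon with positive count has model probability zero; ",
            "log-likelihood is -Inf", call. = FALSE)
    return(-Inf)
  }
  sum(cnt[pos] * log(p[pos]))
}
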