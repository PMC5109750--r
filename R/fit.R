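#' Grid specification for the brute-force likelihood search
#'
#' Default search ranges bracket every parameter value the model is expected
#' to produce on real microbial data with a wide margin: sel_n in [-1, 1] at
#' step 0.01, m on a logarithmic grid of 200 points over [0.05, 20], sel_tai
#' in [-1, 1] at step 0.01. One zoom pass re-searches a +/- one-coarse-step
#' window around the coarse optimum at 10x resolution.
#'
#' @param sel_n numeric vector of candidate selection biases.
#' @param mut_m numeric vector of candidate mutation biases (positive).
#' @param sel_tai numeric vector of candidate translational selection biases.
#' @param zoom number of refinement passes (each at 10x local resolution).
#' @return a \code{grid_spec} list.
#' @export
grid_spec <- function(sel_n = seq(-1, 1, by = 0.01),
                      mut_m = exp(seq(log(0.05), log(20), length.out = 200)),
                      sel_tai = seq(-1, 1, by = 0.01),
                      zoom = 1L) {
  stopifnot(all(mut_m > 0), zoom >= 0)
  structure(list(sel_n = sel_n, mut_m = mut_m, sel_tai = sel_tai,
                 zoom = as.integer(zoom)),
            class = "grid_spec")
}

# Evaluate the log-likelihood over a Cartesian grid of (sel_n, m, sel_tai)
# and return the argmax. Weights are exp(s*N + u*AT + t*W) with u = log(m):
# the (1-delta)^3 factor common to all codons of a family cancels in the
# within-family normalization, so this parameterization gives exactly the
# same probabilities as codon_probs(). Family log-partition sums are batched
# as matrix cross-products so a full 201 x 200 coarse grid costs a handful
# of BLAS calls.
eval_grid <- function(cnt, nitrogen, at, w, fams, s_vec, m_vec, t_vec) {
  u_vec <- log(m_vec)
  ns <- length(s_vec); nu <- length(u_vec); nt <- length(t_vec)
  fam_tot <- vapply(fams, function(i) sum(cnt[i]), numeric(1))
  # linear term: s*sum(cnt*N) + u*sum(cnt*AT) + t*sum(cnt*W)
  Sn <- sum(cnt * nitrogen); Sat <- sum(cnt * at); Sw <- sum(cnt * w)

  sum_logz <- array(0, dim = c(ns, nu, nt))
  if (nt == 1L) {
    for (k in seq_along(fams)) {
      idx <- fams[[k]]
      if (fam_tot[k] == 0) next
      A <- exp(outer(nitrogen[idx], s_vec) + t_vec * w[idx])
      B <- exp(outer(at[idx], u_vec))
      sum_logz[, , 1L] <- sum_logz[, , 1L] + fam_tot[k] * log(crossprod(A, B))
    }
  } else if (nu == 1L) {
    for (k in seq_along(fams)) {
      idx <- fams[[k]]
      if (fam_tot[k] == 0) next
      A <- exp(outer(nitrogen[idx], s_vec) + u_vec * at[idx])
      B <- exp(outer(w[idx], t_vec))
      sum_logz[, 1L, ] <- sum_logz[, 1L, ] + fam_tot[k] * log(crossprod(A, B))
    }
  } else {
    for (iu in seq_len(nu)) {
      acc <- matrix(0, ns, nt)
      for (k in seq_along(fams)) {
        idx <- fams[[k]]
        if (fam_tot[k] == 0) next
        A <- exp(outer(nitrogen[idx], s_vec) + u_vec[iu] * at[idx])
        B <- exp(outer(w[idx], t_vec))
        acc <- acc + fam_tot[k] * log(crossprod(A, B))
      }
      sum_logz[, iu, ] <- acc
    }
  }
  lin <- outer(s_vec * Sn, u_vec * Sat, "+")
  ll <- array(rep(lin, nt), dim = c(ns, nu, nt)) +
    array(rep(t_vec * Sw, each = ns * nu), dim = c(ns, nu, nt)) - sum_logz

  # argmax with ties broken toward the neutral parameter vector
  mx <- max(ll)
  cand <- which(ll >= mx - 1e-9, arr.ind = TRUE)
  d <- s_vec[cand[, 1]]^2 + u_vec[cand[, 2]]^2 + t_vec[cand[, 3]]^2
  pick <- cand[which.min(d), ]
  list(sel_n = s_vec[pick[1]], mut_m = m_vec[pick[2]], sel_tai = t_vec[pick[3]],
       loglik = ll[pick[1], pick[2], pick[3]])
}

# Refined grid around a coarse optimum: +/- one local step at 10x resolution,
# clipped to the original range. Log-spaced parameters refine in log space.
refine_grid <- function(grid_vec, best, log_space = FALSE) {
  if (length(grid_vec) < 2L) return(grid_vec)
  g <- if (log_space) log(grid_vec) else grid_vec
  b <- if (log_space) log(best) else best
  i <- which.min(abs(g - b))
  step <- if (i < length(g)) g[i + 1L] - g[i] else g[i] - g[i - 1L]
  lo <- max(min(g), b - step)
  hi <- min(max(g), b + step)
  out <- seq(lo, hi, length.out = 21L)
  if (log_space) exp(out) else out
}

#' Fit the selection-mutation-translation model by maximum likelihood
#'
#' Brute-force search of the log-likelihood over a parameter grid, followed
#' by zoom passes at 10x local resolution around the coarse optimum. Ties on
#' the grid are broken toward the neutral parameter vector (smallest |sel_n|,
#' m closest to 1, smallest |sel_tai|), which is conservative with respect to
#' claiming selection. The fit depends on the data only through the pooled
#' codon counts.
#'
#' @param counts a \code{codon_counts} object or named numeric vector of
#'   pooled counts over sense codons.
#' @param variant model variant (see \code{\link{model_params}}).
#' @param code a \code{\link{genetic_code}}.
#' @param tai a \code{tai_table}; required iff the variant includes
#'   translational selection.
#' @param grid a \code{\link{grid_spec}}.
#' @param nitrogen optional per-codon nitrogen override (permutation test).
#' @return a \code{codon_fit}: list with \code{params}, \code{loglik},
#'   \code{aic}, \code{probs} (fitted codon-probability table), and
#'   \code{grid_meta} (search ranges, resolutions, zoom passes).
#' @examples
#' code <- genetic_code(1)
#' p <- codon_probs(model_params(mut_m = 3, variant = "mutation_only"), code)
#' fit <- fit_codon_model(round(1e5 * p), "mutation_only", code)
#' fit$params$mut_m  # close to 3
#' @export
fit_codon_model <- function(counts, variant = "selection+mutation",
                            code = genetic_code(1), tai = NULL,
                            grid = grid_spec(), nitrogen = NULL) {
  variant <- match.arg(variant, model_variants())
  cnt <- pooled_counts(counts, code)
  sense <- code$sense_codons
  if (is.null(nitrogen)) nitrogen <- nitrogen_mrna(sense)
  at <- at_count(sense)
  w <- as.numeric(omega_vector(variant, tai, code))
  fams <- lapply(code$families, function(f) match(f, sense))
  multi <- vapply(fams, length, integer(1)) > 1L
  if (sum(cnt[unlist(fams[multi])]) == 0) {
    stop("degenerate counts: no observations in any multi-codon family",
         call. = FALSE)
  }

  free <- free_params(variant)
  s_vec <- if ("sel_n" %in% free) grid$sel_n else 0
  m_vec <- if ("mut_m" %in% free) grid$mut_m else 1
  t_vec <- if ("sel_tai" %in% free) grid$sel_tai else 0

  best <- eval_grid(cnt, nitrogen, at, w, fams, s_vec, m_vec, t_vec)
  passes <- 0L
  rs <- s_vec; rm <- m_vec; rt <- t_vec
  while (passes < grid$zoom) {
    if ("sel_n" %in% free) rs <- refine_grid(rs, best$sel_n)
    if ("mut_m" %in% free) rm <- refine_grid(rm, best$mut_m, log_space = TRUE)
    if ("sel_tai" %in% free) rt <- refine_grid(rt, best$sel_tai)
    best <- eval_grid(cnt, nitrogen, at, w, fams, rs, rm, rt)
    passes <- passes + 1L
  }

  params <- model_params(sel_n = best$sel_n, mut_m = best$mut_m,
                         sel_tai = best$sel_tai, variant = variant)
  k <- length(free)
  probs <- codon_probs(params, code, tai, nitrogen)
  fit <- structure(
    list(
      params = params,
      loglik = best$loglik,
      aic = 2 * k - 2 * best$loglik,
      probs = probs,
      grid_meta = list(
        variant = variant, free = free,
        coarse = list(sel_n = range(s_vec), n_sel = length(s_vec),
                      mut_m = range(m_vec), n_m = length(m_vec),
                      sel_tai = range(t_vec), n_tai = length(t_vec)),
        zoom_passes = passes,
        refined_step = list(
          sel_n = if (length(rs) > 1) diff(rs[1:2]) else NA_real_,
          log_mut_m = if (length(rm) > 1) diff(log(rm[1:2])) else NA_real_,
          sel_tai = if (length(rt) > 1) diff(rt[1:2]) else NA_real_
        )
      )
    ),
    class = "codon_fit"
  )
  fit
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("Selection-mutation model fit [", x$params$variant, "]\n", sep = "")
  cat("  2Ng.s = ", x$params$sel_n, ", m = ", signif(x$params$mut_m, 4),
      ", 2Ng.sigma = ", x$params$sel_tai, "\n", sep = "")
  cat("  logLik = ", x$loglik, ", AIC = ", x$aic, "\n", sep = "")
  invisible(x)
}

#' Akaike information criterion of a model fit
#'
#' AIC = 2k - 2 logLik, with k the number of free parameters in the fitted
#' variant.
#'
#' @param fit a \code{codon_fit}.
#' @return the AIC (numeric scalar).
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "codon_fit"), is.finite(fit$loglik))
  2 * length(free_params(fit$params$variant)) - 2 * fit$loglik
}

#' Serialize a model fit to JSON (and optionally its probabilities to TSV)
#'
#' @param fit a \code{codon_fit}.
#' @param json_path output JSON path.
#' @param probs_path optional TSV path for the fitted codon-probability table.
#' @return invisibly, the list written to JSON.
#' @export
write_fit <- function(fit, json_path, probs_path = NULL) {
  stopifnot(inherits(fit, "codon_fit"))
  out <- list(
    params = fit$params[c("sel_n", "mut_m", "sel_tai", "variant")],
    loglik = fit$loglik, aic = fit$aic, grid_meta = fit$grid_meta
  )
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(probs_path)) {
    utils::write.table(
      data.frame(codon = names(fit$probs), prob = as.numeric(fit$probs)),
      probs_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}
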