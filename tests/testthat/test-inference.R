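code <- genetic_code(1)

test_that("paired signed-rank test detects shifts and rejects degenerate input", {
  expect_error(paired_wilcoxon(c(1, 2, 3), c(1, 2, 3)), "all paired differences")

  set.seed(8)
  a <- rnorm(1000, 11, 0.2)
  b <- a + 0.07 + rnorm(1000, 0, 0.01)
  res <- paired_wilcoxon(a, b)
  expect_lt(res$p_value, 0.001)
  expect_gt(res$median_difference, 0)

  # null calibration: symmetric zero-mean noise gives uniform p-values
  ps <- vapply(1:100, function(seed) {
    set.seed(seed)
    x <- rnorm(100, 11, 0.2)
    paired_wilcoxon(x, x + rnorm(100, 0, 0.05))$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("permutation p-values obey the Monte-Carlo formula and bounds", {
  set.seed(2)
  p <- codon_probs(model_params(sel_n = -0.24, mut_m = 3.5), code)
  cnt <- sim_pooled_counts(p, 2e4, code)
  r1 <- permutation_test_selection(cnt, "selection+mutation", n_perm = 1,
                                   code = code, seed = 1)
  expect_true(r1$p_value %in% c(0.5, 1.0))
  r19 <- permutation_test_selection(cnt, "selection+mutation", n_perm = 19,
                                    code = code, seed = 1)
  expect_gt(r19$p_value, 0)
  expect_lte(r19$p_value, 1)
  expect_lte(r19$p_value, 0.05)  # strong selection beats every shuffle
  expect_length(r19$null_logliks, 19)

  expect_error(permutation_test_selection(cnt, "mutation_only", n_perm = 5,
                                          code = code),
               "selection")
  expect_error(permutation_test_selection(cnt, "selection+mutation",
                                          n_perm = 0, code = code),
               "n_perm")
})

test_that("model accuracy is an R-squared over paired percentages", {
  p <- codon_probs(model_params(sel_n = -0.1, mut_m = 2), code)
  expect_equal(model_accuracy(p, p), 1.0)

  set.seed(6)
  emp <- empirical_probs(sim_pooled_counts(p, 1e6, code), code)
  r2_self <- model_accuracy(p, emp)
  expect_gt(r2_self, 0.99)
  expect_equal(model_accuracy(p, emp), model_accuracy(emp, p))

  # a family-uniform table explains strongly biased data worse than the model
  uniform <- codon_probs(model_params(variant = "selection+mutation"), code)
  expect_lt(model_accuracy(uniform, emp), r2_self)

  expect_error(model_accuracy(p, p[-1]), "codon sets")
})

test_that("likelihood classification assigns the generating group", {
  groups <- list(
    L_N = model_params(sel_n = -0.24, mut_m = 3.5),
    M_N = model_params(sel_n = -0.15, mut_m = 3.5),
    H_N = model_params(sel_n = -0.13, mut_m = 3.5)
  )
  set.seed(14)
  cnt <- sim_pooled_counts(codon_probs(groups$H_N, code), 1e6, code)
  res <- classify_species(cnt, groups, code)
  expect_equal(res$assigned, "H_N")
  expect_false(res$tie)
  expect_equal(names(which.max(res$logliks)), "H_N")

  # identical candidate models are an exact tie, flagged not broken
  tie <- classify_species(cnt, list(A = groups$L_N, B = groups$L_N), code)
  expect_true(tie$tie)

  expect_error(classify_species(setNames(numeric(61), code$sense_codons),
                                groups, code),
               "empty")
  expect_error(classify_species(cnt, groups["L_N"], code), "two candidate")
})

test_that("per-gene selection recovers gene-level parameters with m fixed", {
  set.seed(21)
  p_strong <- codon_probs(model_params(sel_n = -0.3, mut_m = 2), code)
  genes <- list(
    strong = sim_pooled_counts(p_strong, 5000, code),
    tiny = sim_pooled_counts(p_strong, 10, code)
  )
  # neutral gene: usage exactly at sel_n = 0 under the fixed mutation bias
  genes$neutral <- expected_counts(
    codon_probs(model_params(sel_n = 0, mut_m = 2), code), 5000, code)
  pg <- do.call(rbind, genes)
  cc <- structure(list(per_gene = pg, pooled = colSums(pg),
                       n_genes = nrow(pg), code = code),
                  class = "codon_counts")
  res <- per_gene_selection(cc, mut_m = 2, code = code, min_codons = 100)
  expect_setequal(res$gene, c("strong", "neutral"))
  expect_equal(attr(res, "skipped"), "tiny")
  expect_lt(abs(res$sel_n[res$gene == "strong"] + 0.3), 0.05)
  expect_lt(abs(res$sel_n[res$gene == "neutral"]), 0.01)
  expect_error(per_gene_selection(cc, mut_m = 2, code = code,
                                  min_codons = 1e6),
               "below the minimum")
})

test_that("expression correlation detects selection-abundance coupling", {
  set.seed(33)
  n_genes <- 60
  log_ab <- seq(0, 4, length.out = n_genes)
  true_sel <- -0.05 - 0.06 * log_ab
  pg <- t(vapply(true_sel, function(s) {
    sim_pooled_counts(codon_probs(model_params(sel_n = s, mut_m = 2), code),
                      3000, code)
  }, setNames(numeric(61), code$sense_codons)))
  rownames(pg) <- paste0("g", seq_len(n_genes))
  cc <- structure(list(per_gene = pg, pooled = colSums(pg),
                       n_genes = n_genes, code = code),
                  class = "codon_counts")
  sel <- per_gene_selection(cc, mut_m = 2, code = code, min_codons = 100)
  ab <- data.frame(gene = rownames(pg), abundance = 10^log_ab)
  res <- expression_correlation(sel, ab)
  expect_lt(res$rho, 0)
  expect_lt(res$p_value, 0.01)
  expect_lt(res$slope, 0)

  # shuffled abundances carry no signal on average
  rhos <- vapply(1:100, function(seed) {
    set.seed(seed)
    ab2 <- data.frame(gene = ab$gene, abundance = sample(ab$abundance))
    expression_correlation(sel, ab2)$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)

  expect_error(expression_correlation(sel[1:2, ], ab), "three matched")
  expect_error(expression_correlation(
    sel, data.frame(gene = ab$gene, abundance = 1)), "constant")
})

test_that("nitrogen savings summaries invert mean differences", {
  s <- nitrogen_savings_summary(11.00, 11.0667)
  expect_true(s$saving)
  expect_equal(s$codons_per_atom, 15.0, tolerance = 1e-3)
  expect_equal(s$percent, 0.0667 / 11.0667 * 100, tolerance = 1e-6)

  expect_false(nitrogen_savings_summary(11, 11)$saving)
  expect_equal(nitrogen_savings_summary(23.0, 23.25)$codons_per_atom, 4.0)
})

test_that("group ANOVA over per-species selection estimates detects shifts", {
  set.seed(12)
  sel <- c(rnorm(5, -0.24, 0.01), rnorm(5, -0.15, 0.01), rnorm(5, -0.13, 0.01))
  grp <- rep(c("L_N", "M_N", "H_N"), each = 5)
  res <- anova_selection(sel, grp)
  expect_lt(res$p_value, 0.01)
  null <- anova_selection(rnorm(15, -0.2, 0.01), grp)
  expect_gt(null$p_value, 0.001)
})
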