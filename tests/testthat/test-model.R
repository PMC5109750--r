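code <- genetic_code(1)

test_that("selection and mutation weights match their closed forms", {
  expect_equal(selection_bias("TGC", 0), 1.0)
  expect_equal(selection_bias("TGC", -0.1), exp(-1.0))
  expect_equal(selection_bias("TGT", -0.1), exp(-0.9))

  expect_equal(mutation_delta(3), 0.75)
  expect_equal(mutation_delta(1), 0.5)
  expect_equal(mutation_delta(0.25), 0.2)
  expect_error(mutation_delta(0), "m must be > 0")

  expect_equal(mutation_bias("TGC", 3), 0.75^1 * 0.25^2)
  expect_equal(mutation_bias("TGT", 3), 0.75^2 * 0.25^1)
  expect_equal(unname(mutation_bias(c("AAA", "GGG", "ATG"), 1)), rep(0.125, 3))
})

test_that("codon probabilities normalize within families for every variant", {
  tai <- structure(setNames(rep(1.5, 61), code$sense_codons),
                   class = "tai_table")
  set.seed(11)
  for (variant in model_variants()) {
    for (rep in 1:5) {
      p <- codon_probs(
        model_params(sel_n = runif(1, -1, 1), mut_m = exp(runif(1, -3, 3)),
                     sel_tai = runif(1, -1, 1), variant = variant),
        code, tai = tai)
      fam_sums <- vapply(code$families, function(f) sum(p[f]), numeric(1))
      expect_true(all(abs(fam_sums - 1) <= 1e-12))
    }
  }
})

test_that("mutation-only and selection-only probabilities match hand calculations", {
  p_mut <- codon_probs(model_params(mut_m = 3, variant = "mutation_only"), code)
  expect_equal(unclass(p_mut[c("TGC", "TGT")]), c(TGC = 0.25, TGT = 0.75))

  p_sel <- codon_probs(model_params(sel_n = -0.1, variant = "selection_only"), code)
  expect_equal(unname(p_sel["TGC"]), 1 / (1 + exp(0.1)))

  p_neutral <- codon_probs(model_params(variant = "selection+mutation"), code)
  fam_sizes <- lengths(code$families)[code$aa_of]
  expect_equal(as.numeric(p_neutral), unname(1 / fam_sizes))
})

test_that("variant limits coincide: joint model collapses to its margins", {
  m <- 2.3
  p_joint <- codon_probs(model_params(sel_n = 0, mut_m = m), code)
  p_mut <- codon_probs(model_params(mut_m = m, variant = "mutation_only"), code)
  expect_equal(unclass(p_joint), unclass(p_mut))

  s <- -0.21
  p_joint2 <- codon_probs(model_params(sel_n = s, mut_m = 1), code)
  p_sel <- codon_probs(model_params(sel_n = s, variant = "selection_only"), code)
  expect_equal(unclass(p_joint2), unclass(p_sel))
})

test_that("increasing m raises the probability of the most AT-rich codon", {
  fams <- Filter(function(f) length(f) > 1 &&
                   length(unique(nchar(gsub("[GC]", "", f)))) > 1,
                 code$families)
  for (fam in fams) {
    at <- nchar(gsub("[GC]", "", fam))
    rich <- fam[which.max(at)]
    ms <- c(0.5, 1, 2, 4, 8)
    ps <- vapply(ms, function(m) {
      codon_probs(model_params(mut_m = m, variant = "mutation_only"), code)[[rich]]
    }, numeric(1))
    expect_true(all(diff(ps) > 0))
  }
})

test_that("log-likelihood matches hand computation and pools across genes", {
  ll <- log_likelihood(model_params(mut_m = 3, variant = "mutation_only"),
                       c(TGC = 2, TGT = 3), code)
  expect_equal(ll, 2 * log(0.25) + 3 * log(0.75), tolerance = 1e-12)

  zero <- setNames(numeric(61), code$sense_codons)
  expect_equal(log_likelihood(model_params(mut_m = 3, variant = "mutation_only"),
                              zero, code), 0)
  expect_equal(log_likelihood(model_params(mut_m = 3, variant = "mutation_only"),
                              c(ATG = 100), code), 0)

  # depends on counts only through the pooled totals
  params <- model_params(sel_n = -0.1, mut_m = 0.8)
  split_a <- c(TGC = 5, TGT = 2, GCA = 9, GCG = 1)
  split_b <- c(TGC = 1, TGT = 6, GCA = 3, GCG = 4)
  pooled <- c(TGC = 6, TGT = 8, GCA = 12, GCG = 5)
  expect_equal(log_likelihood(params, split_a, code) +
                 log_likelihood(params, split_b, code),
               log_likelihood(params, pooled, code))
})

test_that("ML fit matches the closed-form estimate for a two-codon family", {
  # mutation-only on the Cys family: p(TGT) = delta, so m.hat = N_TGT/N_TGC
  f <- fit_codon_model(c(TGC = 250, TGT = 750), "mutation_only", code)
  expect_equal(f$params$mut_m, 3, tolerance = 0.004)
  # selection-only: p(TGC)/p(TGT) = e^{s}, so s.hat = log(N_TGC/N_TGT)
  f2 <- fit_codon_model(c(TGC = 400, TGT = 600), "selection_only", code)
  expect_lt(abs(f2$params$sel_n - log(400 / 600)), 0.0011)
})

test_that("fit recovers exact-proportional counts to grid precision", {
  truth <- model_params(sel_n = -0.09, mut_m = 0.67)
  cnt <- expected_counts(codon_probs(truth, code), 1e6, code)
  f <- fit_codon_model(cnt, "selection+mutation", code)
  expect_equal(f$params$sel_n, -0.09, tolerance = 0.001)
  expect_equal(log(f$params$mut_m), log(0.67),
               tolerance = f$grid_meta$refined_step$log_mut_m)
  expect_equal(f$loglik, log_likelihood(f$params, cnt, code), tolerance = 1e-8)
})

test_that("neutral data fit lands at the neutral parameter vector", {
  cnt <- expected_counts(
    codon_probs(model_params(variant = "selection+mutation"), code), 1e4, code)
  f <- fit_codon_model(cnt, "selection+mutation", code)
  expect_equal(f$params$sel_n, 0, tolerance = 1e-9)
  expect_equal(f$params$mut_m, 1, tolerance = 1e-6)
})

test_that("parameter recovery error stays within the search resolution", {
  # truths spanning weak to strong selection and GC- to AT-biased mutation
  set.seed(20)
  errs_s <- c(); errs_logm <- c()
  for (s in c(-0.3, -0.1, 0)) {
    for (m in c(0.5, 1, 4)) {
      p <- codon_probs(model_params(sel_n = s, mut_m = m), code)
      f <- fit_codon_model(sim_pooled_counts(p, 1e5, code),
                           "selection+mutation", code)
      errs_s <- c(errs_s, f$params$sel_n - s)
      errs_logm <- c(errs_logm, log(f$params$mut_m / m))
    }
  }
  expect_lt(mean(abs(errs_s)), 2 * 0.001)
  expect_lt(mean(abs(errs_logm)), 2 * 0.00302)
})

test_that("fit rejects degenerate counts", {
  expect_error(fit_codon_model(c(ATG = 50, TGG = 10), "selection+mutation", code),
               "degenerate")
})

test_that("AIC follows 2k - 2 logLik and prefers the generating model class", {
  f <- fit_codon_model(c(TGC = 250, TGT = 750), "mutation_only", code)
  expect_equal(f$aic, 2 * 1 - 2 * f$loglik)
  expect_equal(aic(f), f$aic)

  set.seed(5)
  truth <- codon_probs(model_params(sel_n = -0.3, mut_m = 1.0), code)
  cnt <- sim_pooled_counts(truth, 1e5, code)
  aic_joint <- fit_codon_model(cnt, "selection+mutation", code)$aic
  aic_mut <- fit_codon_model(cnt, "mutation_only", code)$aic
  expect_lt(aic_joint, aic_mut)
})

test_that("tAI weights sum discounted copy numbers over recognizing tRNAs", {
  # single Watson-Crick isoacceptor with s = 0.5 and two gene copies
  suppressWarnings({
    t1 <- tai_omega(data.frame(anticodon = "GCA", count = 2),
                    data.frame(codon3 = "C", anticodon34 = "G", s = 0.5),
                    code)
  })
  expect_equal(unname(unclass(t1)["TGC"]), 1.0)

  # Watson-Crick (s = 0) plus an inosine wobble isoacceptor (s = 0.28)
  suppressWarnings({
    t2 <- tai_omega(data.frame(anticodon = c("GCA", "ACA"), count = c(1, 1)),
                    data.frame(codon3 = c("C", "C"), anticodon34 = c("G", "A"),
                               s = c(0, 0.28)),
                    code)
  })
  expect_equal(unname(unclass(t2)["TGC"]), 1.72)
  # codons with no recognizing tRNA are flagged with omega zero
  expect_true("AAA" %in% attr(t2, "unrecognized"))
  expect_equal(unname(unclass(t2)["AAA"]), 0)

  expect_error(tai_omega(data.frame(anticodon = "GCA", count = -1),
                         code = code),
               "negative")
})

test_that("tai variants require a tai table and fit translational selection", {
  expect_error(codon_probs(model_params(sel_tai = 0.5, variant = "tai_only"),
                           code),
               "requires a tai_table")
  # synthetic adaptiveness: recover a known translational selection bias
  set.seed(3)
  w <- setNames(round(runif(61, 0, 3), 2), code$sense_codons)
  tai <- structure(w, class = "tai_table")
  truth <- model_params(sel_tai = 0.4, variant = "tai_only")
  cnt <- expected_counts(codon_probs(truth, code, tai), 1e5, code)
  f <- fit_codon_model(cnt, "tai_only", code, tai = tai)
  expect_equal(f$params$sel_tai, 0.4, tolerance = 0.001)
})
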