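# Shared simulation helpers for the test suite. Counts are drawn directly at
# the codon level: residues multinomial over amino-acid frequencies, then
# codons multinomial within each synonymous family. This is distributionally
# identical to simulating sequences codon by codon, and the likelihood
# depends on the data only through pooled counts.

sim_pooled_counts <- function(probs, n_codons, code, aa_freq = NULL) {
  if (is.null(aa_freq)) {
    aas <- names(code$families)
    aa_freq <- stats::setNames(rep(1 / length(aas), length(aas)), aas)
  }
  cnt <- stats::setNames(numeric(length(probs)), names(probs))
  n_aa <- drop(stats::rmultinom(1, n_codons, aa_freq))
  for (i in seq_along(aa_freq)) {
    fam <- code$families[[names(aa_freq)[i]]]
    if (length(fam) == 1L) {
      cnt[fam] <- n_aa[i]
    } else {
      cnt[fam] <- drop(stats::rmultinom(1, n_aa[i], probs[fam]))
    }
  }
  cnt
}

# noiseless expected counts: probabilities scaled by uniform amino-acid
# weights to a total codon budget
expected_counts <- function(probs, n_codons, code) {
  aas <- names(code$families)
  aa_freq <- stats::setNames(rep(1 / length(aas), length(aas)), aas)
  cnt <- as.numeric(probs) * aa_freq[code$aa_of[names(probs)]] * n_codons
  stats::setNames(cnt, names(probs))
}

random_protein <- function(n, code) {
  paste(sample(names(code$families), n, replace = TRUE), collapse = "")
}
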