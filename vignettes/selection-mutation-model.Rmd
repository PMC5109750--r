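---
title: "A selection-mutation model of synonymous codon use and nitrogen cost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A selection-mutation model of synonymous codon use and nitrogen cost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Nucleotides differ in how many nitrogen atoms they contain: the purines A and
G carry five, cytosine three, thymine/uracil two. Because the genetic code is
redundant, an organism can encode the same protein with codons of different
nitrogen cost — `TGT` (9 atoms in mRNA) and `TGC` (10 atoms) both encode
cysteine. In microorganisms whose diets differ persistently in biologically
available nitrogen, this flexibility lets selection shave atoms off the
transcriptome: nitrogen-limited lineages should drift toward nitrogen-poor
synonymous codons in the same orthologous genes.

`codonN` implements the accounting and the inference machinery for this
question: per-codon nitrogen content in mRNA and double-stranded DNA, a
likelihood model of genome-wide synonymous codon use under selection on
nitrogen content, mutation bias and translational selection, a brute-force
maximum-likelihood fitter, a permutation test for the selection signal,
sequence simulation, likelihood-based classification of species into
nitrogen-availability groups, and an orthology-based pipeline for paired
per-gene comparisons.

## The model

For codon $C_i$ encoding amino acid $\theta$, three multiplicative biases are
modelled:

* **Selection on nitrogen content.** The relative fitness of a codon is
  proportional to its mRNA nitrogen content, $S(C_i) = s\,N_{mRNA}(C_i)$,
  giving a selection weight $\alpha(C_i) = e^{2N_g s\,N_{mRNA}(C_i)}$. The
  selection coefficient $s$ and the effective gene number $N_g$ only ever
  appear as the composite $2N_g s$ (`sel_n`), negative when selection acts to
  reduce nitrogen use.
* **Mutation bias.** With an equilibrium AT bias of $m$ (`mut_m`), the
  probability that a site is A or T is $\delta = m/(m+1)$, and the codon
  weight is $\beta(C_i) = \delta^{AT}(1-\delta)^{GC}$, with $AT$ and $GC$ the
  codon's A/T and G/C counts. $m = 1$ is neutral; $m > 1$ favours AT.
* **Translational selection.** Codon adaptiveness is
  $\omega(C_i) = \sum_j (1 - s_{ij})\,tGCN_{ij}$, summing tRNA gene copy
  numbers over recognizing isoacceptors discounted by wobble-coupling
  constraints $s_{ij}$; its weight is $\eta(C_i) = e^{2N_g\sigma\,\omega(C_i)}$
  with composite `sel_tai`. $\omega$ is used unnormalized (absolute
  adaptiveness), since it is exponentiated directly.

The probability of observing $C_i$ is its weight divided by the summed
weights of all codons encoding $\theta$, so probabilities obey the law of
total probability within every synonymous family. Six variants are supported
(each bias alone, selection+mutation, mutation+tai, all three); parameters
outside a variant sit at their neutral values. The log-likelihood of a set
of coding sequences is $\sum_i N_{C_i} \ln p(C_i \mid \theta)$ over pooled
sense-codon counts $N_{C_i}$ — it depends on the data only through those
pooled counts, and single-codon families contribute nothing.

## Fitting

With at most three free parameters, the likelihood is maximized by an
exhaustive grid search: `sel_n` over $[-1, 1]$ in steps of 0.01, $m$ on a
200-point logarithmic grid over $[0.05, 20]$, `sel_tai` over $[-1, 1]$ in
steps of 0.01, followed by one zoom pass at 10× resolution in a ±1-step
window around the coarse optimum. These ranges bracket all plausible
microbial estimates (|2N_g s| well below 0.5, m between ~0.3 and ~4) with a
wide margin. The search is deterministic; grid ties are broken toward the
neutral vector (smallest |`sel_n`|, $m$ nearest 1), which is conservative
with respect to claiming selection. Internally the weights are evaluated in
an exponential-family parameterization (`sel_n`, $\log m$, `sel_tai` acting
linearly on nitrogen count, AT count and $\omega$), so a whole coarse
surface costs a handful of matrix cross-products; a full two-parameter fit
takes tens of milliseconds, which is what makes the permutation machinery
affordable. Variants are compared by AIC $= 2k - 2\log\mathcal{L}$.

After the zoom pass the effective resolution is $10^{-3}$ for `sel_n` and
$\approx 0.3\%$ (relative) for $m$. On exact-proportional counts the fitter
recovers generating parameters to that resolution. On stochastically
simulated data the sampling noise, not the grid, limits accuracy: at
$10^6$ uniform-amino-acid codons the statistical uncertainty of the
selection estimate is of the same order as the refined grid step, so
single-seed recovery scatters by about one step, and recovery checks at
$10^5$ codons are assessed through the mean absolute error over a grid of
truths rather than per-run.

## Significance of the selection signal

Whether the *nitrogen values themselves* matter is tested by permutation:
the per-codon nitrogen contents are shuffled globally across all sense
codons, the model is refitted with the shuffled values, and the maximized
log-likelihood recorded; $p = (1 + \#\{\text{shuffled} \ge
\text{observed}\})/(n_{perm} + 1)$. The add-one form avoids $p = 0$ and is
standard for Monte-Carlo tests. The shuffle is global rather than
within-family because the hypothesis is about the assignment of nitrogen
costs to codons as such. The analysis scripts use 199 shuffles (p-value
floor 1/200 = 0.005), a problem size chosen so that the whole workflow runs
in minutes on one core; more shuffles sharpen the floor proportionally.

Paired comparisons of per-gene nitrogen means between groups use two-tailed
Wilcoxon signed-rank tests (zero differences dropped), pairing genes by
orthogroup. Spread of per-species selection estimates across groups is
summarized by one-way ANOVA, and gene-level selection can be regressed on
log10 mRNA abundance (Spearman rank correlation plus OLS slope), with the
genome-wide $m$ held fixed for per-gene fits since mutation bias is a
genome-level process.

## The synthetic data generator

Real analyses of this kind start from downloaded genomes, orthogroup
inference and curated alignments. The generator replaces that stack at desk
scale with a dataset whose truth is known: three nitrogen-availability
groups (L\_N, M\_N, H\_N) at `sel_n` = −0.24 / −0.15 / −0.13 and $m = 3.5$
(a strongly AT-biased, Mollicute-like regime), four species per group, 300
single-copy orthogroups sharing one amino-acid sequence per orthogroup,
log-normal gene lengths with mean 630 codons (sdlog 0.45, a realistic
length dispersion), and uniform amino-acid frequencies. All randomness
flows from one recorded seed.

What the generator does *not* emulate: phylogenetic non-independence among
species, indels and alignment error, gene-specific selective pressures
(expression level, mRNA structure, splice sites), non-equilibrium base
composition, and real amino-acid usage. Passing tests therefore demonstrate
that the estimator and tests are correct and calibrated under the model's
own assumptions — not that real genomes satisfy those assumptions.

## Numerical and policy choices

* Translation tables 1 (61 sense codons, the default) and 4 (TGA→Trp, 62
  sense codons) are supported; stop codons are excluded from all families
  and counts. U/T equivalence is normalized to T at parse time.
* CDS validation: genes whose length is not a multiple of three are dropped
  (logged); a terminal stop is discarded; an internal stop drops the gene;
  codons containing non-ACGT characters are skipped individually. This keeps
  counts defined over sense codons only.
* Zero-count synonymous families get uniform empirical probabilities with a
  warning, so sparse inputs keep finite likelihoods.
* Alignment columns are kept only when gap-free in every row and scoring
  strictly above 0.75; when no external column scores are supplied, a
  fallback modal-residue conservation score is computed and clearly labelled
  as not equivalent to an external aligner's score.
* Wobble coupling constants default to the widely used optimized values
  (Watson–Crick 0; G:U 0.41, I:C 0.28, I:A 0.9999, U:G 0.68) and ship as an
  editable TSV (`extdata/wobble_s.tsv`), treated as data, not code. Codons
  recognized by no tRNA get $\omega = 0$ and are flagged.
* Group-level fits pool codon counts across a group's species; per-species
  fits are also provided, and analyses record which was used.

## Known limitations

The model is genome-wide: one parameter vector per species or group, so
gene-to-gene heterogeneity in codon bias shows up as residual misfit rather
than being modelled. Biased gene conversion is deliberately not a term.
Classification between groups whose parameters are close (e.g. `sel_n`
−0.15 vs −0.13) needs on the order of $10^5$ codons to be reliable, and the
permutation test's resolution is bounded by the number of shuffles. The
selection composite $2N_g s$ confounds the selection coefficient with
effective gene number, so cross-lineage comparisons of $s$ itself require
external information about $N_g$.
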