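---
title: "Methods: detecting and stress-testing balanced polymorphisms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and stress-testing balanced polymorphisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polybal)
```

# The scientific setting

A discrete phenotypic polymorphism — here, a dominant male color pattern
mimicking the female pregnancy spot in a poeciliid fish — segregates at
intermediate frequency in every surveyed population. Two families of
questions follow. First, *mapping*: which locus controls the trait, given
only very low-coverage (~0.35x) whole-genome data from a few hundred wild
males? Second, *maintenance*: is the persistence of both alleles compatible
with neutral drift under the populations' demographic histories, and does
the locus carry the molecular footprint of balancing selection? `polybal`
implements the statistical machinery for both, plus the behavioral power
analysis used to interpret mate-choice experiments, and seeded synthetic
generators so every analysis can be exercised and calibrated without any
external data.

# Association mapping on pooled read counts

At ~0.35x coverage most individuals have zero or one read per site, so
genotype calling is hopeless and association works directly on allele read
counts. For each biallelic site, reads are pooled within phenotype classes
and compared with a binomial likelihood-ratio test: if $a_1, r_1$ are
alternate/reference read counts in cases and $a_0, r_0$ in controls, with
class ML frequencies $\hat p_i = a_i/(a_i + r_i)$ and pooled frequency
$\hat p$,

$$\Lambda = 2\left[\ell(a_1, r_1; \hat p_1) + \ell(a_0, r_0; \hat p_0)
          - \ell(a_1 + a_0,\, r_1 + r_0; \hat p)\right],
  \qquad \ell(a, r; p) = a \log p + r \log(1 - p),$$

referred to $\chi^2_1$. The statistic is zero iff the class frequencies
coincide and is symmetric in the labels. Sites with no reads in a class or
monomorphic in the pooled reads are flagged `NA`, never given a fabricated
p-value.

**Why the genome-wide threshold is permutation-based.** The binomial model
treats reads as independent draws from a class allele pool, but two reads
from the same individual share that individual's genotype (correlation 0.5
between their alleles). Pooling therefore overdisperses the statistic
whenever cells receive more than one read, and the $\chi^2_1$ tail is
anticonservative — mildly at 0.35x, strongly at high coverage. This is a
property of the model class, not of the implementation: when each
individual contributes at most one read, the model holds exactly and null
p-values are uniform (the test suite checks both facts). Consequently
nominal p-values are used only for *ranking*, and genome-wide significance
comes from `permutation_threshold()`: phenotypes are shuffled among
individuals (preserving the read-clustering structure exactly), the scan is
re-run, the minimum p recorded, and the threshold set to the
$\lceil B\alpha \rceil$-th smallest of $B$ minima (inverse-ECDF quantile; a
true-data p equal to the threshold counts as significant). Because
permutation preserves exchangeability, family-wise error control holds
regardless of the LRT's miscalibration; the test suite verifies an
empirical FWER of ~0.05 over 200 replicate datasets at the study scale
(200 individuals, 5000 sites, 0.35x, 100 permutations per replicate).

**Structure checks.** `pseudo_haploid()` draws one read per covered cell
(zero-read cells missing) — a depth-unbiased genotype proxy.
`filter_calls()` removes sites with minor allele frequency below 2% (strict
inequality) or missingness of 75% or more; the boundary semantics are
documented because the verbal rule is ambiguous at the cutoffs.
`covariate_association()` fits per-site logistic regressions with the
leading principal components of the mean-imputed, centered call matrix as
covariates (default 4); sites with (quasi-)separation are flagged rather
than reported, since their Wald p-values are meaningless. `pairwise_r2()`
reports composite LD as squared Pearson correlation of call/dosage vectors
over pairwise-complete individuals — appropriate for unphased, sparse data.

# The balancing-selection scan

Three phase-free statistics are computed in non-overlapping windows
(default 8.8 kb, the size of the inversion of interest) tiled from
coordinate 1 — the simplest reproducible tiling; the window size, phase and
invariant-site handling are all parameters because upstream conventions
vary.

* **Nucleotide diversity** uses the ratio-of-sums estimator: per site,
  the number of differing pairs among non-missing alleles over the number
  of comparable pairs, summed over sites before dividing. Invariant covered
  sites contribute zero to the numerator and full pair counts to the
  denominator, so windows with different call rates are comparable; this is
  the missing-data convention popularized by ratio-of-sums diversity tools.
  With `assume_invariant_covered = TRUE`, positions without a VCF record are
  treated as covered invariant sites — appropriate for the synthetic VCFs
  and for all-sites VCFs; set it to `FALSE` when absent records mean "no
  data".
* **Tajima's D** is the classical normalized difference between pairwise
  diversity and Watterson's estimator, using only sites genotyped in every
  haplotype (so the constants' sample size is well-defined). $S = 0$ yields
  `NA`, not zero. An excess of intermediate-frequency variants drives D
  positive.
* **NCD1** is the root-mean-square deviation of minor-allele frequencies
  from a target frequency $tf$ (default 0.3, near the observed allele
  frequency at the focal locus): small values mean frequencies cluster near
  $tf$, the long-term balancing-selection expectation. Only within-window
  polymorphic sites are used (no outgroup). Because the statistic is
  insensitive to the exact target in practice, results should be read
  alongside a small sweep of $tf$; `ncd1()` takes `tf` as an argument to
  make that sweep one `sapply`.

Windows are ranked by `empirical_quantile()`, which counts the focal window
into its own tail (upper for diversity and D, lower for NCD1), so "top
X%" statements include ties and are conservative. `recomb_matched()`
re-ranks within the windows at or below a low quantile (default 8%) of
recombination rate, removing the confounding of diversity by recombination
rate variation.

# Neutral retention under piecewise demography

Whether a polymorphism *should* have survived drift is answered by forward
simulation. A `demography_schedule` is an ordered list of
(generations-before-present, Ne) segments — the form of scaled PSMC output;
`truncate_recent()` drops the most recent segments (default 4), where PSMC
is unreliable, shortening the simulated span by the generations they cover.
`wf_run()` and `retention_probability()` iterate binomial sampling
$x_{t+1} \sim \mathrm{Binomial}(2N_t, x_t/2N_t)$ from the oldest retained
segment to the end of the schedule, with no recurrent mutation and early
exit on absorption; "retained" means both alleles present at the final
generation. Starting frequencies come from `dominant_freq()`:
$d = 1 - \sqrt{1 - f}$ converts a dominant phenotype frequency $f$ into its
Hardy–Weinberg allele frequency (0.39 → 0.219, 0.24 → 0.128, 0.29 → 0.157).

Correctness is pinned to independent oracles: at small $2N$ the simulated
retention matches the exactly-computed distribution from powering the
$(2N{+}1)$-state binomial transition matrix; neutral fixation probability
equals $p_0$; heterozygosity decays as $(1 - 1/2N)^t$. Defaults follow the
study conventions (10,000 replicates; mutation rate $3.5\times10^{-9}$ and
generation time 0.5 yr carried on the schedule for scaling helpers).

`retention_probability()` advances all replicates in lock-step on one
seeded stream (vectorized binomial draws per generation, absorbed
replicates dropping out). This is bit-reproducible given (parameters,
seed) and far faster in R than per-replicate streams; `wf_run()` offers the
single-trajectory interface when a per-run seed or trajectory is wanted.

The inferred per-population segment tables are not distributed with the
package, so published retention values (e.g. ~2.3% for a strongly
bottlenecked population) are reproducible in *procedure* but not in
*value*; the package instead verifies the driving phenomenon — a
3000-generation bottleneck at $N_e = 300$ inside an $N_e = 10^4$ history
strictly lowers retention relative to the matched constant-size schedule,
over 50 seed-paired replicate pairs on a 5000-generation span (a desk-scale
span chosen so the constant-size arm retains polymorphism at high
probability while the bottleneck arm loses it; heterozygosity decays by
$e^{-3000/600} \approx 0.7\%$ through such a bottleneck, so the ordering is
insensitive to the span).

# Haplotype–phenotype association and diagnostic sites

With long-read assemblies, phenotype–haplotype co-segregation reduces to
small exact tests: `fisher_exact()` (standard two-sided convention: sum of
point probabilities ≤ observed, tolerance $1+10^{-7}$; one-sided in the
direction of the observed odds ratio) and `two_prop_z()` (pooled-variance
two-proportion z). `prob_all_het()` quantifies whether observing *only*
heterozygous carriers in a sample of $n$ phenotype-positive individuals is
surprising: under HWE and full dominance a carrier is heterozygous with
probability $2d(1-d)/f$, so the analytic answer is $(2d(1-d)/f)^n$ (0.399
at $f = 0.39$, $n = 7$ — unremarkable); the simulation route draws carrier
genotypes by rejection from HWE and must agree within Monte Carlo error.
`diagnostic_snps()` implements the fixed-difference filter for diagnostic
markers: a position is kept iff each group is fixed for a different base,
no gap or ambiguity occurs there, and the position is more than 5 bp
(default) from every indel, where alignment artifacts concentrate.

# Mate-choice power analysis

Preference in dichotomous choice trials is scored per female as the
difference in the proportion of trial time spent with the two stimuli, in
$[-1, 1]$, tested against zero with a two-sided Wilcoxon signed-rank test
(zeros dropped; exact null distribution for $n \le 25$ without ties, else
normal approximation with continuity and tie corrections — `wilcox.test`'s
conventions, which the implementation delegates to). `power_simulation()`
draws datasets from $\mathrm{Normal}(\text{effect}, sd)$ — plain normals,
matching the generative model of the original power analysis; the bounded
generator `simulate_trials()` (truncation by rejection, since a difference
of proportions is bounded) is kept separate — and reports the fraction of
replicates with $p < \alpha$ strictly. `power_curve()` sweeps the effect
grid (default 0–0.4 by 0.025, 17 points) with common random numbers, so
curves are smooth and comparisons across sample sizes with a shared seed
are paired. Because the exact test is discrete, the attained size at
$\alpha = 0.05$ is below nominal at small $n$: 0.0448 at $n = 17$, 0.0484
at $n = 23$ (computed from the exact null distribution and verified by
simulation). Observed group standard deviations are inputs, not constants:
published power figures depend on them and are reproducible in procedure
only.

# The synthetic-data generators

The generators produce data with exactly the structure the analyses assume,
which is what makes the calibration tests meaningful — and bounds what they
show.

* `simulate_population()`: HWE genotypes at independent sites (background
  frequencies uniform on [0.05, 0.5] by default), a causal site at
  $d = 1-\sqrt{1-f}$, and a dominant phenotype with configurable
  penetrance. Independence of sites means no LD and no population
  structure; tests of structure correction build stratified data
  explicitly.
* `simulate_reads()`: Poisson($\lambda$) reads per cell, each reporting a
  uniformly chosen chromosome, flipped with probability $\varepsilon$. This
  reproduces the depth distribution and the within-individual read
  clustering of real shallow data (see the association section), but not
  mapping bias, base-quality variation or reference bias.
* `simulate_neutral_window()`: a standard Kingman coalescent with
  infinite-sites mutation (exponential coalescence at rate
  $\binom{k}{2}$, Poisson($\theta t/2$) mutations per lineage per
  interval), positions uniform without replacement on the window —
  infinite sites on a finite grid, which keeps windows VCF-representable.
  $E[S] = \theta\sum_{i<n} 1/i$ is verified in the tests.
* `simulate_balanced_window()`: a structural emulation of an old balanced
  polymorphism — neutral coalescent variation over the whole sample, plus
  $\mathrm{Poisson}(\theta\, t_{\text{split}})$ class-diagnostic sites
  fixed between two allelic classes drawn at frequencies $tf$/$1-tf$. The
  default $t_{\text{split}} = 5$ coalescent units represents allelic
  classes far older than the within-population coalescent, the regime the
  long-read phylogeny of the focal locus indicates. At
  $t_{\text{split}} = 0$ the generator reduces *exactly* to the neutral
  one, which pins the null; selection is emulated structurally rather than
  through fitness, so the generator supports property tests (elevated
  diversity, depressed NCD1, top-decile ranking of a planted window) but is
  not a substitute for a structured coalescent when quantitative accuracy
  of the balanced-window statistics' distribution matters.
* `simulate_trials()`: truncated normal preference differences, as above.

All generators take a `seed` and are bit-reproducible given (parameters,
seed).

# Numerical choices and degenerate inputs

* $0\log 0 = 0$ in all binomial log-likelihoods; tiny negative LRT values
  from rounding are clamped to zero.
* Undefined statistics (no comparable pairs, $S=0$, no SNPs, zero reads in
  a class, separation) are `NA` plus a flag — never silently 0 or 1.
* Quantile conventions are explicit everywhere: inverse-ECDF
  ($\lceil n\alpha\rceil$-th order statistic) for the permutation
  threshold, focal-inclusive tail counts for window ranks,
  threshold-inclusive (`<=`) retention for recombination matching; ties are
  always resolved toward inclusion/significance (conservative for "top X%"
  claims).
* Effective sizes are rounded to integers ≥ 1 before binomial sampling.
* Problem sizes used by the test suite (its own desk-scale choices): 2000
  replicate windows for neutral-D calibration; 200 replicate datasets of
  200 individuals x 5000 sites at 0.35x with 100 permutations each for
  FWER; 50 seed-paired schedule pairs for the bottleneck ordering; 20
  replicate 51-window chromosomes for planted-window ranking; full
  enumeration of 2x2 tables to total 30 and of $2^n$ sign assignments to
  $n = 12$ for the exact-test oracles.

# Known limitations

* The binomial LRT ignores within-individual read clustering by design;
  its nominal p-values rank sites but are anticonservative in the tail —
  use the permutation threshold for significance (this is the package's
  central calibration message, and the test suite demonstrates both sides).
* The balanced-window generator is a structural heuristic, not a
  population-genetic model of balancing selection.
* The drift simulator is single-locus and mutation-free: no selection,
  linkage, or recurrent mutation.
* PCA-based structure correction assumes structure is linear in the call
  matrix and that mean imputation of missing calls is benign at the
  missingness levels left after filtering.
* The scan assumes biallelic sites; multi-allelic records are rejected.
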