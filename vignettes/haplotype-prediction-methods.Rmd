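---
title: "Methods: LD-defined haploblocks and haplotype-based genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LD-defined haploblocks and haplotype-based genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hapblup)
```

This vignette is the package's account of its statistical machinery: the
models, the constructions, the numerical choices, and what the simulated
study conditions do and do not demonstrate.

## 1. The prediction problem

Litter traits such as the number of piglets born alive are sex-limited,
lowly heritable and repeatedly recorded, so genomic prediction for them is
conventionally run in two stages. First a pedigree **repeatability animal
model** turns raw records into one corrected phenotype per sow; then a
genomic mixed model regresses those corrected phenotypes on a marker-derived
relationship matrix to predict breeding values of young, unphenotyped
animals. The package's question is whether replacing SNP dosages with
**haplotype-allele dosages** — built from variable-length blocks of SNPs in
mutual linkage disequilibrium (LD) — changes the accuracy and bias of those
predictions, in a single population and when two related populations pool
their reference animals.

## 2. Stage one: the repeatability model and corrected phenotypes

For records $y$ with herd-year-season (HYS) fixed effects $b$:

$$y = Xb + Za + Wpe + e, \qquad
  a \sim N(0, \sigma_a^2 A),\;
  pe \sim N(0, \sigma_{pe}^2 I),\;
  e \sim N(0, \sigma_e^2 I)$$

`build_additive_relationship()` fills $A$ by the tabular method
($A_{ii} = 1 + F_i$, unknown parents contribute nothing), after a
topological sort that rejects pedigree cycles by name.
`fit_repeatability()` estimates the three variance components by REML
(section 6) and returns BLUP solutions for $a$ and $pe$, BLUE for the HYS
classes, per-record residuals $\hat e$, and reliabilities
$1 - \mathrm{PEV}_i/\sigma_a^2$ clamped to $[0,1]$.

The **corrected phenotype** of sow $i$ is
$y_c(i) = \hat a_i + \overline{\hat e_i}$, the EBV plus the plain mean of
the animal's record residuals. The permanent-environment solution is *not*
added by default: it is a non-transmissible nuisance, and $y_c$ is paired
with genomic breeding values downstream. Because the phrase "average
estimated residuals" admits the other reading, `include_pe = TRUE` switches
it on. Sows with reliability below 0.3 (`filter_by_reliability()`) are
excluded from genomic analyses, the conventional cut.

Degenerate inputs are handled explicitly: a zero-variance phenotype yields
a flagged degenerate fit with all components at zero; when no animal has
repeated records, $\sigma_{pe}^2$ is confounded with $\sigma_e^2$
record-for-record, so the term is dropped (fixed at zero) with a warning
and the model collapses to the plain animal model; an HYS class whose
records all come from one animal is reported as confounded.

## 3. Variant QC

`apply_variant_qc()` applies, in order: call rate $\ge$ 0.90, minor allele
frequency $\ge$ 0.01, Hardy-Weinberg exact-test $p \ge 10^{-7}$. The order
is a deliberate choice — frequency-based filters should only see reliably
called genotypes — and each filter's removal count is reported. The HWE
test is the exact conditional test (enumeration over heterozygote counts
given allele counts, summing outcomes no more probable than the observed
one); a chi-square approximation misbehaves at desk-scale counts, and the
convention used is flagged in the QC report header together with the
frequency scope (frequencies are computed on the sample set as supplied, so
pooled-set filtering requires merging the populations first).
`prune_duplicate_ld()` then removes near-duplicates: a greedy left-to-right
within-chromosome scan drops any SNP whose $r^2$ with an earlier *kept* SNP
reaches 0.999, so exactly the first SNP of each duplicate run survives.
Cross-chromosome duplicates are not searched — they are not expected
biologically — and a `max_window_snps` lookback bounds the scan on dense
panels.

## 4. Haploblocks and haplotype-allele dosages

LD between loci $i, j$ is the composite (genotype-dosage) measure
$r^2 = \mathrm{cov}(g_i,g_j)^2 / (\mathrm{var}(g_i)\mathrm{var}(g_j))$
with $g \in \{0,1,2\}$; it needs no phasing, is symmetric, bounded in
$[0,1]$ and invariant to which allele is counted. `signed_r()` keeps the
sign for the phase diagnostic below.

A **haploblock** at threshold $t$ is a run of consecutive SNPs in which
*every* pair has $r^2 \ge t$. The defining rule fixes membership but not
the construction, so the package formalises it as a greedy left-to-right
complete-linkage scan per chromosome: open a block at the first unassigned
SNP, append the next consecutive SNP iff its $r^2$ with every current
member (within a `max_window_snps = 100` lookback) clears $t$, close when
extension fails. Ties at exactly $t$ are included ("greater than or
equal"). Runs of length one are reclassified as **non-blocked** singleton
SNPs. The tests hold this construction to an exhaustive leftmost-maximal
oracle on small panels and audit the all-pairs rule post hoc. The default
ladder is $t = 0.1, 0.2, \dots, 0.9$: toward $t \to 0$ a whole chromosome
becomes one block, toward $t \to 1$ every SNP stands alone.

`recode_haplotype_dosages()` maps each distinct observed haplotype string
of a block to a pseudo-marker column counting 0/1/2 copies per animal;
within a block each animal's row sums to 2 and column frequencies sum
to 1. Two modes matter downstream:

* **GHBLUP** uses blocks *plus* every singleton SNP as a one-SNP haplotype
  (two complementary columns $g$ and $2-g$), so all markers are
  represented and the information content matches GBLUP's. Whether
  singletons belong in GH at all is genuinely open; the package implements
  both (`include_singletons`), defaults to inclusion, and the
  `GH_plus_GBLUP` model covers the alternative reading.
* **GH+GBLUP** uses blocks-only GH plus a SNP matrix on the non-blocked
  SNPs as a second random effect.

No rare-haplotype-allele filter is applied by default; `min_allele_count`
makes one available.

## 5. Relationship matrices and the single-SNP identity

`compute_grm()` centers each column by twice its observed frequency and
scales by the heterozygosity sum:
$$G = \frac{MM'}{2\sum_i p_i(1-p_i)}.$$
The same code builds GH from haplotype-allele columns. Frequencies are
taken from the full analysis set (reference plus validation), the
conventional choice; population-specific centering is possible by
subsetting first. For a one-SNP haplotype, the two complementary columns
double both the cross-product and the divisor, so **GH from single-SNP
haplotypes equals G exactly** — `grm_identity_snp1()` verifies the identity
to $10^{-10}$, and with identical relationship matrices the three
predictors coincide. This algebraic anchor is the package's strongest
correctness check, because it must hold on *any* panel.

## 6. REML: one engine, three models

All variance components are estimated by **average-information REML** on
the record-level covariance
$V = \sum_i \theta_i V_i + \theta_e I$:

* restricted log-likelihood
  $-\tfrac12(\log|V| + \log|X'V^{-1}X| + y'Py)$ with
  $P = V^{-1} - V^{-1}X(X'V^{-1}X)^{-1}X'V^{-1}$;
* score $-\tfrac12(\mathrm{tr}(PV_i) - y'PV_iPy)$, where
  $\mathrm{tr}(PV_i)$ is computed as an elementwise product sum so each
  iteration costs one Cholesky factorisation, not repeated matrix products;
* AI matrix $\tfrac12\, y'PV_iPV_jPy$ from matrix-vector work only.

The first iteration is an EM step (robust far from the optimum); later
iterations take AI steps with step-halving when a move would leave the
parameter space or lower the likelihood, and an EM fallback otherwise.
Components are kept above a floor of $10^{-8}\,\mathrm{var}(y)$; a
component pinned at the floor whose score points further down is frozen
out of the update (active-set treatment), which is what lets boundary
cases — zero permanent-environment variance, noise-free phenotypes —
converge instead of crawling. Convergence requires a relative likelihood
change below $10^{-8}$ *and* a parameter change below $10^{-6}$ (relative
to $\mathrm{var}(y)$) within 200 iterations; non-convergence is an error
carrying the likelihood trajectory. Fixed variance components can be
supplied to skip iteration (used by the SNP-BLUP equivalence check, where
relationship-matrix GBLUP must match marker-effect ridge regression with
$\lambda = \sigma_e^2/(\sigma_g^2/\text{divisor})$ to $10^{-6}$).

In the genomic models the only fixed effect is the overall mean ($y_c$ is
already adjusted), the incidence matrix is shared between the two genomic
terms of GH+GBLUP, and every genotyped animal appears in the relationship
matrices while only reference animals contribute phenotype rows — so
validation GEBV are predicted through genomic covariances,
$\hat g = \hat\sigma_g^2\, G_{\cdot,\text{ref}} P y$. A ridge of
$10^{-8} \times$ mean diagonal is added before factorisation because GH
with complementary singleton columns is exactly rank-deficient.

## 7. The simulator: what it emulates, and what it does not

`sim_dataset()` provides the study conditions the methods are exercised
under, since the motivating multi-population pig data are proprietary:

* **Founders.** `n_founders = 200` animals, `n_snps = 1000` SNPs on 5
  chromosomes of 1 Morgan (1 cM/Mb). Allele frequencies follow a U-shaped
  Beta(0.5, 0.5) spectrum (clipped to [0.02, 0.98]). Founder haplotypes
  carry **ancestral LD** via a first-order Markov chain whose allele
  correlation decays as $\exp(-d/\lambda)$ with `founder_ld_cm` $\lambda$
  = 3 cM. This shortcut stands in for a long ancestral drift phase: it is
  what gives the two descendant populations *shared* LD to lose. Without
  it, split populations in linkage equilibrium develop only independent
  drift LD and their LD-phase correlation is near zero at any divergence
  time.
* **Divergence.** The pool splits in half; each half breeds for
  `generations_split = 10` non-overlapping generations of random mating
  (cohort size `n_pop1 = n_pop2 = 100`; sexes assigned at birth, sires
  and dams drawn from the previous cohort) with Haldane recombination —
  Poisson crossover counts with mean equal to the map length, no
  interference. The default divergence time was calibrated once so that
  the mean between-population correlation of signed $r$
  (`ld_phase_correlation()`, 5 Mb pair window) lands near 0.5 — the
  moderately-consistent-LD regime the haplotype method targets; longer
  divergence lowers it monotonically, which is itself a tested property.
  The 5 Mb window is deliberate: long-range pairs carry no ancestral LD
  and only dilute the diagnostic with drift noise.
* **Genotyped set.** The last two cohorts of each population (older cohort
  = prospective reference, final cohort = validation), 400 animals in all,
  with birthdates one year apart per generation so `split_by_birthdate()`
  has a natural cut.
* **Trait.** `n_qtl = 50` additive QTL drawn from the SNP panel with
  normal effects rescaled so the realized additive variance among
  genotyped animals is exactly $\sigma_a^2 = 1$; then
  $\sigma_{pe}^2 = \sigma_a^2(\rho - h^2)/h^2$ and
  $\sigma_e^2 = \sigma_a^2(1-\rho)/h^2$ from the defaults $h^2 = 0.3$,
  repeatability $\rho = 0.5$. Every genotyped animal receives
  `n_parities = 3` records with a random HYS class from 5 levels
  (effect SD 0.5). All genotyped animals are phenotyped as sows; sex is
  modelled only for mating, since halving the records to simulated
  females would just shrink desk-scale power without changing any method
  under test.

Not emulated: selection, overlapping generations, genotyping or imputation
error, real chromosome counts or marker densities, migration after the
split, and contemporary-group structure beyond a single categorical HYS
factor. Passing tests therefore show the machinery is correct and behaves
in the expected directions under drift-type divergence; they do not
forecast accuracy magnitudes on real livestock data.

## 8. Problem sizes and runtime choices

The shipped tests run the pipeline at deliberately modest sizes — panels of
up to 2,000 SNPs, 400-1,000 animals, 10-seed Monte-Carlo loops for
parameter-recovery checks (repeatability model at 500 sows × 3 parities;
genomic variance recovery at 500 animals) — chosen so the whole suite
completes in a few minutes on one core while keeping sampling error well
inside the asserted tolerances. `scripts/acceptance.R` reruns the full
chain at the default study conditions from a single `--seed` and writes
every headline quantity it computes as JSON.

## 9. Known limitations

* The LD-threshold block rule is scan-order dependent in principle; the
  greedy-from-left construction is fixed and oracle-tested, but other
  valid partitions of the same panel exist, and block nesting across
  thresholds is typical rather than guaranteed.
* Dense-matrix REML is $O(n^3)$ per iteration in the number of records;
  beyond a few thousand records a sparse mixed-model-equation
  implementation would be the right tool.
* Reliability uses $1 - \mathrm{PEV}/\sigma_a^2$ without an inbreeding
  correction in the denominator; with the simulator's shallow pedigrees
  the difference is negligible.
* PLINK input is read unphased and serves the QC stages only; haplotype
  recoding requires phased VCF input.
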