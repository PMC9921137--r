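---
title: "Measuring clonal diversity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring clonal diversity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonediv)
```

## The problem

A clonally propagated variety is a set of lineages descended from one
mother plant. All of its diversity is somatic: microsatellite alleles that
slipped by a repeat unit, retroelements that inserted or excised, and
quantitative traits that drifted under many small genetic and environmental
effects. `clonediv` measures that diversity from three assays — codominant
SSR genotypes, dominant band profiles, and replicated quantitative traits —
and asks whether the three classifications agree.

This vignette explains the statistical machinery, the defaults, and the
choices made where more than one defensible convention exists.

## Diversity indices

For a locus with allele frequencies $p_1,\dots,p_k$ counted over all
non-missing allele copies ($2 \times$ samples):

* $H_o$ — fraction of non-missing samples with two distinct alleles;
* $H_e = 1 - \sum_i p_i^2$ — **without** the $2n/(2n-1)$ small-sample
  correction. The uncorrected form is the one under which a biallelic locus
  where every sample is the same heterozygote gives exactly $H_e = 0.50$
  (the corrected form gives $\approx 0.515$), matching how such loci are
  conventionally tabulated in clone studies;
* $I = -\sum_i p_i \ln p_i$ (Shannon);
* $F = (H_e - H_o)/H_e$, reported as missing when $H_e = 0$: the ratio is
  undefined at a monomorphic locus and reporting 0 there would fake
  equilibrium. Under fixed heterozygosity $F \to -1$;
* $E = \frac{1/\lambda - 1}{e^{H} - 1}$ with $\lambda = \sum_i p_i^2$ and
  $H = I$ (Stoddart–Taylor evenness), computed from **allele** frequencies,
  not multilocus-genotype frequencies — this is the reading under which the
  published per-locus values of clone panels (e.g. $E = 0.83$ for a
  four-allele locus with a 94% predominant combination) are reproduced.
  A monomorphic locus gets $E = 1$ by the $0/0$ limit (uniform frequencies
  of any order give exactly 1).

Internal values are kept at full precision; `round_half_up()` is provided
for display because diversity tables conventionally round halves away from
zero.

Multilocus genotypes are matched strictly by default: a missing call
matches nothing, so partial profiles are never merged silently. A lenient
mode (missing is compatible with anything, greedy merge in input order) is
available because partial profiles are common in practice.

## Distances

**Prevosti** (codominant, between individuals): each individual is a
frequency vector per locus (homozygote 1; heterozygote 0.5/0.5) and
$d = \frac{1}{m}\sum_{\ell}\frac{1}{2}\sum_a |p_a(x)-p_a(y)|$ over the $m$
loci where both samples have calls. Distances are between individual
clones, not populations, because the dendrogram leaves are clones. Missing
loci are dropped pairwise with renormalization by $m$ — the conventional
extension; a pair sharing no locus is an error rather than a silent `NA`.

**Jaccard** (dominant): $1 - |x \cap y| / |x \cup y|$; joint absences carry
no signal for dominant markers and are excluded by definition. A pair of
all-empty profiles is 0 (identical emptiness) with a warning.

**Gower** (traits): replicates are averaged per clone first (clustering
operates on one point per clone), each trait is Z-scored across clones, and
then range-normalized absolute differences are averaged. Z-scoring before
range normalization is redundant for a single trait but not for several;
the pipeline applies both, in that order. Constant traits are dropped with
a warning — they carry no information under range normalization.

## UPGMA, cophenetic analysis, Newick

`upgma()` implements classic average linkage with size-weighted updates.
Conventions:

* **node height** = merge distance / 2, so the cophenetic value of two
  leaves (2 × height of their lowest common ancestor) is on the scale of
  the input distances — required for cophenetic correlations and for
  Mantel tests on cophenetic matrices;
* **tie-break**: among pairs at the minimal distance, the pair whose
  smallest member labels sort lexicographically first merges first, and the
  lexicographically smaller child is written first, so identical inputs
  give byte-identical Newick strings;
* branch lengths are parent height − child height; leaf-to-leaf path
  lengths therefore reproduce the cophenetic matrix (round-tripped through
  an independent Newick parser in the tests).

UPGMA applied to an ultrametric matrix reconstructs it exactly, and every
cophenetic matrix is ultrametric; both properties are enforced by tests,
which also check equality with a from-definition oracle (average distances
recomputed from the original matrix at every step) and with
`stats::hclust(method = "average")`.

## Mantel tests and the concordance table

The Mantel statistic is the Pearson correlation of the lower triangles;
the null is built by jointly permuting rows and columns of one matrix.
P-values use the add-one rule $(\text{hits}+1)/(n_{perm}+1)$, so
$p \ge 1/(n_{perm}+1)$ and identical seeds give identical p-values. The
default is 9999 permutations. For six or fewer samples the test can
enumerate all $n!$ permutations exactly.

The default alternative is `"greater"`: concordance between classifications
of the same material is a one-sided hypothesis. A two-sided option exists
because published concordance tables sometimes report large p-values for
negative correlations, which is consistent with either convention.

Matrices are aligned by label; a label mismatch is an error, never a
silent positional match. The concordance table reports distance-matrix
tests below the diagonal and cophenetic-matrix tests above it, with each
test seeded by a distinct sub-seed derived from one top-level seed.

## Morphology stage

Derived traits — bunch compactness index (berries per bunch / total rachis
length, berries/cm) and TSS/TA — are computed **per observation** and then
averaged per clone. The alternative (ratio of clone means) gives visibly
different numbers (e.g. 133 berries / 14.0 cm = 9.5 ≠ 9.9); published
clone tables are consistent with per-observation computation.

Duncan's multiple range test uses critical ranges
$R_p = q_{(1-\alpha)^{p-1},\,p,\,df_e}\sqrt{MSE/n_h}$ with the harmonic
mean group size $n_h$ for unbalanced data, and the protected stepwise
rule: a pair inside any non-significant wider range is not separated.
Letters are assigned to maximal runs of mutually non-separated means, so
two groups share a letter iff no significant range separates them. When the
within-group variance is numerically zero the ANOVA is flagged degenerate
and letters fall back to exact equality of means.

PCA is of the correlation matrix (clone means standardized): eigenvalues
then sum to the number of variables, which is how published trait-PCA
tables are scaled. Components are retained while the eigenvalue exceeds
$10^{-9}$ — with collinear derived variables (a ratio and its parents) the
trailing eigenvalues are numerically zero and carry no variance; percent
variance is taken relative to the retained sum. Variable–component
correlations are $\text{loading}\times\sqrt{\text{eigenvalue}}$, with
two-sided t tests on $r$ at $n-2$ df for the significance codes.

## The synthetic clone panel

`simulate_clonal_population()` draws one founder — heterozygous at every
SSR locus, mirroring the fixed heterozygosity of clonally propagated
crops — and derives each clone independently:

* **SSR**: each allele copy mutates with probability
  `ssr_mutation_rate` per clone, stepping ±1 repeat motif with equal
  probability (symmetric single-step stepwise mutation model — the
  standard microsatellite model, chosen because somatic slippage is not
  modeled explicitly in clone studies);
* **bands**: presence flips 1→0 with `band_loss_rate` and 0→1 with
  `band_gain_rate`; separate rates, since element insertion and excision
  are mechanistically asymmetric;
* **traits**: value = grand mean + clone effect (drawn once per clone) +
  replicate noise, both zero-mean normal.

Defaults describe a study-sized panel: 17 clones, 10 loci (founder allele
pool of 2–4 sizes per locus, 2-bp motif), 26 bands at founder prevalence
0.45 (≈ 12 bands per clone), 5 trait replicates, and rates chosen once so
the panel reproduces the summary structure such studies report:
`ssr_mutation_rate = 0.05` per allele per clone gives an expected mean
pairwise Prevosti distance of $2 \times 20r \times 0.05 \approx 0.10$ and
leaves roughly a third of clones carrying the unmutated founder profile
(≈ 11–14 multilocus genotypes among 17); band rates 0.12/0.08 give ≈ 2.5
flips per clone, making essentially every band profile unique. These rates
are free parameters of the generator, not estimates of any real somatic
rate. Trait means and s.d. are on the scale of bunch/berry measurements
(≈ 110 berries per bunch, ≈ 16 cm rachis, ≈ 22 °Brix).

Since a diploid founder carries exactly two alleles, the configured 2–4
"founder alleles per locus" is implemented as the size of the per-locus
allele pool the founder's two alleles are drawn from; additional alleles
enter the population only by mutation.

Reproducibility: one top-level seed deterministically derives a sub-seed
per stage (founder, SSR mutation, bands, traits), so outputs are
bit-identical across runs and a change in one stage's code cannot shift
another stage's draws. The low-level mutation operators draw from the
current R random stream, which is the idiomatic R equivalent of passing an
explicit generator.

**What the generator does not emulate**: genotyping error and allelic
dropout, linkage between loci, selection, homoplasy structure beyond
single-step slippage, environment-by-clone interaction in traits, and any
geographic structure. Passing tests on simulated panels therefore validate
the *arithmetic and algorithms*, not field-data robustness to those
artifacts.

## Numerical conventions and degenerate inputs

* Distance matrices must be symmetric within $10^{-9}$, nonnegative,
  zero-diagonal; they are symmetrized exactly on construction.
* Constant half-matrices make correlations undefined: an error in
  `mantel_test()` (a test would be meaningless), a warning + `NA` in
  `cophenetic_correlation()`.
* Replicate consensus requires a strict majority; ties and three-way
  disagreement give a missing call, and every non-unanimous cell is logged
  with its calls.
* Test problem sizes: the brute-force UPGMA oracle runs on 1000 random
  matrices of up to 5 samples; Mantel calibration uses 100 independent
  10-sample pairs at 9999 permutations; ANOVA type-I calibration uses 1000
  null simulations; exhaustive Mantel enumeration is used up to 6 samples.
  These sizes make the Monte-Carlo bands (3 binomial s.d.) tight enough to
  catch implementation errors while keeping the suite fast.

## Known limitations

* UPGMA is $O(n^3)$ as implemented; panels here are tens of clones, for
  which this is instantaneous.
* The GenAlEx reader covers the codominant CSV layout (count row, title
  row, one sample per row); exotic multi-population layouts are out of
  scope.
* Published concordance values for any particular study cannot be
  recomputed without that study's raw profiles; the package validates its
  machinery by oracle equivalence, exhaustive enumeration, metric/
  ultrametric properties and statistical calibration instead.
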