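---
title: "Single-step genomic evaluation for fish breeding nuclei: models, algorithms and design choices"
author: "aquaGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step genomic evaluation for fish breeding nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Carcass traits such as fillet yield cannot be measured on live selection
candidates, so a fish breeding nucleus must select candidates on
information from slaughtered relatives. Genomic selection removes that
bottleneck: with genome-wide SNP genotypes, the realized relationships
among full and half sibs separate within-family Mendelian sampling, and
candidates can be ranked on their own genotypes. The obstacle is cost —
genotyping thousands of candidates per year-class with a high-density
(HD) chip is expensive. A widely used remedy genotypes parents and a
fraction of offspring at HD, the remaining offspring with a cheap
low-density (LD) panel, and imputes the missing genotypes through the
family structure.

`aquaGS` implements this whole evaluation loop as composable, tested
pieces: a breeding-population simulator, genotype QC and relationship
matrices, an animal-model REML/BLUP engine, a weighted single-step GWAS,
LD-panel design and family-based imputation, cross-validated prediction
accuracy, and a genotyping-cost model.

# The animal model

Every evaluation in the package fits the same linear mixed model,

$$ y = X\beta + Z a + W c + e, $$

where $y$ holds one trait (e.g. fillet yield in percent, or harvest
weight in grams), $\beta$ the contemporary-group fixed effects plus one
covariate, $a \sim N(0, K\sigma^2_a)$ the additive breeding values over
*all* pedigree animals, $c \sim N(0, I\sigma^2_c)$ a common-environment
effect shared by the full sibs of each family (hatching and early rearing
happen family-by-family in separate hapas, which inflates full-sib
resemblance beyond the additive expectation — omitting $c$ would inflate
$\sigma^2_a$), and $e \sim N(0, I\sigma^2_e)$. Heritability is
$h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_c + \sigma^2_e)$.

The kinship $K$ is either the pedigree relationship matrix $A$ (PBLUP) or
the single-step matrix $H$, whose inverse replaces the genotyped block:

$$ H^{-1} = A^{-1} + \begin{bmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1}
\end{bmatrix}. $$

Here $G$ is the (optionally SNP-weighted) VanRaden matrix
$Z_m D Z_m'/(2\sum_j p_j(1-p_j))$ built from dosages centered at observed
allele frequencies, and $A_{22}$ the pedigree sub-matrix of the genotyped
animals. Two standard numerical repairs are applied before inversion and
are exposed as arguments of `makeG()`:

* **tuning** — a two-parameter adjustment $a + bG$ matching the mean
  diagonal and mean off-diagonal of $G$ to $A_{22}$, so the two
  relationship scales are compatible;
* **blending** — $G^* = 0.95\,G + 0.05\,A_{22}$. A $G$ centered at
  observed frequencies is singular by construction (the vector of ones is
  in its null space), so some blending is *required*, not cosmetic.

Whether the original analyses tuned or blended is not documented in the
study this package re-implements, so both knobs are explicit and
overridable rather than hard-wired.

`solveMME()` solves Henderson's equations by sparse Cholesky
factorization, with the variance ratios
$\lambda_a = \sigma^2_e/\sigma^2_a$, $\lambda_c = \sigma^2_e/\sigma^2_c$
on the random blocks; the contract is a relative residual below $10^{-8}$,
not a particular factorization. The contemporary-group factor enters with
an intercept and treatment contrasts (a drop-first-level constraint):
contrasts are invariant to this choice but raw solution values are not,
which is why it is documented. Covariates are centered, which moves their
mean into the intercept and changes nothing else.

# REML

`remlVC()` estimates $(\sigma^2_a, \sigma^2_c, \sigma^2_e)$ by
average-information REML. Each iteration solves the mixed-model equations,
forms the exact first derivatives from the solutions and the inverse
coefficient matrix, and takes a Newton step with the average-information
matrix. Three safeguards make the iteration robust at desk scale:

* **step-halving** — an AI step that would leave the parameter space is
  damped by factors of 2 until admissible;
* **EM fallback** — if no damped step is admissible, a (guaranteed
  in-bounds) EM update is taken instead;
* **boundary pinning** — a component whose proposal drops below
  $10^{-3}$ of the phenotypic variance while its score is still negative
  is fixed at (effectively) zero and removed from the update set, with its
  standard error reported as `NA`. Small designs with few families often
  cannot support $\sigma^2_c > 0$; declaring the boundary is more honest
  than oscillating around it.

Convergence is a maximum relative parameter change below $10^{-8}$
(default cap 200 iterations). Standard errors come from the inverse AI
matrix at convergence; the standard error of $h^2$ uses the delta method
on that covariance, and is labelled as such because a resampling-based
alternative would generally differ. The score and likelihood
implementation is verified in the test suite against a dense
projection-matrix oracle on a small pedigree, so the sparse identities
cannot silently drift from the definition.

# Weighted single-step GWAS

`runWssGBLUP()` iterates the classic weighting loop: iteration 1 is plain
ssGBLUP (unit SNP weights); each later iteration back-solves SNP effects
from the genotyped animals' GEBV,

$$ \hat u = D M' G^{*-1} \hat a_g / (2\textstyle\sum_j p_j q_j), $$

re-weights each SNP by its estimated variance
$d_j = \hat u_j^2\, 2 p_j q_j$ (normalized to sum to the SNP count, so the
trace of the weighted $G$ is preserved), rebuilds $G^*$, and refits.
Iteration 2 is flagged as the reporting default — further iterations
concentrate weight on few SNPs without improving localisation. Variance
components are estimated once, under unit weights, and reused across
iterations.

Association signal is summarised as the percentage of genetic variance
explained by non-overlapping windows of 20 consecutive SNPs:
$100 \cdot \mathrm{var}(M_w \hat u_w) / \mathrm{var}(M \hat u)$, computed
over the genotyped animals. The variance of the window score includes
within-window LD covariance (the convention of the postGS-style
pipelines); a `method = "sum"` alternative adds per-SNP variances and is
only equivalent under linkage equilibrium. Window percentages are
invariant to rescaling $\hat u$, and top windows are ordered by percent
with ties broken by genomic position.

# Low-density panels and imputation

`selectLDPanel()` mimics chromosome-wide pairwise LD pruning: each
chromosome receives a quota proportional to its length, and a bisection
search finds the pairwise-$r^2$ threshold whose greedy, step-1 pruning
survivor count best matches the quota (survivors beyond the quota are
thinned evenly). The pruning window is the whole chromosome: the
published pruning command used a window far larger than any chromosome,
which we read as chromosome-wide pruning.

`imputeGenotypes()` fills validation animals from a low-density panel up
to the HD panel with a deliberately transparent family-first algorithm
(the study used a closed-source imputation tool; we implement the stated
design — pedigree use, long-to-short windows — not its code):

1. **Gamete deduction.** For each reference parent, the gamete it
   transmitted to each of its HD reference offspring is deduced by
   Mendelian rules (homozygous child or parent; otherwise the mate's
   homozygosity resolves the split). Each deduced gamete also implies its
   Mendelian complement (parent dosage minus gamete), which is locally
   the parent's other haplotype: the complements double the library and
   mean that one observed sib gamete is enough to expose *both* parental
   haplotypes in a region.
2. **Window matching.** The validation animal's received gamete is
   deduced the same way at its LD loci and matched against the parent's
   library within windows of 64, 32, 16 and 8 LD markers (long to
   short). A candidate matches when it agrees at every *mutually
   observed* constraint locus; the untyped loci take the majority vote of
   all matching candidates, ties broken by library order — the procedure
   is fully deterministic. (Requiring exact matches on fully observed
   windows, or trusting the single first match, measurably hurt accuracy
   on the package's own fixtures; agreement-where-comparable plus voting
   is the package's design choice.) Resolved loci on one parental side
   propagate to the other side through dosage arithmetic at the observed
   LD loci.
3. **Fallbacks.** Segments still open are matched against the pooled
   library of all deduced gametes (population tier, with a stricter
   minimum overlap of 4 comparable loci to limit chance matches);
   anything left takes the parent-expected contribution (0.5 per
   heterozygous parent) or the reference allele frequency, so every
   locus receives a call. Observed LD dosages always override.

Accuracy is scored by `imputationAccuracy()` as the per-SNP Pearson
correlation between true and imputed dosages across validation animals
(SNPs monomorphic in the truth are excluded and counted), with the mean
over SNPs as the headline number, plus the concordance rate and a
per-animal summary. Per-SNP correlation is the primary statistic because
per-locus accuracy maps (including the depressed accuracy near chromosome
ends, where windows lose flanking markers) are the standard diagnostic.

# Cross-validated accuracy and the cost model

`crossValidate()` implements fivefold cross-validation (five replicates
by default): the validation animals' phenotype *records are removed* from
the training data (not set to missing inside group means, which would
leak), the model is refit, and accuracy is computed as

$$ \mathrm{acc} = r(\hat a_{\text{val}}, y_{\text{val}}) / h, $$

with $h$ the square root of the *pedigree-based* heritability, estimated
once on the full data per replicate rather than per fold (fold-wise
re-estimation adds noise to a quantity the design holds fixed).
Non-genotyped phenotyped animals always stay in training — that is the
single-step property being exercised. All methods compared (PBLUP,
ssGBLUP on HD, true-LD or imputed genotypes) share the same fold objects,
so comparisons are paired.

The genotyping cost model prices an HD chip at \$50 and the 3K/1K/0.5K
panels at \$25/\$20/\$10 per sample. Scenario A genotypes parents,
reference population (RP) and selection candidates (SC) all at HD;
scenarios B/C/D genotype parents plus 20% of RP at HD and everyone else
on one LD panel. The HD price falls 10% for each extra 1,000 samples
beyond a base volume of 4,150 — keyed on the non-parent (RP+SC) count,
the convention that reproduces the published \$50 to \$26.6 price range;
parents are counted on top of the RP+SC total because the scenario
definitions list them separately. Both conventions are arguments, not
constants.

# The synthetic-data generator

`simulatePopulation()` produces the study conditions at desk scale. The
defaults describe a commercial tilapia-like nucleus: 50 sires and 100
dams per generation mated two dams per sire into 80 full-sib families per
year-class; family sizes from a truncated normal with mean 18, SD 7,
range 5–49; four offspring year-classes (tests and the acceptance run use
the two-generation subset they state); a 22-chromosome genome summing to
about 1 Gb at 1 cM/Mb; 5,000 SNPs (a deliberate desk-scale stand-in for a
post-QC 32K chip — panel size is a config knob); 500 additive QTL per
trait; and two traits shaped like fillet yield (mean 34.2, SD 2.13,
$h^2$ 0.21, $c^2$ 0.037) and harvest weight (mean 878 g, SD 254 g,
$h^2$ 0.36, $c^2$ 0.068).

Founder haplotypes come from 100 generations of random mating in a base
population of 200, which produces LD decaying with distance without
coalescent machinery; descendants are gene-dropped with Poisson
crossovers. True breeding values are QTL-dosage sums rescaled so the
additive variance matches the target exactly; the common-environment
value is drawn once per family; contemporary-group effects are drawn per
level at 0.25 trait SD; covariates are standard-normal noise with a
0.3-SD slope (the real covariates — harvest weight for fillet yield, age
for harvest weight — are only named in the source material, so generic
covariates exercise the same model structure). The two traits are
simulated independently by default (`trait_cor` exists but no value is
claimed for the real population).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: genotyping error and missingness mechanisms,
ascertainment-shaped MAF spectra, selection during the breeding
generations, sex chromosomes, genotype-by-environment interaction, and
map or assembly errors. Results on simulated data are evidence that the
*algorithms* are correct, not that the real-data numbers would be
reproduced.

```{r example}
library(aquaGS)
cfg <- simulationConfig(n_generations = 1, seed = 101)
pop <- simulatePopulation(cfg)
qc <- qcFilter(pop@genotypes)
design <- mmeDesign(pop@phenotypes, "hw", pop@pedigree,
                    covariate = "hw_cov")
vc <- remlVC(design, makeAInverse(pop@pedigree))
heritability(vc)
```

# Problem sizes and numerical choices

The test suite and the acceptance script run everything at sizes chosen
to keep a full run in minutes while leaving the statistics meaningful:
the imputation check uses the full two-generation default (about 1,600
animals, 5,000 SNPs, 500-SNP panel, five replicates in the acceptance
script); REML parameter recovery uses ~1,300 animals and 400 SNPs;
cross-validation orderings use ~600 genotyped offspring, 1,000 SNPs and a
100-SNP true-LD tier. These are the package's own desk-scale choices;
every one of them is a config argument.

Other fixed numerical choices, all overridable: QC order (sample call
rate, then SNP call rate, MAF, HWE — order changes the per-filter counts,
so it is part of the reported interface), the HWE test as a 1-df
chi-square goodness-of-fit at the printed $p < 10^{-6}$ cutoff,
mean-imputation of missing dosages before building $G$, G blending 0.05
and mean tuning on, REML tolerance $10^{-8}$ with a 200-iteration cap,
window size 20 for GWAS summaries, the imputation window schedule
64/32/16/8 LD markers, and first-in-order tie-breaks wherever a tie is
possible (panel thinning, window votes, top-window ranking).

# Known limitations

* `makeA()` is dense and quadratic in pedigree size; it is intended for
  the genotyped block and desk-scale pedigrees (the sparse
  `makeAInverse()` is the scalable path).
* The REML engine inverts the coefficient matrix densely per iteration;
  fine up to a few thousand equations, not for national-scale data.
* The imputation method is a transparent re-implementation of a
  family-first design, not a reproduction of any specific tool; its
  accuracy on real data with genotyping error is untested by
  construction.
* Single-trait models only; no maternal effects, no multi-trait REML,
  no dominance or epistatic relationship matrices, no metafounders or
  unknown-parent groups.
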