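---
title: "Heterozygosity, heterosis and dominance associations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterozygosity, heterosis and dominance associations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetdom)
```

## The scientific problem

Crossbred cattle outperform the mean of their parental breeds — heterosis —
and the standard adjustment in genetic evaluation is a pedigree-derived
heterosis coefficient. With dense SNP genotypes, heterozygosity can instead be
measured directly on the genome. `hetdom` implements a complete analysis
chain for studying how pedigree-expected and genome-realized heterozygosity
relate to each other and to quantitative traits such as carcass weight,
conformation and fat score, and for locating individual loci whose
*heterozygous* genotype shifts the trait (dominance), not just loci with
allele-dosage (additive) effects.

The chain is: pedigree coefficients → genomic heterozygosity measures →
mixed-model trait association → two-stage additive + dominance genome scan →
LD-based QTL region collapsing. Because suitable cattle datasets are
restricted-access, the package ships a crossbred-population simulator that
generates genotypes, pedigrees and phenotypes with known architecture; every
stage is validated against that known truth and against independent
brute-force oracles.

## Pedigree coefficients

For sire and dam breed fractions $B_{S_i}$, $B_{D_i}$ over breeds $i$:

* heterosis coefficient $= 1 - \sum_i B_{S_i} B_{D_i}$ — the expected
  fraction of loci at which the offspring's two alleles trace to different
  breeds. 0 for a purebred mating, 1 for a fully outcrossed one; symmetric
  in the parents.
* recombination loss (Dickerson) $= 1 - \tfrac12\sum_i (B_{S_i}^2 +
  B_{D_i}^2)$ — the expected breakdown of parental epistatic combinations;
  0 when both parents are purebred, 0.5 when both are F1s.

Recombination loss is binned into seven right-closed classes (0, (0–10]%,
…, (40–50]%, >50%) and enters the association model as a factor.
Compositions are propagated down the pedigree as parent averages; an animal
with a single unknown parent is refused unless a purebred phantom of the
known parent's majority breed is explicitly enabled.

The numerator relationship matrix $A$ is built by the tabular recursion.
Founders are assigned to genetic groups by majority breed (ties broken
lexicographically); group fractions accumulate down the pedigree
(Westell-style), every row of $Q$ summing to one. Rather than modifying the
mixed-model equations, the group fractions enter the model as fixed
covariates — algebraically the same expectation shift
$a \sim N(Qg, A\sigma^2_a)$, but simpler and directly testable.

## Genomic heterozygosity measures

Three per-animal measures, computed from 0/1/2 dosages with missing calls
excluded throughout:

* **OH**, observed heterozygosity: heterozygous calls / called SNPs.
* **HL**, homozygosity by locus: $\sum E_{hom} / (\sum E_{hom} + \sum
  E_{het})$, where $E = 1 - \sum_i q_i^2 = 2q(1-q)$ is the locus's expected
  heterozygosity; homozygosity at an ancestrally variable locus counts for
  more. By default $E$ uses the analyzed cohort's frequencies; external
  frequencies may be supplied. Note HL is a *homozygosity* index, so its
  correlations with heterozygosity measures are strong and negative; their
  magnitudes are what carries information.
* **ROHet**, runs of heterozygosity: a 50-SNP window slides one SNP at a
  time; a window is heterozygous if it has ≤ 2 missing and ≤ 1 homozygous
  calls; a SNP is flagged when more than `snp_in_run_threshold` (default
  0.05) of its covering windows are heterozygous; consecutive flagged SNPs
  (gap ≤ 1 Mb) form candidate runs, kept at ≥ 1 kb span and ≥ 1 SNP per
  50 kb. Runs are summarized as counts, total span, and short
  (≤ 150 kb) / intermediate (151–300 kb) / long (> 300 kb) classes.

Three detector parameters deserve comment. A printed density rule of one
SNP per 50 *bp* is physically impossible for any genotyping array (it would
require 20 SNPs per kb); the package defaults to one SNP per 50 kb, the
common detector default, and the parameter is configurable. The
fraction-of-windows threshold and the maximum gap are not standardized
anywhere; defaults (0.05, 1 Mb) are configurable and logged. Because the
window tolerates missing calls, a missing genotype may sit inside a run the
way a single homozygote may; run *endpoints*, however, are always called
SNPs. An alternative "every covering window must pass" rule is available
via `snp_in_run_threshold = 1 - 1e-9`.

Trait-specific variants recompute OH/HL on a SNP subset (e.g. only
chromosomes carrying dominance hits), and per-animal exclusion sets support
recomputing OH without each animal's own ROHet SNPs.

## Mixed models

Both association stages use one engine: a single-random-effect linear mixed
model $y = X\beta + Zu + e$, $u \sim N(0, K\sigma^2_a)$, fitted by REML.
The variance ratio $\lambda = \sigma^2_a/\sigma^2_e$ is profiled on the
eigendecomposition of $ZKZ'$, making each likelihood evaluation
closed-form; the ratio is optimized by Brent search on $\log\lambda$
(tolerance $10^{-8}$), with $\hat\sigma^2_a = 0$ reported as a boundary
fit. Fixed effects come from GLS at the optimum, random effects from BLUP,
and p-values use a t reference with $n - p$ degrees of freedom.

* **Trait association (pedigree model).** Fixed effects: dam parity
  (1–5+), birth herd type (beef/dairy), twin status, recombination-loss
  class, contemporary group, genetic-group fractions; covariates: the
  heterosis coefficient and/or genomic measures; $K = A$. OH and HL are
  never allowed together — they are near-duplicates and the variance
  inflation factor (VIF $= 1/(1-R^2_j)$, computed for every multi-covariate
  model) explodes. Coefficients are also reported per SD of each measure
  when SDs are supplied, for comparability across measures with different
  ranges.
* **Model comparison.** AIC $= -2\,\mathrm{logL}_{ML} + 2(p + 2)$ uses the
  *ML* likelihood, because the compared models differ in fixed effects and
  REML likelihoods are not comparable across fixed-effect structures. This
  deviates from mixed-model software that prints REML-based AIC; the
  ranking question being asked (which covariate set explains the trait
  best) requires ML.
* **Genome-scan pre-adjustment.** Fixed effects only (contemporary group,
  herd type, parity, twin — no heterozygosity covariate), $K = G$, the
  VanRaden Method I GRM $G = ZZ'/(2\sum p_i(1-p_i))$ with $Z$ the
  frequency-centered dosages and missing dosages mean-imputed at $2p_i$.
  The residuals $e = y - X\hat\beta - \hat u$ carry neither nuisance
  structure nor the additive polygenic background.

## The dominance scan

Per SNP, OLS of the adjusted residuals on an intercept, the additive code
(0/1/2) and the dominance code (heterozygote indicator). With all three
genotype classes present the model is saturated in the class means, so
$b_1 = (\bar e_2 - \bar e_0)/2$ and $b_2 = \bar e_1 - (\bar e_0 + \bar
e_2)/2$; the scan exploits this closed form and runs vectorized over loci
from per-class sufficient statistics. Animals missing a call are dropped
from that locus only. Loci with two genotype classes get an additive-only
fit ($b_2$ not estimable, flagged NA); monomorphic loci are fully NA and
excluded from the FDR family.

Additive and dominance p-value families are separately converted to Storey
q-values: $\hat\pi_0$ from the tail estimator on the grid
$\lambda = 0, 0.05, \ldots, 0.90$ with a df-3 smoothing-spline
extrapolation, then $q_{(i)} = \min_{t \ge p_{(i)}} \hat\pi_0 m t / \#\{p
\le t\}$; with $\hat\pi_0 = 1$ this is exactly Benjamini–Hochberg, which is
the cross-check used in the tests. Significance is declared at
$q \le 0.01$ (1% FDR). The genomic inflation factor $\lambda_{GC} =
\mathrm{median}(\chi^2_1)/0.4549$ is reported per family. On iid residuals
the scan is exactly calibrated; on residuals from the GRM pre-adjustment
$\lambda_{GC}$ runs somewhat *below* 1 at small cohort sizes — the
well-known conservatism of two-stage residual (GRAMMAR-type) association
testing, strongest when relatedness is high.

## QTL regions

Each significant SNP anchors a candidate region containing every
same-chromosome SNP within ±0.5 Mb whose genotypic LD with the anchor
($r^2$, squared Pearson correlation of dosages over jointly called
animals) is ≥ 0.5. The "0.5 Mb window" wording is ambiguous between a
half-width and a total span; the half-width reading is the default and the
total-span reading is a flag. Overlapping candidates merge transitively;
LD is always computed against anchors, never chained through partners. The
lead SNP is the significant member with the smallest p (ties: smaller
position, then id). Regions are 1-based closed intervals internally and
convert to 0-based half-open on BED export.

## The synthetic population

The simulator emulates the data-generating features the analysis relies on,
at desk scale:

* **Breed divergence.** Founder allele frequencies follow a
  Balding–Nichols model around shared ancestral frequencies
  ($F_{ST} = 0.2$ by default, the upper range of divergence among European
  cattle breeds), plus two 60-SNP "divergence islands" per chromosome where
  breeds sit near fixation for alternating alleles — a stand-in for the
  strongly differentiated haplotype blocks around selected loci. The
  islands matter: runs of heterozygosity require *locally contiguous*
  divergence, which independent-locus drift essentially never produces, and
  without segregating runs the ROHet measure would be degenerate in every
  simulated cohort.
* **Maps.** Each simulated chromosome is a compressed autosome: 400 SNPs
  over 4 Mb of physical coordinates (≈ 10 kb spacing, high-density-array
  like, so the run detector's density rule is meaningful) with 1 Morgan of
  genetic length, so chromosomes recombine and assort like real ones.
  Gametes get Poisson crossover counts (no interference) with uniform
  breakpoints; founder haplotype alleles are Bernoulli(breed frequency).
* **Cohorts.** `sim_crossbred()` mixes purebred matings (heterosis 0), F1s
  (1), F2s and backcrosses (0.5) and three-way crosses (1, recombination
  loss 0.25), giving the coefficient spread the pedigree analysis needs.
  The default cohort is 120 animals from 48 founders.
* **Phenotypes.** Trait = intercept + dam parity + herd type + twin +
  recombination-class effects + sparse additive and dominance QTL + a
  polygenic value + $N(0, \sigma^2_e)$ noise. The polygene is gene-dropped
  down the pedigree (parent average plus Mendelian sampling), independent
  of the markers, so planted marker QTL and the polygenic background are
  separable in recovery tests. Founder breeds carry polygenic means (SD 1
  residual unit by default): breeds genuinely differ in genetic merit, and
  this between-breed component is precisely what the genetic groups of the
  pedigree model and the breed-composition structure of the GRM exist to
  absorb — without it the GRM pre-adjustment has nothing to adjust and its
  variance component collapses. The within-breed polygenic SD is derived
  from `h2_poly` against the realized QTL variance plus residual variance.
  Contemporary groups are block-randomized labels of configurable size;
  the real grouping algorithm (herd × slaughter window × sex) is
  proprietary, so only its role as a nuisance factor is emulated.

What the simulator does *not* emulate — within-breed linkage
disequilibrium, genotyping and imputation error, selection, non-random
mating, sex chromosomes — bounds what passing tests show: they validate the
statistical machinery under the stated generative model, not robustness to
every artifact of real data.

## Validation scales and numerical choices

The test suite validates, at these problem sizes (chosen as the smallest
that give stable Monte Carlo behavior):

* formula oracles (heterosis, recombination loss, OH, HL, expected
  heterozygosity, GRM, per-locus OLS, BH q-values) to ≤ 1e-10 on
  randomized instances;
* the run detector against a naive enumerate-all-windows oracle on 200
  random chromosomes across five parameter settings, exactly;
* REML against a dense direct-formula likelihood oracle to 1e-8, and mean
  $\hat h^2$ within ±0.03 of a true 0.4 over 200 cohorts of n = 500,
  m = 2000;
* scan calibration on 20 null cohorts (n = 1000, m = 5000): dominance
  type-I error within ±0.01 of 0.05 and $\lambda_{GC} \in [0.95, 1.05]$;
  a planted one-residual-SD dominance QTL reaching $q \le 0.01$ in ≥ 90%
  of 50 replicates with unbiased $b_2$;
* heterosis–OH rank correlation positive and exceeding heterosis–ROHet in
  ≥ 90% of 50 crossbred cohorts;
* hand-worked QTL-collapsing cases exactly, and merge idempotence over
  1000 random configurations.

Numerical conventions: dosages count the PLINK A1 allele (logged on read);
coordinates are 1-based closed; MAF filtering removes MAF ≤ threshold
computed on non-missing calls; factor levels observed fewer than twice
merge into the reference with a warning; a 1e-8 diagonal ridge is applied
to a relationship matrix only where a Cholesky factorization requires it.

## Known limitations

Dense-matrix mixed models target cohorts up to a few thousand animals, not
national evaluations. The scan's per-locus OLS ignores residual relatedness
beyond the stage-one adjustment (by design, at the cost of GRAMMAR-type
conservatism). ROHet defaults are tuned to high-density panels; sparse
panels need rescaled density/gap parameters. Gene-context annotation of QTL
regions is out of scope.
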