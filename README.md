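# hetdom

Genomic heterozygosity, heterosis and dominance association analysis for
crossbred populations.

## What this is for

Crossbred livestock outperform the mean of their parental breeds
(heterosis), and routine genetic evaluation adjusts for it with a
pedigree-derived coefficient. Dense SNP genotypes make it possible to
measure heterozygosity on the genome instead, and to ask two questions this
package answers end to end:

1. How do pedigree-expected and genome-realized heterozygosity relate to
   each other and to quantitative traits (e.g. carcass weight,
   conformation and fat in cattle)?
2. Which individual SNPs show *dominance* associations — a trait shift in
   the heterozygote beyond the allele-dosage (additive) effect?

The package is aimed at quantitative geneticists working with crossbred
pedigree + SNP data, and at anyone who needs a tested, desk-scale
implementation of this analysis chain with a simulator for method
validation.

## The models

* **Pedigree coefficients.** Heterosis
  `1 − Σᵢ B_Sᵢ·B_Dᵢ` and Dickerson recombination loss
  `1 − ½·Σᵢ(B_Sᵢ² + B_Dᵢ²)` from sire/dam breed fractions, with the
  recombination-loss 0–6 class binning.
* **Genomic heterozygosity.** Observed heterozygosity (OH); homozygosity
  by locus (HL), weighting each locus by its expected heterozygosity
  `1 − Σ qᵢ²`; and runs of heterozygosity (ROHet) from a 50-SNP sliding
  window (≤ 2 missing, ≤ 1 homozygote per window; ≥ 1 kb span), with
  ≤ 150 kb / 151–300 kb / > 300 kb length classes.
* **Trait association.** `y = Xβ + het·c + a + e`, `a ~ N(Qg, Aσ²ₐ)`:
  fixed dam parity, herd type, twin status, recombination class and
  contemporary group; heterosis/heterozygosity covariates; pedigree NRM
  `A` with breed genetic groups `Q` entering as fixed covariates. REML by
  eigendecomposition + Brent profiling; VIF collinearity checks; ML-based
  AIC for covariate-set comparison.
* **Two-stage dominance scan.** Stage 1 adjusts the trait by fixed effects
  plus a polygenic effect with the VanRaden Method I GRM
  `G = ZZ′ / 2Σpᵢ(1−pᵢ)`; stage 2 regresses the residuals per SNP on
  additive (0/1/2) and dominance (heterozygote = 1) codes,
  `e = 1μ + b₁·a_k + b₂·d_k + ε`, with Storey q-values (separately per
  effect family, significance at q ≤ 0.01) and genomic-control λ.
* **QTL regions.** Significant SNPs collapse with same-chromosome SNPs
  within ±0.5 Mb at `r² ≥ 0.5`; overlapping candidates merge; the lead SNP
  is the smallest-p member.

A gamete-dropping simulator (`breed_model()`, `simulate_founders()`,
`mate()`, `simulate_phenotypes()`, `sim_crossbred()`) generates crossbred
cohorts with known trait architecture for validation. PLINK .bed/.bim/.fam
is the genotype interchange format.

## Worked example

```r
library(hetdom)

sc   <- sim_crossbred(seed = 42)                 # 120 crossbred animals
g    <- as_geno_matrix(sc$pop, animals = sc$cohort)
st   <- locus_stats(g)
prof <- het_profile(g, st)                        # OH, HL, ROHet per animal
het  <- sc$coefficients$heterosis[match(prof$animal_id,
                                        sc$coefficients$animal_id)]

rank_correlation(het, prof$oh)
rank_correlation(het, prof$hl)
rank_correlation(het, prof$rohet_count)
```

prints (cohort of 120 animals, 2,000 SNPs):

```
Spearman het~OH    =  0.70
Spearman het~HL    = -0.69
Spearman het~ROHet =  0.51
```

Pedigree-expected heterozygosity ranks animals much like realized OH does;
HL mirrors it with the opposite sign (it is a homozygosity index); the
ROHet count is a coarser, more weakly related summary. `head(prof)`:

```
  animal_id     oh        hl rohet_count rohet_total_bp
1    pb_001 0.2020 0.7926084           0              0
2    pb_002 0.2145 0.7763796           0              0
3    pb_003 0.2210 0.7648631           0              0
```

(purebred animals: low OH, no heterozygous runs).

## The analysis workflow

`analysis/` contains the numbered drivers that run the full study on a
simulated cohort (500 phenotyped animals, 2,000 SNPs, one planted
dominance QTL), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # cohort: PLINK triplet, pedigree, phenotypes, truth
Rscript analysis/02_coefficients.R    # heterosis, recombination loss + classes
Rscript analysis/03_het_measures.R    # OH / HL / ROHet + Spearman correlations
Rscript analysis/04_associations.R    # mixed-model associations, VIF, AIC
Rscript analysis/05_dominance_scan.R  # GRM adjustment + additive/dominance scan
Rscript analysis/06_qtl_regions.R     # LD collapsing of significant SNPs
```

On the default seed the scan recovers the planted QTL as the single
dominance hit at q ≤ 0.01 and collapses it into one QTL region.

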