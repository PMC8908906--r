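#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Generates a crossbred cattle cohort from four diverged founder breeds
# (purebreds, F1s, F2s, backcrosses and three-way crosses, so pedigree
# heterosis spans 0..1), with a known trait architecture: one planted
# dominance QTL, a polygenic term, fixed effects and residual noise.
# Writes a PLINK triplet plus pedigree, breed-composition, phenotype and
# truth tables under results/sim/.

library(hetdom)

seed <- 20260927
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sc <- sim_crossbred(seed = seed, n_per_breed = 20, n_purebred = 100,
                    n_f1 = 100, n_f2 = 100, n_backcross = 100,
                    n_threeway = 100)
g <- as_geno_matrix(sc$pop, animals = sc$cohort)

# trait architecture: one dominance QTL of 1.2 units at a common SNP
fr <- allele_freqs(g)
qtl_snp <- g$map$snp_id[which(fr$maf > 0.3)[200]]
arch <- trait_architecture(qtl_dom = setNames(1.2, qtl_snp), h2_poly = 0.3,
                           sigma_e = 1)
sim <- simulate_phenotypes(sc$pop, arch, animals = sc$cohort,
                           seed = seed + 1)

write_plink(g, file.path(out, "cohort"))
write.table(sc$pop$pedigree, file.path(out, "pedigree.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
founders <- sc$pop$pedigree$animal_id[is.na(sc$pop$pedigree$sire_id)]
comp <- data.frame(animal_id = founders,
                   sc$pop$comp[founders, , drop = FALSE])
write.table(comp, file.path(out, "founder_breeds.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sim$pheno, file.path(out, "phenotypes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
truth <- sim$truth
truth$qtl_snp <- qtl_snp
truth$qtl_dom_effect <- 1.2
write.table(truth, file.path(out, "truth.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

message(sprintf("cohort: %d animals x %d SNPs; planted dominance QTL at %s (d = 1.2)",
                nrow(g$dosage), ncol(g$dosage), qtl_snp))
message("wrote PLINK triplet + pedigree/phenotype/truth tables to ", out)
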