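#!/usr/bin/env Rscript
# Stage 4: heterozygosity-trait associations (pedigree mixed model).
#
# Regresses the simulated trait on each heterozygosity measure -- the
# pedigree heterosis coefficient, OH, HL and ROHet count -- separately and
# in the admissible combinations, in a mixed model with dam parity, birth
# herd type, twin status, recombination-loss class and contemporary group
# as fixed effects and a polygenic effect with covariance A (pedigree NRM
# with breed genetic groups). Reports coefficients, SD-scaled
# coefficients, VIFs and per-model AIC.

library(hetdom)

ph <- read.delim("results/sim/phenotypes.tsv", stringsAsFactors = FALSE,
                 colClasses = c(dam_parity = "character",
                                twin = "character"))
ph <- filter_small_groups(ph, 5)
ped <- read.delim("results/sim/pedigree.tsv", stringsAsFactors = FALSE)
fb <- read.delim("results/sim/founder_breeds.tsv", stringsAsFactors = FALSE)
comp <- as.matrix(fb[, -1])
rownames(comp) <- fb$animal_id
co <- read.delim("results/coefficients.tsv", stringsAsFactors = FALSE)
prof <- read.delim("results/het_measures.tsv", stringsAsFactors = FALSE)

pm <- build_nrm_with_groups(ped, comp)
meas <- data.frame(animal_id = prof$animal_id, oh = prof$oh, hl = prof$hl,
                   rohet = prof$rohet_count,
                   heterosis = co$heterosis[match(prof$animal_id,
                                                  co$animal_id)])
sds <- vapply(meas[, -1], sd, numeric(1))

combos <- list("heterosis", "oh", "hl", "rohet",
               c("heterosis", "oh"), c("heterosis", "hl"),
               c("heterosis", "rohet"), c("heterosis", "oh", "rohet"),
               c("heterosis", "hl", "rohet"))
rows <- list()
for (cv in combos) {
  res <- suppressWarnings(het_association(ph, meas, cv, pm, sds = sds))
  tab <- res$coefficients
  tab$model <- paste(cv, collapse = "+")
  tab$aic <- res$fit$aic
  tab$vif <- if (is.null(res$vif)) NA else res$vif[tab$term]
  rows[[length(rows) + 1]] <- tab
  message(sprintf("model {%s}: AIC = %.1f", tab$model[1], tab$aic[1]))
  for (i in seq_len(nrow(tab))) {
    message(sprintf("   %-9s  b = %7.3f (SE %.3f)  per-SD = %6.3f  p = %.3g%s",
                    tab$term[i], tab$estimate[i], tab$se[i],
                    tab$estimate_per_sd[i], tab$p[i],
                    ifelse(is.na(tab$vif[i]), "",
                           sprintf("  VIF = %.2f", tab$vif[i]))))
  }
}
out <- do.call(rbind, rows)
write.table(out, "results/associations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("note: OH and HL are never entered together (collinear by design)")
message("wrote results/associations.tsv")
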