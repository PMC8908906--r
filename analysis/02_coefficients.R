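#!/usr/bin/env Rscript
# Stage 2: pedigree-based coefficients.
#
# Computes breed composition, the heterosis coefficient, the Dickerson
# recombination-loss coefficient and its 0-6 class for every pedigree
# animal, from the simulated pedigree and founder breed fractions.

library(hetdom)

ped <- read.delim("results/sim/pedigree.tsv", stringsAsFactors = FALSE)
fb <- read.delim("results/sim/founder_breeds.tsv", stringsAsFactors = FALSE)
comp <- as.matrix(fb[, -1])
rownames(comp) <- fb$animal_id

co <- pedigree_coefficients(ped, comp)
write.table(co, "results/coefficients.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

known <- !is.na(co$heterosis)
message(sprintf("coefficients for %d animals (%d founders skipped)",
                sum(known), sum(!known)))
message("heterosis spread: ",
        paste(names(table(round(co$heterosis[known], 2))), collapse = " / "))
message("recombination-loss classes: ",
        paste(sprintf("%s:%d", names(table(co$rec_class[known])),
                      table(co$rec_class[known])), collapse = "  "))
message("wrote results/coefficients.tsv")
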