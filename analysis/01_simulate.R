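#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Draws the default synthetic cohort -- 91 normal, 158 osteopenic and 117
# osteoporosis samples with two planted osteoporosis subtypes, three
# molecular modalities, genotypes and clinical phenotypes -- and writes it
# in the package's standard on-disk layout. Every later stage reads these
# files; truth.csv is written for the final simulation-study evaluation
# only and no analysis stage reads it.

suppressPackageStartupMessages(library(osteomix))

out <- "results/cohort"
cfg <- sim_config(seed = 20260929)
coh <- generate_cohort(cfg)
write_cohort(coh, out)

cat("cohort written to", out, "\n")
print(coh)
cat("group sizes:", paste(table(coh$truth$group), collapse = " / "), "\n")
cat("osteoporosis subtype sizes:",
    paste(table(coh$truth$subtype), collapse = " / "), "\n")
cat("fracture events:", sum(coh$phenotypes$fracture), "of",
    nrow(coh$phenotypes), "\n")
for (m in names(coh$omics))
  cat(sprintf("%-12s %4d features\n", m, nrow(coh$omics[[m]]$values)))
cat(ncol(coh$genotypes$dosages), "variants\n")
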