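#!/usr/bin/env Rscript
# Stage 2: molecular landscape of the cohort.
#
# Loads the simulated cohort from disk, applies genotype QC, screens each
# modality for features discriminating osteoporosis from the other groups
# (Wilcoxon, raw P < 0.05), quantifies shared information between
# modalities with the RV index, and summarizes group-wise Spearman
# co-expression. Writes per-stage TSV tables under results/landscape/.

suppressPackageStartupMessages(library(osteomix))

ind <- "results/cohort"; out <- "results/landscape"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

omics <- list(
  methylation = read_omics(file.path(ind, "methylation.tsv"), "methylation"),
  metabolite = read_omics(file.path(ind, "metabolite.tsv"), "metabolite"),
  microbiota = read_omics(file.path(ind, "microbiota.tsv"), "microbiota"))
geno <- read_genotypes(file.path(ind, "genotypes.vcf"))
ph <- read_phenotypes(file.path(ind, "phenotypes.csv"))

al <- do.call(align_samples, c(list(ph), unname(omics)))
ph <- al[[1]]; omics <- setNames(al[-1], names(omics))

# genotype QC: call rate >= 95%, MAF >= 5%, exact HWE P >= 1e-5
geno_qc <- filter_snps(geno)
qc <- attr(geno_qc, "qc_report")
write.table(qc, file.path(out, "snp_qc_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("SNP QC: %d of %d variants kept (%s)\n",
            sum(qc$kept), nrow(qc),
            paste(names(table(qc$reason[qc$reason != ""])),
                  table(qc$reason[qc$reason != ""]), collapse = ", ")))

# differential screens: osteoporosis vs others, per modality
grp <- ifelse(ph$group == "osteoporosis", "osteoporosis", "other")
for (m in names(omics)) {
  scr <- wilcoxon_screen(omics[[m]], grp)
  write.table(scr$results, file.path(out, paste0("differential_", m, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-12s discriminative fraction %.3f\n",
              m, scr$discriminative_fraction))
}

# shared information between modalities
rv <- rv_matrix(omics)
write.table(round(rv, 4), file.path(out, "rv_matrix.tsv"), sep = "\t",
            quote = FALSE)
cat("RV index matrix:\n"); print(round(rv, 3))

# co-expression coupling per sample group (metabolites shown as example)
net <- coexpression_network(omics$metabolite, ph$group, edge_threshold = 0.3)
coupling <- data.frame(group = names(net),
                       mean_abs_rho = sapply(net, `[[`, "mean_abs_rho"),
                       n_edges = sapply(net, function(g) nrow(g$edges)))
write.table(coupling, file.path(out, "coexpression_coupling.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(coupling, row.names = FALSE)
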