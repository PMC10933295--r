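#!/usr/bin/env Rscript
# Stage 7: fracture-risk biomarker ranking and composite index.
#
# Ranks clinical indices and methylation features by fracture AUC in the
# ALL population (everyone) and the OP population (osteoporosis only),
# adjusts feature AUCs under the three covariate schemes (age+sex;
# +prior fracture; +FN BMD), and exhaustively screens composite sum-index
# panels (N < 5) over the top OP-population candidates.

suppressPackageStartupMessages(library(osteomix))

ind <- "results/cohort"; out <- "results/fracture"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

me <- read_omics(file.path(ind, "methylation.tsv"), "methylation")
ph <- read_phenotypes(file.path(ind, "phenotypes.csv"))
frac <- ph$fracture
op <- ph$group == "osteoporosis"

# clinical indices first: FN BMD behaves differently in ALL vs OP
clin <- t(as.matrix(ph[, c("fn_bmd", "th_bmd", "l1l4_bmd", "age", "bmi")]))
colnames(clin) <- ph$sample_id
for (popname in c("ALL", "OP")) {
  mask <- if (popname == "ALL") rep(TRUE, length(frac)) else op
  rk_c <- feature_auc_ranking(clin, frac, mask, population = popname)
  rk_m <- feature_auc_ranking(
    omics_matrix(me$values[, mask, drop = FALSE], "methylation"),
    frac[mask], population = popname)
  cat(sprintf("%s population: FN BMD AUC %.3f; %d candidate CpGs (AUC > 0.6)\n",
              popname, rk_c$auc[rk_c$feature_id == "fn_bmd"],
              sum(rk_m$candidate)))
  # covariate-adjusted AUC of the top candidates under the three schemes
  topf <- head(rk_m$feature_id, 12)
  covs <- ph[mask, c("age", "sex", "prior_fracture", "fn_bmd")]
  adj <- t(sapply(topf, function(f) {
    v <- analysis_scale(me)[f, mask]
    sapply(1:3, function(s) adjusted_auc(v, frac[mask], covs, s)$auc)
  }))
  tab <- cbind(rk_m[match(topf, rk_m$feature_id),
                    c("feature_id", "orientation", "auc")],
               auc_adj1 = adj[, 1], auc_adj2 = adj[, 2], auc_adj3 = adj[, 3])
  write.table(tab, file.path(out, paste0("feature_auc_", popname, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

# composite sum-index screening over the top OP-population candidates
rk_op <- feature_auc_ranking(
  omics_matrix(me$values[, op, drop = FALSE], "methylation"),
  frac[op], population = "OP")
cands <- head(rk_op$feature_id, 8)
panels <- composite_screen(
  omics_matrix(me$values[, op, drop = FALSE], "methylation"),
  frac[op], candidates = cands,
  covariates = ph[op, c("age", "sex", "prior_fracture", "fn_bmd")],
  scheme = 3)
write.table(panels, file.path(out, "composite_panels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("best composite panel (OP): %s  AUC %.3f (adjusted %.3f)\n",
            panels$panel[1], panels$auc[1], panels$auc_adjusted[1]))
cat(sprintf("best single member AUC: %.3f\n", rk_op$auc[1]))
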