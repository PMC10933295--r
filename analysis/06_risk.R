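#!/usr/bin/env Rscript
# Stage 6: osteoporosis risk models.
#
# Builds the three nested logistic tiers on a stratified 70/30 split:
# Baseline I (age, BMI, drinking, smoking), Baseline II (+ bone turnover
# markers beta-CTX, OST, PINP) and the M3S model (+ molecular signatures,
# an optimal subset picked by mRMR on the training split only). Reports
# held-out ROC/AUC with DeLong intervals and decision-curve net benefit.

suppressPackageStartupMessages(library(osteomix))

ind <- "results/cohort"; out <- "results/risk"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

omics <- list(
  methylation = read_omics(file.path(ind, "methylation.tsv"), "methylation"),
  metabolite = read_omics(file.path(ind, "metabolite.tsv"), "metabolite"),
  microbiota = read_omics(file.path(ind, "microbiota.tsv"), "microbiota"))
ph <- read_phenotypes(file.path(ind, "phenotypes.csv"))

dat <- data.frame(age = ph$age, bmi = ph$bmi, drinking = ph$drinking,
                  smoking = ph$smoking, ctx = ph$ctx, ost = ph$ost,
                  pinp = ph$pinp,
                  outcome = as.integer(ph$group == "osteoporosis"))
feats <- do.call(rbind, lapply(omics, analysis_scale))
dat <- cbind(dat, as.data.frame(t(feats)))

evals <- list()
for (tier in c("baseline1", "baseline2", "m3s")) {
  spec <- risk_model_spec(tier, m3s_features = rownames(feats), n_m3s = 5,
                          seed = 17)
  ev <- suppressWarnings(train_eval(spec, dat))
  evals[[tier]] <- ev
  cat(sprintf("%-10s test AUC %.3f (95%% CI %.3f-%.3f)\n", tier,
              ev$test_auc$auc, ev$test_auc$ci[1], ev$test_auc$ci[2]))
  write.table(ev$roc, file.path(out, paste0("roc_", tier, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ev$decision_curve,
              file.path(out, paste0("decision_curve_", tier, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("M3S features selected by mRMR:",
    paste(evals$m3s$selected_m3s, collapse = ", "), "\n")

jsonlite::write_json(
  lapply(evals, function(e) list(
    tier = e$tier,
    train_auc = e$train_auc$auc, test_auc = e$test_auc$auc,
    test_auc_ci = e$test_auc$ci, selected_m3s = e$selected_m3s,
    coefficients = as.list(e$model$coefficients))),
  file.path(out, "evaluation.json"), auto_unbox = TRUE, digits = NA)
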