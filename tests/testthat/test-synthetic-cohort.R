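test_that("cohort matches the configured group sizes and subtype structure", {
  coh <- fixture_cohort()
  expect_identical(as.integer(table(coh$truth$group)[c("normal", "osteopenia",
                                                       "osteoporosis")]),
                   c(91L, 158L, 117L))
  expect_identical(length(coh$truth$sample_id), 366L)
  # subtypes exist only inside the osteoporosis group
  expect_true(all(is.na(coh$truth$subtype[coh$truth$group != "osteoporosis"])))
  expect_setequal(unique(na.omit(coh$truth$subtype)), c("S1", "S2"))
  # shared sample ordering across every component
  expect_identical(colnames(coh$omics$methylation$values),
                   coh$truth$sample_id)
  expect_identical(rownames(coh$genotypes$dosages), coh$truth$sample_id)
  expect_identical(coh$phenotypes$sample_id, coh$truth$sample_id)
})

test_that("value semantics invariants hold on generated data", {
  coh <- fixture_cohort()
  expect_true(all(coh$omics$methylation$values >= 0 &
                    coh$omics$methylation$values <= 1))
  expect_lt(max(abs(colSums(coh$omics$microbiota$values) - 1)), 1e-9)
  expect_true(all(coh$omics$metabolite$values > 0))
})

test_that("identical configs give bit-identical cohorts", {
  a <- generate_cohort(sim_config(seed = 42))
  b <- generate_cohort(sim_config(seed = 42))
  expect_identical(a$omics$methylation$values, b$omics$methylation$values)
  expect_identical(a$omics$microbiota$values, b$omics$microbiota$values)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$phenotypes$fracture, b$phenotypes$fracture)
  c2 <- generate_cohort(sim_config(seed = 43))
  expect_false(identical(a$omics$methylation$values,
                         c2$omics$methylation$values))
})

test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(n_normal = 0), "positive")
  expect_error(sim_config(effect_size = -1), "non-negative")
  expect_error(sim_config(subtype_fraction = 1), "subtype_fraction")
  expect_error(sim_config(maf_range = c(0, 0.4)), "maf_range")
  expect_error(sim_config(rho_pos = 1.2), "rho")
})

test_that("subtype phenotype contrast: S1 lower at hip, higher at spine", {
  coh <- fixture_cohort()
  st <- coh$truth$subtype
  ph <- coh$phenotypes
  expect_lt(mean(ph$fn_bmd[which(st == "S1")]),
            mean(ph$fn_bmd[which(st == "S2")]))
  expect_lt(mean(ph$th_bmd[which(st == "S1")]),
            mean(ph$th_bmd[which(st == "S2")]))
  expect_gt(mean(ph$l1l4_bmd[which(st == "S1")]),
            mean(ph$l1l4_bmd[which(st == "S2")]))
})

test_that("null configuration produces no signal beyond chance", {
  cfg <- sim_config(effect_size = 0,
                    n_group_signature = c(methylation = 0, metabolite = 0,
                                          microbiota = 0),
                    n_fracture_features = c(methylation = 0, metabolite = 0,
                                            microbiota = 0),
                    n_features = c(methylation = 1000, metabolite = 600,
                                   microbiota = 400),
                    rewiring_pairs = 0, n_qtl_effects = 0, seed = 5)
  coh <- generate_cohort(cfg)
  grp <- ifelse(coh$truth$group == "osteoporosis", "op", "rest")
  scr <- wilcoxon_screen(coh$omics$methylation, grp)
  # discriminative fraction near alpha, and BH-corrected survivors near zero
  expect_lt(abs(scr$discriminative_fraction - 0.05), 0.02)
  expect_lte(sum(scr$results$q_value < 0.05), 2)
})

test_that("planted subtype signatures pass the Wilcoxon screen", {
  coh <- fixture_cohort()  # effect 1.5, ~58 samples per subtype
  st <- coh$truth$subtype
  op <- !is.na(st)
  hit <- numeric(0)
  for (m in names(coh$omics)) {
    sig <- coh$truth$signatures
    planted <- sig$feature_id[sig$modality == m & sig$kind == "subtype"]
    scr <- wilcoxon_screen(
      omics_matrix(coh$omics[[m]]$values[, op, drop = FALSE],
                   coh$omics[[m]]$modality), st[op])
    hit <- c(hit, scr$results$p_value[match(planted,
                                            scr$results$feature_id)] < 0.05)
  }
  expect_gte(mean(hit), 0.9)
})

test_that("genotypes follow Hardy-Weinberg proportions", {
  g <- generate_genotypes(10000, 30, c(0.449, 0.4499), seed = 9)
  het <- mean(g$dosages == 1)
  # expected 2*maf*(1-maf) ~ 0.4949 at maf ~ 0.45
  expect_lt(abs(het - 2 * 0.45 * 0.55), 0.015)
  expect_error(generate_genotypes(10, 0, c(0.1, 0.2), seed = 1), "n_variants")
  expect_error(generate_genotypes(10, 5, c(0, 0.5), seed = 1), "maf_range")
})

test_that("planted strong QTL is recovered by the scan at P < 1e-5", {
  cfg <- sim_config(n_qtl_effects = 3, qtl_beta = 1.0,
                    geno_missing_rate = 0, seed = 12)
  coh <- generate_cohort(cfg)
  qtl <- coh$truth$qtl
  found <- logical(nrow(qtl))
  for (i in seq_len(nrow(qtl))) {
    m <- qtl$modality[i]
    sc <- qtl_scan(
      genotype_matrix(coh$genotypes$dosages[, qtl$variant[i], drop = FALSE],
                      coh$genotypes$variants[
                        coh$genotypes$variants$id == qtl$variant[i], ]),
      coh$omics[[m]])
    row <- sc$scan[sc$scan$feature_id == qtl$feature_id[i], ]
    found[i] <- nrow(row) == 1 && row$p_value < 1e-5
  }
  expect_true(all(found))
})

test_that("plant_rewiring hits the target correlations and preserves nulls", {
  set.seed(2)
  n <- 140
  st <- rep(c("S1", "S2"), each = n / 2)
  mk <- function(p, mod) {
    v <- matrix(exp(rnorm(p * n)), p, n,
                dimnames = list(paste0(mod, 1:p), paste0("s", 1:n)))
    omics_matrix(v, "metabolite")
  }
  om <- list(metabolite = mk(6, "met"), microbiota = local({
    x <- matrix(exp(rnorm(5 * n)), 5, n,
                dimnames = list(paste0("tax", 1:5), paste0("s", 1:n)))
    omics_matrix(sweep(x, 2, colSums(x), "/"), "microbiota")
  }))
  pairs <- data.frame(modality_a = "microbiota", feature_a = "tax1",
                      modality_b = "metabolite", feature_b = "met1")
  out <- plant_rewiring(om, st, pairs, rho_pos = 0.6, rho_neg = -0.6,
                        seed = 33)
  a <- analysis_scale(out$microbiota); b <- analysis_scale(out$metabolite)
  r1 <- cor(a["tax1", st == "S1"], b["met1", st == "S1"], method = "spearman")
  r2 <- cor(a["tax1", st == "S2"], b["met1", st == "S2"], method = "spearman")
  expect_gt(r1, 0.35); expect_lt(r2, -0.35)
  # marginals preserved up to the simplex re-closure
  expect_equal(unname(sort(out$metabolite$values["met1", st == "S1"])),
               unname(sort(om$metabolite$values["met1", st == "S1"])))
  # empty pair list is the identity
  same <- plant_rewiring(om, st, pairs[0, ], 0.6, -0.6, seed = 1)
  expect_identical(same$metabolite$values, om$metabolite$values)
  expect_error(plant_rewiring(om, st, pairs, 1.0, -0.6, seed = 1), "rho")
  badp <- pairs; badp$feature_b <- "nope"
  expect_error(plant_rewiring(om, st, badp, 0.6, -0.6, seed = 1), "unknown")
})

test_that("fracture outcomes follow the logistic model", {
  coh <- fixture_cohort()
  ph <- as.data.frame(coh$phenotypes)
  ph$fracture <- NULL
  ph <- phenotype_table(ph)
  # zero coefficients: marginal rate equals the intercept probability
  null_model <- list(intercept = qlogis(0.1), subtype2 = 0, fn_bmd = 0,
                     prior_fracture = 0)
  rates <- replicate(20, {
    out <- generate_fracture_outcomes(ph, coh$truth, null_model,
                                      seed = sample.int(1e6, 1))
    mean(out$fracture)
  })
  expect_lt(abs(mean(rates) - 0.1), 0.015)
  # positive subtype-2 coefficient raises the subtype-2 rate
  mod <- list(intercept = qlogis(0.1), subtype2 = 1.5, fn_bmd = 0,
              prior_fracture = 0)
  big <- coh$truth
  out <- generate_fracture_outcomes(ph, big, mod, seed = 77)
  st <- big$subtype
  expect_gt(mean(out$fracture[which(st == "S2")]),
            mean(out$fracture[which(st == "S1")]))
  # determinism
  o1 <- generate_fracture_outcomes(ph, big, mod, seed = 5)
  o2 <- generate_fracture_outcomes(ph, big, mod, seed = 5)
  expect_identical(o1$fracture, o2$fracture)
  ph_bad <- ph; ph_bad$fn_bmd <- NULL
  expect_error(generate_fracture_outcomes(ph_bad, big, mod, 1), "fn_bmd")
})
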