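test_that("feature AUC ranking orients every feature above one half", {
  set.seed(61)
  n <- 120
  frac <- rbinom(n, 1, 0.25)
  feats <- rbind(
    protective = rnorm(n) - 1.2 * frac,   # low values risky, like BMD
    risky = rnorm(n) + 1.2 * frac,
    noise = rnorm(n))
  colnames(feats) <- paste0("s", 1:n)
  rk <- feature_auc_ranking(feats, frac)
  expect_true(all(rk$auc >= 0.5))
  expect_identical(rk$orientation[rk$feature_id == "protective"], -1)
  expect_identical(rk$orientation[rk$feature_id == "risky"], 1)
  expect_false(rk$candidate[rk$feature_id == "noise"])
  expect_true(all(diff(rk$auc) <= 0))
  expect_error(feature_auc_ranking(feats, rep(1, n)), "single-class")
})

test_that("per-feature AUC equals the pairwise oracle on a 12-sample toy", {
  set.seed(62)
  v <- matrix(rnorm(24), 2, 12, dimnames = list(c("a", "b"), NULL))
  lab <- rep(c(0, 1), 6)
  rk <- feature_auc_ranking(v, lab)
  for (f in c("a", "b")) {
    o <- oracle_auc(v[f, ], lab)
    expect_equal(rk$auc[rk$feature_id == f], max(o, 1 - o), tolerance = 1e-12)
  }
})

test_that("covariate adjustment removes exactly the explained signal", {
  set.seed(63)
  n <- 800
  cov <- data.frame(age = rnorm(n, 65, 8), sex = rbinom(n, 1, 0.5),
                    prior_fracture = rbinom(n, 1, 0.2),
                    fn_bmd = rnorm(n, 0.7, 0.08))
  frac <- rbinom(n, 1, plogis(-1.4 + 1.0 * scale(cov$age)[, 1]))
  # feature that is a pure covariate readout: adjusted AUC collapses to 0.5
  f_cov <- 2 * cov$age + 0.5 * cov$sex
  a1 <- adjusted_auc(f_cov, frac, cov, scheme = 1)
  raw1 <- feature_auc_ranking(matrix(f_cov, 1), frac)$auc
  expect_gt(raw1, 0.6)
  expect_lt(abs(a1$auc - 0.5), 0.05)
  # feature orthogonal to covariates keeps its AUC
  f_ind <- rnorm(n) + 1.0 * frac
  a2 <- adjusted_auc(f_ind, frac, cov, scheme = 3)
  raw2 <- feature_auc_ranking(matrix(f_ind, 1), frac)$auc
  expect_lt(abs(a2$auc - raw2), 0.05)
  # mixture lands strictly between, matching the explicit projection oracle
  f_mix <- 3 * scale(cov$age)[, 1] + (rnorm(n) + 1.0 * frac)
  a3 <- adjusted_auc(f_mix, frac, cov, scheme = 2)
  X <- cbind(1, cov$age, cov$sex, cov$prior_fracture)
  res_oracle <- f_mix - X %*% solve(t(X) %*% X, t(X) %*% f_mix)
  o <- oracle_auc(res_oracle, frac)
  expect_equal(a3$auc, max(o, 1 - o), tolerance = 1e-10)
  raw3 <- feature_auc_ranking(matrix(f_mix, 1), frac)$auc
  expect_lt(a3$auc, raw3)
  expect_gt(a3$auc, 0.5)
  expect_error(adjusted_auc(f_mix, frac, cov["age"], scheme = 2), "missing")
  expect_error(adjusted_auc(f_mix, frac, cov, scheme = 9), "scheme")
})

test_that("composite screening enumerates exactly the sub-5 panels", {
  set.seed(64)
  n <- 80
  frac <- rbinom(n, 1, 0.3)
  v <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("cg", 1:5), paste0("s", 1:n)))
  v[1, ] <- v[1, ] + frac; v[2, ] <- v[2, ] - 0.8 * frac
  panels <- composite_screen(v, frac)
  expect_equal(nrow(panels), choose(5, 1) + choose(5, 2) + choose(5, 3) +
                 choose(5, 4))
  expect_true(all(panels$size < 5))
  expect_true(all(panels$auc >= 0.5))
})

test_that("composite screening matches an independent exhaustive oracle", {
  set.seed(65)
  n <- 60
  frac <- rbinom(n, 1, 0.35)
  v <- matrix(rnorm(6 * n), 6, n,
              dimnames = list(paste0("cg", 1:6), paste0("s", 1:n)))
  v[1, ] <- v[1, ] + 0.9 * frac
  v[3, ] <- v[3, ] - 0.9 * frac
  panels <- composite_screen(v, frac)
  # oracle: enumerate all subsets independently with its own scoring path
  orient <- sapply(rownames(v), function(f) {
    if (oracle_auc(v[f, ], frac) >= 0.5) 1 else -1
  })
  zs <- t(sapply(rownames(v), function(f)
    as.numeric(scale(orient[f] * v[f, ]))))
  best_auc <- 0; best_panel <- NULL
  for (size in 1:4) for (s in combn(rownames(v), size, simplify = FALSE)) {
    sc <- colSums(zs[s, , drop = FALSE])
    a <- oracle_auc(sc, frac); a <- max(a, 1 - a)
    if (a > best_auc) { best_auc <- a; best_panel <- s }
  }
  expect_equal(panels$auc[1], best_auc, tolerance = 1e-12)
  expect_identical(panels$panel[1], paste(best_panel, collapse = "+"))
  # invariant to candidate input order
  panels_rev <- composite_screen(v[6:1, ], frac)
  expect_identical(panels$panel, panels_rev$panel)
  expect_equal(panels$auc, panels_rev$auc)
})

test_that("fracture signal planted in omics is BMD-independent in OP", {
  cfg <- sim_config(fracture_model = list(intercept = qlogis(0.15),
                                          subtype2 = 0, fn_bmd = 0,
                                          prior_fracture = 0),
                    fracture_effect = 1.3, seed = 71)
  coh <- generate_cohort(cfg)
  op <- coh$truth$group == "osteoporosis"
  frac <- coh$phenotypes$fracture
  bmd_auc <- feature_auc_ranking(matrix(coh$phenotypes$fn_bmd[op], 1,
                                        dimnames = list("fn_bmd", NULL)),
                                 frac[op])$auc
  expect_lt(bmd_auc, 0.62)
  planted <- coh$truth$signatures
  planted <- planted[planted$kind == "fracture" &
                       planted$modality == "methylation", ]
  rk <- feature_auc_ranking(
    omics_matrix(coh$omics$methylation$values[, op, drop = FALSE],
                 "methylation"), frac[op], population = "OP")
  planted_auc <- rk$auc[match(planted$feature_id, rk$feature_id)]
  expect_gt(mean(planted_auc > 0.6), 0.7)
})

test_that("published signature panels load from the shipped fixtures", {
  cpgs <- published_fracture_panel()
  expect_length(cpgs, 4)
  expect_true(all(grepl("^cg", cpgs)))
  op <- published_m3s_panel("osteoporosis")
  expect_equal(nrow(op), 5)
  st <- published_m3s_panel("subtype")
  expect_equal(nrow(st), 16)
  expect_true("Klebsiella" %in% op$feature_id)
})
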