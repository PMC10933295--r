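test_that("association matrices match the rank-then-Pearson oracle", {
  set.seed(24)
  x <- matrix(rnorm(4 * 40), 4, 40, dimnames = list(paste0("a", 1:4), NULL))
  y <- matrix(rnorm(4 * 40), 4, 40, dimnames = list(paste0("b", 1:4), NULL))
  am <- association_matrix(x, y)
  or <- oracle_spearman(x, y)
  expect_equal(unname(am$rho), or$rho, tolerance = 1e-12)
  expect_equal(unname(am$p), or$p, tolerance = 1e-10)
  # monotone transform of matched rows gives rho = 1 on the diagonal
  am2 <- association_matrix(x, exp(x))
  expect_equal(unname(diag(am2$rho)), rep(1, 4))
  expect_error(association_matrix(x[, 1:4], y[, 1:4]), "fewer than 5")
  # constant feature in stratum flagged missing
  x3 <- x; x3[2, ] <- 5
  am3 <- association_matrix(x3, y)
  expect_true(all(is.na(am3$rho[2, ])))
})

test_that("Fisher-z rewiring statistic follows its closed form", {
  mk <- function(rho, n, lab) structure(
    list(rho = matrix(rho, 1, 1, dimnames = list("f", "g")),
         p = matrix(0.5, 1, 1), n_stratum = n, stratum = lab),
    class = "association_matrix")
  d0 <- differential_association(mk(0.4, 50, "a"), mk(0.4, 60, "b"))
  expect_equal(d0$z, 0); expect_equal(d0$p_rewire, 1)
  d1 <- differential_association(mk(0.5, 50, "a"), mk(-0.5, 50, "b"))
  expect_equal(d1$z, (atanh(0.5) - atanh(-0.5)) / sqrt(2 / 47),
               tolerance = 1e-12)
  expect_equal(round(d1$z, 2), 5.33)
  expect_true(d1$sign_flip)
  # antisymmetry under stratum exchange
  d2 <- differential_association(mk(-0.5, 50, "b"), mk(0.5, 50, "a"))
  expect_equal(d1$delta, -d2$delta)
  expect_equal(d1$p_rewire, d2$p_rewire)
  expect_error(differential_association(mk(0.1, 3, "a"), mk(0.1, 50, "b")),
               "n <= 3")
})

test_that("rewiring p-values are uniform under a no-rewiring null", {
  set.seed(25)
  n <- 50
  x <- matrix(rnorm(45 * n), 45, n, dimnames = list(paste0("a", 1:45), NULL))
  y <- matrix(rnorm(45 * n), 45, n, dimnames = list(paste0("b", 1:45), NULL))
  a1 <- association_matrix(x[, 1:25], y[, 1:25], stratum_label = "s1")
  a2 <- association_matrix(x[, 26:50], y[, 26:50], stratum_label = "s2")
  d <- differential_association(a1, a2)
  expect_gte(nrow(d), 2000)
  ks <- suppressWarnings(ks.test(d$p_rewire, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted sign-flip pairs are recovered at BH-FDR 0.05", {
  set.seed(26)
  n_per <- 60
  st <- rep(c("S1", "S2"), each = n_per)
  p <- 30
  mk <- function(prefix) matrix(rnorm(p * 2 * n_per), p,
                                dimnames = list(paste0(prefix, 1:p),
                                                paste0("s", 1:(2 * n_per))))
  A <- mk("tax"); B <- mk("met")
  omA <- omics_matrix(exp(A), "metabolite", feature_ids = rownames(A))
  omB <- omics_matrix(exp(B), "metabolite", feature_ids = rownames(B))
  pairs <- data.frame(modality_a = "A", feature_a = paste0("tax", 1:10),
                      modality_b = "B", feature_b = paste0("met", 1:10))
  om <- plant_rewiring(list(A = omA, B = omB), st, pairs,
                       rho_pos = 0.6, rho_neg = -0.6, seed = 9)
  a1 <- association_matrix(om$A, om$B, st == "S1", "S1")
  a2 <- association_matrix(om$A, om$B, st == "S2", "S2")
  d <- differential_association(a1, a2)
  d$planted <- paste(d$row_feature, d$col_feature) %in%
    paste(pairs$feature_a, pairs$feature_b)
  sens <- mean(d$q_rewire[d$planted] < 0.05)
  expect_gte(sens, 0.8)
  fp <- sum(d$q_rewire < 0.05 & !d$planted)
  expect_lte(fp, ceiling(0.15 * sum(d$q_rewire < 0.05)))
})

test_that("stemness-like weights find the dominant reference feature", {
  set.seed(27)
  n <- 40; p <- 12
  base <- matrix(rnorm(p * n, sd = 1), p, n,
                 dimnames = list(paste0("f", 1:p), paste0("s", 1:n)))
  ref <- paste0("s", 1:20)
  base[1, 1:20] <- base[1, 1:20] + 3   # f1 defines the reference stratum
  sw <- stemness_like_weights(base, ref)
  expect_equal(sw$ranking[1], "f1")
  # reference samples score above anti-correlated ones
  expect_gt(mean(sw$index[1:20]), mean(sw$index[21:40]))
  # determinism and scale invariance of the rank-based index
  sw2 <- stemness_like_weights(base, ref)
  expect_identical(sw$weights, sw2$weights)
  scaled <- base; scaled[3, ] <- scaled[3, ] * 100
  sw3 <- stemness_like_weights(scaled, ref)
  expect_equal(unname(sw3$index), unname(sw$index), tolerance = 1e-12)
  expect_error(stemness_like_weights(base, ref[1:3]), ">= 5")
})

test_that("M3S selection intersects weights with the differential screen", {
  set.seed(28)
  w <- c(a = 0.9, b = -0.7, c = 0.5, d = 0.1, e = 0.05)
  scr <- list(results = data.frame(
    feature_id = names(w),
    significant = c(TRUE, FALSE, TRUE, TRUE, FALSE)))
  m3s <- select_m3s(list(met = w), list(met = scr), top_q = 3)
  expect_identical(m3s$feature_id, c("a", "c"))
  expect_identical(m3s$rank, 1:2)
  # q = all features: exactly the significant ones
  m3s_all <- select_m3s(list(met = w), list(met = scr), top_q = 5)
  expect_setequal(m3s_all$feature_id, c("a", "c", "d"))
  # empty intersection falls back to top-q by weight with a warning
  scr0 <- list(results = data.frame(feature_id = names(w),
                                    significant = FALSE))
  expect_warning(fb <- select_m3s(list(met = w), list(met = scr0), top_q = 2),
                 "falling back")
  expect_identical(fb$feature_id, c("a", "b"))
})

test_that("planted subtype signatures dominate the selected M3S", {
  coh <- fixture_cohort()
  st <- coh$truth$subtype
  op <- !is.na(st)
  hits <- 0; planted_n <- 0
  for (m in names(coh$omics)) {
    sub <- omics_matrix(coh$omics[[m]]$values[, op, drop = FALSE],
                        coh$omics[[m]]$modality)
    scr <- wilcoxon_screen(sub, st[op])
    sw <- stemness_like_weights(sub, which(st[op] == "S1"))
    planted <- coh$truth$signatures
    planted <- planted$feature_id[planted$modality == m &
                                    planted$kind == "subtype"]
    m3s <- select_m3s(setNames(list(sw$weights), m),
                      setNames(list(scr), m), top_q = 2 * length(planted))
    hits <- hits + sum(planted %in% m3s$feature_id)
    planted_n <- planted_n + length(planted)
  }
  expect_gte(hits / planted_n, 0.8)
})
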