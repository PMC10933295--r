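make_geno <- function(dos) {
  genotype_matrix(dos, data.frame(id = colnames(dos), chrom = "chr1",
                                  pos = seq_len(ncol(dos)) * 1000,
                                  ref = "A", alt = "G"))
}

test_that("qtl_scan beta and se equal the normal-equations oracle", {
  set.seed(41)
  n <- 45
  dos <- cbind(v1 = rbinom(n, 2, 0.3), v2 = rbinom(n, 2, 0.4))
  rownames(dos) <- paste0("s", 1:n)
  g <- make_geno(dos)
  covar <- cbind(age = rnorm(n, 60, 8), sex = rbinom(n, 1, 0.5))
  y <- matrix(rnorm(3 * n), 3, n,
              dimnames = list(paste0("m", 1:3), rownames(dos)))
  sc <- qtl_scan(g, y, covariates = covar)
  for (j in 1:2) for (i in 1:3) {
    or <- oracle_ols(y[i, ], cbind(dos[, j], 1, covar))
    row <- sc$scan[sc$scan$variant == colnames(dos)[j] &
                     sc$scan$feature_id == rownames(y)[i], ]
    expect_equal(row$beta, unname(or["beta"]), tolerance = 1e-8)
    expect_equal(row$se, unname(or["se"]), tolerance = 1e-8)
  }
})

test_that("qtl_scan handles perfect fits, missingness and degeneracies", {
  set.seed(42)
  n <- 60
  dos <- cbind(v1 = rbinom(n, 2, 0.4), mono = rep(1, n),
               vmiss = ifelse(runif(n) < 0.1, NA, rbinom(n, 2, 0.3)))
  rownames(dos) <- paste0("s", 1:n)
  g <- make_geno(dos)
  y <- rbind(perfect = dos[, "v1"], noise = rnorm(n))
  colnames(y) <- rownames(dos)
  sc <- qtl_scan(g, y)
  hit <- sc$scan[sc$scan$variant == "v1" & sc$scan$feature_id == "perfect", ]
  expect_equal(hit$beta, 1, tolerance = 1e-10)
  expect_lt(hit$p_value, 1e-50)
  expect_false("mono" %in% sc$scan$variant)
  expect_equal(unique(sc$scan$n[sc$scan$variant == "vmiss"]),
               sum(!is.na(dos[, "vmiss"])))
  # collinear covariates are rejected
  cc <- cbind(a = rnorm(n), b = rnorm(n))
  cc <- cbind(cc, c = cc[, 1] + cc[, 2])
  expect_error(qtl_scan(g, y, covariates = cc), "collinear")
  expect_error(qtl_scan(make_geno(dos[1:10, , drop = FALSE]),
                        y[, 1:10]), "fewer than 20")
})

test_that("scan results are invariant to sample order and covariate scaling", {
  set.seed(43)
  n <- 50
  dos <- cbind(v = rbinom(n, 2, 0.35)); rownames(dos) <- paste0("s", 1:n)
  y <- matrix(rnorm(n), 1, n, dimnames = list("m", rownames(dos)))
  covar <- cbind(age = rnorm(n, 60, 9))
  base <- qtl_scan(make_geno(dos), y, covar)$scan
  perm <- sample(n)
  permuted <- qtl_scan(make_geno(dos[perm, , drop = FALSE]),
                       y[, perm, drop = FALSE], covar[perm, , drop = FALSE])$scan
  expect_equal(base$beta, permuted$beta, tolerance = 1e-10)
  expect_equal(base$p_value, permuted$p_value, tolerance = 1e-10)
  rescaled <- qtl_scan(make_geno(dos), y, covar * 100 + 3)$scan
  expect_equal(base$beta, rescaled$beta, tolerance = 1e-10)
  expect_equal(base$p_value, rescaled$p_value, tolerance = 1e-10)
})

test_that("global chi-squared screen matches closed forms", {
  # printed 2x2 table [[10,20],[20,10]]: chi2 = 6.667, p ~ 0.0098
  dos <- cbind(v = rep(c(0, 1, 0, 1), c(10, 20, 20, 10)))
  rownames(dos) <- paste0("s", 1:60)
  g <- make_geno(dos)
  grp <- rep(c("a", "b"), each = 30)
  res <- global_snp_test(g, grp)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(res$p_value, pchisq(20 / 3, 1, lower.tail = FALSE),
               tolerance = 1e-10)
  # identical distributions: p near 1
  dos2 <- cbind(v = rep(c(0, 1, 2, 0, 1, 2), each = 10))
  rownames(dos2) <- paste0("s", 1:60)
  res2 <- global_snp_test(make_geno(dos2), grp)
  expect_gt(res2$p_value, 0.99)
  expect_error(global_snp_test(g, rep("a", 60)), "2 groups")
})

test_that("sparse genotype classes are pooled before the chi-squared test", {
  set.seed(44)
  dos <- cbind(v = c(rep(0, 50), rep(1, 8), rep(2, 2)))
  rownames(dos) <- paste0("s", 1:60)
  res <- global_snp_test(make_geno(dos), rep(c("a", "b"), 30))
  expect_true(res$pooled)
  expect_equal(res$df, 1)
})

test_that("snpGene annotation respects half-open coordinates and flanks", {
  iv <- gene_intervals(data.frame(
    chrom = c("chr1", "chr1", "chr1"),
    start = c(100, 120, 1000), end = c(200, 160, 1200),
    gene_id = c("G1", "G1", "G2"),
    feature_class = c("gene", "exon", "gene")))
  vars <- data.frame(id = c("rA", "rB", "rC", "rD", "rE"),
                     chrom = "chr1",
                     pos = c(101, 100, 130, 995, 5000))
  ann <- annotate_snp_genes(vars, iv, flank_bp = 0)
  expect_true("rA" %in% ann$map$variant)          # pos 101 inside [100,200)
  expect_false("rB" %in% ann$map$variant)         # pos 100: 0-based 99 < 100
  expect_identical(ann$map$variant_class[ann$map$variant == "rC"], "exonic")
  expect_identical(ann$map$variant_class[ann$map$variant == "rA"], "intronic")
  expect_false("rD" %in% ann$map$variant)
  # a 10 bp flank pulls rD in as intergenic-neighbouring
  ann2 <- annotate_snp_genes(vars, iv, flank_bp = 10)
  expect_identical(ann2$map$variant_class[ann2$map$variant == "rD"],
                   "intergenic")
  expect_error(annotate_snp_genes(data.frame(id = "x", chrom = "chrX",
                                             pos = 5), iv), "chrX")
})

test_that("snpGene set comparison computes Jaccard overlaps", {
  out <- compare_snpgene_sets(list(a = c("A", "B", "C"),
                                   b = c("B", "C", "D")))
  expect_equal(out$jaccard["a", "b"], 0.5)
  expect_identical(out$shared, c("B", "C"))
  expect_identical(out$specific$a, "A")
  same <- compare_snpgene_sets(list(x = c("A", "B"), y = c("A", "B")))
  expect_equal(same$jaccard["x", "y"], 1)
  disj <- compare_snpgene_sets(list(x = "A", y = "B"))
  expect_equal(disj$jaccard["x", "y"], 0)
  expect_warning(compare_snpgene_sets(list(x = "A", y = character(0))),
                 "empty")
})

test_that("genotype PCs capture planted population structure", {
  set.seed(45)
  n <- 80
  popl <- rep(0:1, each = n / 2)
  dos <- sapply(1:50, function(j) {
    f <- runif(1, 0.1, 0.4) + 0.25 * popl
    rbinom(n, 2, f)
  })
  rownames(dos) <- paste0("s", 1:n)
  colnames(dos) <- paste0("v", 1:50)
  g <- genotype_matrix(dos, data.frame(id = colnames(dos), chrom = "chr1",
                                       pos = 1:50, ref = "A", alt = "T"))
  pcs <- genotype_pcs(g, 4)
  expect_identical(dim(pcs), c(80L, 4L))
  expect_gt(abs(cor(pcs[, 1], popl)), 0.8)
})
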