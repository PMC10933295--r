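# Molecular-landscape statistics: per-feature Wilcoxon differential screens,
# Spearman co-expression networks per sample group, and the RV coefficient
# measuring information shared between modalities.

# Analysis-scale transform for a modality: methylation beta -> logit
# (M-value-like), metabolite -> log, microbiota -> centred log-ratio.
#' Map an omics matrix onto its analysis scale
#'
#' Methylation beta values are logit-transformed (after clamping away from
#' exact 0/1), metabolite abundances log-transformed, and microbiota
#' relative abundances CLR-transformed.
#'
#' @param x an [omics_matrix()].
#' @return numeric matrix, features x samples.
#' @export
analysis_scale <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  v <- x$values
  switch(x$value_semantics,
         beta01 = logit(pmin(pmax(v, 1e-6), 1 - 1e-6)),
         positive_abundance = log(pmax(v, min(v[v > 0]) / 2)),
         relative_abundance = clr_transform(v))
}

#' Two-group Wilcoxon rank-sum test
#'
#' Exact p-value when both groups have at most 25 samples and the data are
#' untied; normal approximation with tie correction otherwise (the behaviour
#' of [stats::wilcox.test()], with the exact cutoff made explicit).
#'
#' @param x,y numeric vectors for the two groups.
#' @return list with `p_value`, `statistic` (rank-sum W) and `direction`
#'   (sign of the median shift of `x` relative to `y`).
#' @export
wilcoxon_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("wilcoxon_test: each group needs at least 2 samples")
  if (length(unique(c(x, y))) == 1L)
    return(list(p_value = 1, statistic = length(x) * length(y) / 2,
                direction = 0))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 25 && length(y) <= 25
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       direction = sign(median(x) - median(y)))
}

#' Per-feature Wilcoxon differential screen
#'
#' Tests every feature of a modality between two sample groups and reports
#' the fraction of features discriminative at the raw threshold `alpha`
#' (no multiplicity correction, matching the screening convention the
#' downstream analyses assume); Benjamini-Hochberg q-values are attached
#' for reference.
#'
#' @param x an [omics_matrix()] or numeric feature x sample matrix.
#' @param groups vector over samples with exactly two non-empty levels.
#' @param alpha significance threshold on the raw p-value.
#' @param transform apply the modality's analysis-scale transform first
#'   (rank tests are invariant to it feature-wise; kept for interface
#'   symmetry with other stages).
#' @return list with `results` (data.frame: feature_id, statistic, p_value,
#'   q_value, direction, significant) and `discriminative_fraction`.
#' @export
wilcoxon_screen <- function(x, groups, alpha = 0.05, transform = FALSE) {
  v <- if (inherits(x, "omics_matrix")) {
    if (transform) analysis_scale(x) else x$values
  } else as.matrix(x)
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2) stop("wilcoxon_screen: need exactly two groups")
  g1 <- groups == levels(groups)[1]
  if (sum(g1) < 2 || sum(!g1) < 2)
    stop("wilcoxon_screen: each group needs at least 2 samples")
  res <- t(apply(v, 1L, function(f) {
    wt <- wilcoxon_test(f[g1], f[!g1])
    c(wt$statistic, wt$p_value, wt$direction)
  }))
  out <- data.frame(feature_id = rownames(v), statistic = res[, 1],
                    p_value = res[, 2],
                    q_value = p.adjust(res[, 2], "BH"),
                    direction = res[, 3],
                    significant = res[, 2] < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(results = out,
       discriminative_fraction = mean(out$significant),
       contrast = paste(levels(groups), collapse = " vs "))
}

#' RV coefficient between two multivariate datasets
#'
#' Matrix-level correlation RV = tr(XX'YY') / sqrt(tr((XX')^2) tr((YY')^2))
#' on column-centred data; lies in [0, 1], equals 1 for any orthogonal
#' rotation of the same configuration.
#'
#' @param x,y numeric sample x feature matrices over the same samples.
#' @return scalar RV coefficient.
#' @export
rv_coefficient <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("rv_coefficient: sample counts differ")
  x <- sweep(x, 2L, colMeans(x)); y <- sweep(y, 2L, colMeans(y))
  if (all(x == 0) || all(y == 0)) stop("rv_coefficient: zero-variance matrix")
  sx <- tcrossprod(x); sy <- tcrossprod(y)
  sum(sx * sy) / sqrt(sum(sx * sx) * sum(sy * sy))
}

#' Pairwise RV coefficients between modalities
#'
#' @param omics named list of [omics_matrix()] objects over shared samples;
#'   each is moved to its analysis scale first.
#' @return symmetric matrix of RV coefficients.
#' @export
rv_matrix <- function(omics) {
  mats <- lapply(omics, function(o) t(analysis_scale(o)))
  k <- length(mats)
  out <- matrix(1, k, k, dimnames = list(names(omics), names(omics)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    out[i, j] <- out[j, i] <- rv_coefficient(mats[[i]], mats[[j]])
  out
}

# Spearman correlation matrix between rows of x (and optionally rows of y)
# with asymptotic t-approximation p-values.
spearman_matrix <- function(x, y = NULL, n = ncol(x)) {
  rx <- t(apply(x, 1L, rank))
  if (is.null(y)) {
    rho <- cor(t(rx))
  } else {
    ry <- t(apply(y, 1L, rank))
    rho <- cor(t(rx), t(ry))
  }
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 1e-15))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1] <- 0
  list(rho = rho, p = p, n = n)
}

#' Per-group Spearman co-expression network
#'
#' Computes the feature-feature Spearman correlation matrix within each
#' sample group and thresholds |rho| to define edges. Constant features are
#' excluded with a warning. Relative-abundance matrices are CLR-transformed
#' first (ranks of the other modalities are transform-invariant).
#'
#' @param x an [omics_matrix()] or numeric matrix.
#' @param groups vector over samples.
#' @param edge_threshold minimum |rho| for an edge.
#' @return named list per group: `rho` matrix, `edges` data.frame
#'   (feature_a, feature_b, rho), `mean_abs_rho`.
#' @export
coexpression_network <- function(x, groups, edge_threshold = 0.3) {
  v <- if (inherits(x, "omics_matrix")) analysis_scale(x) else as.matrix(x)
  groups <- as.character(groups)
  out <- list()
  for (g in unique(groups)) {
    vg <- v[, groups == g, drop = FALSE]
    if (ncol(vg) < 3) stop("coexpression_network: group '", g,
                           "' has fewer than 3 samples")
    const <- apply(vg, 1L, function(r) length(unique(r)) == 1L)
    if (any(const)) {
      warning("coexpression_network: dropping constant feature(s) in group '",
              g, "': ", paste(head(rownames(vg)[const], 3), collapse = ", "))
      vg <- vg[!const, , drop = FALSE]
    }
    sm <- spearman_matrix(vg)
    rho <- sm$rho
    ut <- which(upper.tri(rho) & abs(rho) >= edge_threshold, arr.ind = TRUE)
    out[[g]] <- list(
      rho = rho,
      edges = data.frame(feature_a = rownames(rho)[ut[, 1]],
                         feature_b = colnames(rho)[ut[, 2]],
                         rho = rho[ut], stringsAsFactors = FALSE),
      mean_abs_rho = mean(abs(rho[upper.tri(rho)])))
  }
  out
}
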