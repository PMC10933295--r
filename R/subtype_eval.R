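# Cluster-quality evaluation: balance, phenotype-association counts,
# resampling stability, and cross-method label comparison.

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected clustering agreement (contingency-table closed form,
#' delegated to \pkg{mclust}); invariant to label permutation.
#'
#' @param a,b label vectors of equal length.
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

#' Normalized-entropy balance of a clustering
#'
#' H(cluster proportions) / log(k): 1 for equal cluster sizes, tending to 0
#' as one cluster absorbs everything.
#'
#' @param labels cluster labels (>= 2 distinct values).
#' @return balance in (0, 1].
#' @export
balance_index <- function(labels) {
  p <- table(labels) / length(labels)
  k <- length(p)
  if (k < 2) stop("balance_index: need at least 2 clusters")
  -sum(p * log(p)) / log(k)
}

#' Count clinical phenotypes associated with a clustering
#'
#' Continuous phenotypes are tested with a Wilcoxon rank-sum test when
#' k = 2 and Kruskal-Wallis otherwise; binary/categorical phenotypes with a
#' chi-squared test (no continuity correction). Constant phenotypes are
#' skipped with a warning. Raw p-values are compared to `alpha` with no
#' multiplicity correction (the count criterion the subtype evaluation
#' uses); BH q-values are reported alongside.
#'
#' @param labels cluster labels over samples.
#' @param phenotypes a [phenotype_table()] (or data.frame) in the same
#'   sample order.
#' @param pheno_cols columns to test; defaults to every column except
#'   `sample_id` and `group`.
#' @param alpha significance threshold.
#' @return list: `table` (phenotype, test, p_value, q_value, significant)
#'   and `count`.
#' @export
phenotype_association_count <- function(labels, phenotypes, pheno_cols = NULL,
                                        alpha = 0.05) {
  df <- as.data.frame(phenotypes)
  if (is.null(pheno_cols))
    pheno_cols <- setdiff(names(df), c("sample_id", "group"))
  stopifnot(length(labels) == nrow(df))
  k <- length(unique(labels))
  rows <- lapply(pheno_cols, function(cl) {
    v <- df[[cl]]
    if (length(unique(v[!is.na(v)])) < 2) {
      warning("phenotype_association_count: '", cl, "' is constant; skipped")
      return(NULL)
    }
    binary_like <- is.factor(v) || is.character(v) ||
      all(v[!is.na(v)] %in% c(0, 1))
    if (binary_like) {
      tab <- table(labels, v)
      p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
      test <- "chisq"
    } else if (k == 2) {
      sp <- split(v, labels)
      p <- wilcoxon_test(sp[[1]], sp[[2]])$p_value
      test <- "wilcoxon"
    } else {
      p <- kruskal.test(v, factor(labels))$p.value
      test <- "kruskal"
    }
    data.frame(phenotype = cl, test = test, p_value = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) return(list(table = NULL, count = 0L))
  tab$q_value <- p.adjust(tab$p_value, "BH")
  tab$significant <- tab$p_value < alpha
  list(table = tab, count = sum(tab$significant))
}

#' Resampling stability of DLSF clustering
#'
#' Re-runs the full clustering on random sample subsets and reports the
#' mean pairwise ARI over the samples each pair of resamples shares.
#'
#' @param omics named list of [omics_matrix()] objects (aligned samples).
#' @param config a [dlsf_config()].
#' @param k cluster count used on every resample.
#' @param n_resamples number of subsets (>= 2).
#' @param subsample_fraction fraction of samples per subset.
#' @param seed seed for subset draws.
#' @return list: `mean_ari`, `sd_ari`, `pairwise` (vector of pairwise
#'   ARIs), `labelings`.
#' @export
stability <- function(omics, config, k, n_resamples = 10,
                      subsample_fraction = 0.8, seed = 1L) {
  stopifnot(n_resamples >= 2)
  n <- ncol(omics[[1]]$values %||% omics[[1]])
  m <- floor(subsample_fraction * n)
  if (m <= k) stop("stability: subsample too small for k")
  ids <- colnames(if (inherits(omics[[1]], "omics_matrix"))
    omics[[1]]$values else omics[[1]])
  labelings <- vector("list", n_resamples)
  for (r in seq_len(n_resamples)) {
    keep <- with_seed(substream_seed(seed, paste0("resample", r)),
                      sort(sample.int(n, m)))
    sub <- lapply(omics, function(o)
      if (inherits(o, "omics_matrix")) subset_samples(o, ids[keep])
      else o[, keep, drop = FALSE])
    cfg <- config; cfg$seed <- config$seed + r
    fit <- train_dlsf(sub, cfg)
    S <- fuse_affinities(fit$C)
    rownames(S$S) <- colnames(S$S) <- ids[keep]
    asg <- spectral_cluster(S, k, seed = cfg$seed)
    labelings[[r]] <- setNames(asg$labels, ids[keep])
  }
  prs <- combn(n_resamples, 2)
  pw <- apply(prs, 2L, function(ij) {
    a <- labelings[[ij[1]]]; b <- labelings[[ij[2]]]
    shared <- intersect(names(a), names(b))
    adjusted_rand_index(a[shared], b[shared])
  })
  list(mean_ari = mean(pw), sd_ari = sd(pw), pairwise = pw,
       labelings = labelings)
}

#' Compare several labelings of the same samples
#'
#' @param labelings named list of label vectors over identical samples.
#' @param phenotypes optional [phenotype_table()] for association counts.
#' @param alpha association threshold.
#' @return list: `report` (labeling, k, balance, n_associated) and
#'   `pairwise_ari` matrix.
#' @export
compare_labelings <- function(labelings, phenotypes = NULL, alpha = 0.05) {
  stopifnot(length(labelings) >= 2)
  ns <- vapply(labelings, length, integer(1))
  if (length(unique(ns)) != 1) stop("compare_labelings: sample mismatch")
  report <- do.call(rbind, lapply(names(labelings), function(nm) {
    lab <- labelings[[nm]]
    data.frame(labeling = nm, k = length(unique(lab)),
               balance = if (length(unique(lab)) >= 2)
                 balance_index(lab) else NA_real_,
               n_associated = if (!is.null(phenotypes))
                 phenotype_association_count(lab, phenotypes,
                                             alpha = alpha)$count
               else NA_integer_,
               stringsAsFactors = FALSE)
  }))
  m <- length(labelings)
  ari <- matrix(1, m, m, dimnames = list(names(labelings), names(labelings)))
  for (i in seq_len(m - 1)) for (j in (i + 1):m)
    ari[i, j] <- ari[j, i] <- adjusted_rand_index(labelings[[i]],
                                                  labelings[[j]])
  list(report = report, pairwise_ari = ari)
}
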