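# Genotype-molecular phenotype association: additive-model OLS xQTL scans,
# group-wise chi-squared screens for global snpGenes, and interval-based
# snpGene annotation.

#' Top principal components of a dosage matrix
#'
#' Missing calls are mean-imputed (for the PCA only) and variants are
#' standardized before the decomposition.
#'
#' @param genotypes a [genotype_matrix()].
#' @param n_pcs number of components.
#' @return samples x n_pcs score matrix.
#' @export
genotype_pcs <- function(genotypes, n_pcs = 8) {
  d <- genotypes$dosages
  for (j in seq_len(ncol(d))) {
    mj <- mean(d[, j], na.rm = TRUE)
    d[is.na(d[, j]), j] <- mj
  }
  sds <- apply(d, 2L, sd)
  d <- d[, sds > 0, drop = FALSE]
  n_pcs <- min(n_pcs, ncol(d) - 1, nrow(d) - 1)
  pc <- prcomp(d, center = TRUE, scale. = TRUE)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  rownames(scores) <- rownames(genotypes$dosages)
  scores
}

#' Molecular QTL scan (additive linear model)
#'
#' For every (variant, feature) pair within a stratum, fits ordinary least
#' squares of the analysis-scale molecular feature on the dosage plus
#' covariates and reports the Wald p-value of the dosage coefficient.
#' Samples with a missing dosage are dropped pairwise; variants monomorphic
#' within the stratum are skipped.
#'
#' @param genotypes a [genotype_matrix()].
#' @param molecular an [omics_matrix()] or feature x sample matrix over the
#'   same samples (analysis-scale transform applied to omics matrices).
#' @param covariates numeric sample x covariate matrix (or NULL); an
#'   intercept is always included. Must be full rank.
#' @param stratum_mask logical/id/index vector selecting stratum samples
#'   (>= 20 required).
#' @param p_threshold hit threshold on the dosage p-value.
#' @param stratum label stored with the hits.
#' @return list: `hits` (data.frame of pairs with p < threshold), `scan`
#'   (all pairs: variant, feature, beta, se, p_value, n), `n_tests`.
#' @export
qtl_scan <- function(genotypes, molecular, covariates = NULL,
                     stratum_mask = NULL, p_threshold = 1e-5,
                     stratum = "all") {
  v <- if (inherits(molecular, "omics_matrix")) analysis_scale(molecular)
       else as.matrix(molecular)
  dos <- genotypes$dosages
  stopifnot(nrow(dos) == ncol(v))
  if (!is.null(stratum_mask)) {
    dos <- dos[stratum_mask, , drop = FALSE]
    v <- v[, stratum_mask, drop = FALSE]
    if (!is.null(covariates)) covariates <- covariates[stratum_mask, ,
                                                       drop = FALSE]
  }
  n <- nrow(dos)
  if (n < 20) stop("qtl_scan: stratum has fewer than 20 samples")
  X0 <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (qr(X0)$rank < ncol(X0)) stop("qtl_scan: collinear covariates")
  rows <- vector("list", ncol(dos))
  mod <- if (inherits(molecular, "omics_matrix")) molecular$modality else NA
  for (j in seq_len(ncol(dos))) {
    g <- dos[, j]
    ok <- !is.na(g)
    gg <- g[ok]
    if (length(unique(gg)) < 2) next        # monomorphic in stratum
    Xj <- cbind(dosage = gg, X0[ok, , drop = FALSE])
    nj <- sum(ok)
    dfres <- nj - ncol(Xj)
    if (dfres < 1) next
    qrX <- qr(Xj)
    if (qrX$rank < ncol(Xj)) next
    XtXinv11 <- chol2inv(qr.R(qrX))[1, 1]
    B <- qr.coef(qrX, t(v[, ok, drop = FALSE]))   # coef x features
    res <- qr.resid(qrX, t(v[, ok, drop = FALSE]))
    sigma2 <- colSums(res^2) / dfres
    beta <- B["dosage", ]
    se <- sqrt(sigma2 * XtXinv11)
    tt <- beta / se
    p <- 2 * pt(abs(tt), df = dfres, lower.tail = FALSE)
    rows[[j]] <- data.frame(variant = colnames(dos)[j],
                            feature_id = rownames(v), modality = mod,
                            beta = beta, se = se, p_value = p, n = nj,
                            stratum = stratum, stringsAsFactors = FALSE,
                            row.names = NULL)
  }
  scan <- do.call(rbind, rows)
  hits <- scan[!is.na(scan$p_value) & scan$p_value < p_threshold, ,
               drop = FALSE]
  list(hits = hits, scan = scan,
       n_tests = if (is.null(scan)) 0L else nrow(scan))
}

#' Per-variant chi-squared test of genotype distribution across groups
#'
#' Builds the genotype-count x group contingency table per variant and
#' applies the chi-squared test without continuity correction; the
#' homozygous-alternate class is pooled into the heterozygote class when
#' any expected cell falls below 5.
#'
#' @param genotypes a [genotype_matrix()].
#' @param group_labels vector over samples with >= 2 levels.
#' @return data.frame: variant, statistic, df, p_value, pooled.
#' @export
global_snp_test <- function(genotypes, group_labels) {
  g <- factor(as.character(group_labels))
  if (nlevels(g) < 2) stop("global_snp_test: need >= 2 groups")
  d <- genotypes$dosages
  stopifnot(nrow(d) == length(g))
  rows <- lapply(seq_len(ncol(d)), function(j) {
    v <- d[, j]; ok <- !is.na(v)
    tab <- table(factor(v[ok], levels = 0:2), droplevels(g[ok]))
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    pooled <- FALSE
    if (nrow(tab) >= 2 && ncol(tab) >= 2) {
      expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expd < 5) && nrow(tab) == 3) {
        tab <- rbind(tab[1, , drop = FALSE], tab[2, ] + tab[3, ])
        pooled <- TRUE
      }
    }
    if (nrow(tab) < 2 || ncol(tab) < 2)
      return(data.frame(variant = colnames(d)[j], statistic = NA_real_,
                        df = NA_real_, p_value = NA_real_, pooled = pooled))
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    data.frame(variant = colnames(d)[j],
               statistic = unname(ct$statistic), df = unname(ct$parameter),
               p_value = ct$p.value, pooled = pooled,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Annotate variants to genes by interval overlap
#'
#' A variant maps to a gene when its 0-based position falls inside the
#' gene's BED interval extended by `flank_bp` on both sides (half-open
#' arithmetic: pos-1 in [start - flank, end + flank)). Variants inside an
#' exon record are classed `exonic`, inside a gene but no exon `intronic`,
#' otherwise `intergenic`; a variant overlapping several genes keeps all of
#' them.
#'
#' @param variants data.frame with `id`, `chrom`, `pos` (1-based) -- e.g. a
#'   genotype matrix's `variants` element, usually restricted to the
#'   significant ones.
#' @param intervals a [gene_intervals()] set.
#' @param flank_bp symmetric flank in base pairs.
#' @return list of class `snpgene_set`: `genes` (character), `map`
#'   (variant, gene_id, variant_class), `class_tally`.
#' @export
annotate_snp_genes <- function(variants, intervals, flank_bp = 10000) {
  stopifnot(flank_bp >= 0)
  miss <- setdiff(unique(variants$chrom), unique(intervals$chrom))
  if (length(miss) > 0)
    stop("annotate_snp_genes: chromosome(s) absent from intervals: ",
         paste(miss, collapse = ", "))
  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  gene_iv <- intervals[intervals$feature_class != "exon", , drop = FALSE]
  exon_iv <- intervals[intervals$feature_class == "exon", , drop = FALSE]
  as_gr <- function(df, flank) {
    if (nrow(df) == 0)
      return(GenomicRanges::GRanges())
    # BED [start, end) 0-based -> 1-based closed [start+1, end], +- flank
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(pmax(df$start + 1 - flank, 1),
                                            df$end + flank),
                           gene_id = df$gene_id)
  }
  gg <- as_gr(gene_iv, flank_bp)
  eg <- as_gr(exon_iv, 0)
  ov <- GenomicRanges::findOverlaps(vr, gg)
  map <- data.frame(variant = variants$id[S4Vectors::queryHits(ov)],
                    gene_id = gg$gene_id[S4Vectors::subjectHits(ov)],
                    stringsAsFactors = FALSE)
  map <- unique(map)
  inexon <- rep(FALSE, nrow(map))
  if (length(eg) > 0 && nrow(map) > 0) {
    ove <- GenomicRanges::findOverlaps(
      vr[match(map$variant, variants$id)], eg)
    hit_gene <- eg$gene_id[S4Vectors::subjectHits(ove)]
    for (k in seq_along(S4Vectors::queryHits(ove))) {
      i <- S4Vectors::queryHits(ove)[k]
      if (map$gene_id[i] == hit_gene[k]) inexon[i] <- TRUE
    }
  }
  # exonic > intronic > intergenic; intergenic = flank-only (outside the
  # gene body proper)
  body <- as_gr(gene_iv, 0)
  inbody <- rep(FALSE, nrow(map))
  if (nrow(map) > 0) {
    ovb <- GenomicRanges::findOverlaps(vr[match(map$variant, variants$id)],
                                       body)
    bg <- body$gene_id[S4Vectors::subjectHits(ovb)]
    for (k in seq_along(S4Vectors::queryHits(ovb))) {
      i <- S4Vectors::queryHits(ovb)[k]
      if (map$gene_id[i] == bg[k]) inbody[i] <- TRUE
    }
  }
  map$variant_class <- ifelse(inexon, "exonic",
                              ifelse(inbody, "intronic", "intergenic"))
  structure(list(genes = sort(unique(map$gene_id)), map = map,
                 class_tally = table(factor(map$variant_class,
                                            c("exonic", "intronic",
                                              "intergenic")))),
            class = "snpgene_set")
}

#' Overlap report across snpGene sets
#'
#' @param sets named list of [annotate_snp_genes()] results (or plain gene
#'   id vectors).
#' @return list: `jaccard` matrix, `shared` (genes in every set),
#'   `specific` (per-set private genes), `sizes`.
#' @export
compare_snpgene_sets <- function(sets) {
  stopifnot(length(sets) >= 2)
  genes <- lapply(sets, function(s) if (inherits(s, "snpgene_set")) s$genes
                  else unique(as.character(s)))
  if (any(lengths(genes) == 0))
    warning("compare_snpgene_sets: empty set included")
  m <- length(genes)
  jac <- matrix(1, m, m, dimnames = list(names(genes), names(genes)))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    u <- length(union(genes[[i]], genes[[j]]))
    jac[i, j] <- jac[j, i] <- if (u == 0) 0 else
      length(intersect(genes[[i]], genes[[j]])) / u
  }
  all_shared <- Reduce(intersect, genes)
  specific <- lapply(seq_len(m), function(i)
    setdiff(genes[[i]], Reduce(union, genes[-i])))
  names(specific) <- names(genes)
  list(jaccard = jac, shared = all_shared, specific = specific,
       sizes = lengths(genes))
}
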