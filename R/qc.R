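# Genotype quality control: call rate, minor allele frequency and an exact
# Hardy-Weinberg equilibrium test.

#' SNP quality-control thresholds
#'
#' Defaults follow common array QC practice: variants are kept when call
#' rate >= 95\%, MAF >= 5\% and the exact Hardy-Weinberg p-value >= 1e-5.
#'
#' @param min_call_rate,min_maf,hwe_p_floor thresholds in (0,1).
#' @return a list of class `snp_qc_thresholds`.
#' @export
snp_qc_thresholds <- function(min_call_rate = 0.95, min_maf = 0.05,
                              hwe_p_floor = 1e-5) {
  stopifnot(min_call_rate > 0, min_call_rate < 1,
            min_maf > 0, min_maf < 1, hwe_p_floor > 0, hwe_p_floor < 1)
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_p_floor = hwe_p_floor), class = "snp_qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional on the observed allele counts, enumerates every possible
#' heterozygote count of the same parity and returns the two-sided exact
#' p-value: the summed probability of all configurations no more likely
#' than the observed one. Probabilities are computed by the standard
#' recurrence over heterozygote counts, which is numerically stable for
#' the sample sizes genotyping panels reach.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return exact two-sided p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0)) stop("hwe_exact_test: negative counts")
  if (any(counts != round(counts))) stop("hwe_exact_test: non-integer counts")
  n <- sum(counts)
  if (n < 1) stop("hwe_exact_test: empty sample")
  n_a <- 2 * n_hom_alt + n_het           # minor-or-not, either allele works
  n_b <- 2 * n_hom_ref + n_het
  rare <- min(n_a, n_b)
  if (rare == 0) return(1.0)
  hets <- seq(rare %% 2, rare, by = 2)   # feasible heterozygote counts
  # Recurrence: P(h+2)/P(h) = 4 * n_ra(h) * n_ca(h) / ((h+2)*(h+1)) where
  # n_ra, n_ca are the two homozygote counts implied by h.
  logp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    hom_r <- (rare - h) / 2
    hom_c <- (n_a + n_b - rare - h) / 2  # larger-allele homozygotes
    logp[k] <- logp[k - 1] +
      log(4 * hom_r * hom_c) - log((h + 2) * (h + 1))
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_het)
  if (length(obs) == 0L) stop("hwe_exact_test: impossible heterozygote count")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Variant-level genotype QC filter
#'
#' Keeps a variant iff its call rate, minor allele frequency (computed on
#' non-missing calls) and exact Hardy-Weinberg p-value all clear the
#' configured thresholds. Filtering is idempotent.
#'
#' @param genotypes a [genotype_matrix()].
#' @param thresholds a [snp_qc_thresholds()].
#' @return the filtered [genotype_matrix()]; attribute `qc_report` holds a
#'   per-variant data.frame (call_rate, maf, hwe_p, kept, reason).
#' @export
filter_snps <- function(genotypes, thresholds = snp_qc_thresholds()) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  d <- genotypes$dosages
  if (ncol(d) < 1) stop("filter_snps: no variants")
  call_rate <- colMeans(!is.na(d))
  maf <- apply(d, 2L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    f <- mean(v) / 2
    min(f, 1 - f)
  })
  hwe_p <- apply(d, 2L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_real_)
    hwe_exact_test(sum(v == 0), sum(v == 1), sum(v == 2))
  })
  reason <- character(ncol(d))
  reason[!is.na(call_rate) & call_rate < thresholds$min_call_rate] <- "call_rate"
  need <- reason == ""
  reason[need & (is.na(maf) | maf < thresholds$min_maf)] <- "maf"
  need <- reason == ""
  reason[need & (is.na(hwe_p) | hwe_p < thresholds$hwe_p_floor)] <- "hwe"
  kept <- reason == ""
  report <- data.frame(variant = colnames(d), call_rate = call_rate,
                       maf = maf, hwe_p = hwe_p, kept = kept,
                       reason = ifelse(kept, "", reason),
                       stringsAsFactors = FALSE, row.names = NULL)
  if (!any(kept)) warning("filter_snps: all variants excluded")
  out <- genotype_matrix(d[, kept, drop = FALSE],
                         genotypes$variants[kept, , drop = FALSE])
  attr(out, "qc_report") <- report
  out
}
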