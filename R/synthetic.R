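# Synthetic multi-omics osteoporosis cohort generator.
#
# The generator draws per-modality Gaussian latent matrices, plants group-
# and subtype-level mean shifts, genotype->feature effects and fracture-
# associated features on that latent (analysis) scale, then pushes each
# modality through its natural observation transform: inverse-logit for
# methylation beta values, exponential for metabolite abundances, and a
# logistic-normal closure for microbiota relative abundances. Sign-flip
# correlation rewiring between subtypes is planted afterwards through a
# Gaussian-copula quantile remap that preserves each feature's marginal.

#' Simulation configuration for a synthetic osteoporosis cohort
#'
#' Defaults mirror the cohort shape the analyses are designed around:
#' 91 normal, 158 osteopenic and 117 osteoporosis samples, two osteoporosis
#' subtypes of roughly equal size whose molecular signal is split across
#' three modalities, and a logistic fracture model in which subtype 2,
#' low femoral-neck BMD and prior fracture raise risk.
#'
#' @param n_normal,n_osteopenia,n_osteoporosis group sizes.
#' @param subtype_fraction proportion of osteoporosis samples in subtype 1.
#' @param n_features named integer vector: features per modality.
#' @param n_signature named integer vector: subtype-signature features per
#'   modality (mean shift `effect_size` between subtypes on the transformed
#'   scale).
#' @param effect_size standardized subtype mean shift in z-units; must be
#'   non-negative.
#' @param n_group_signature,group_effect features per modality shifted
#'   between the osteoporosis group and the rest, and their z-shift.
#' @param n_fracture_features,fracture_effect features per modality shifted
#'   in samples that go on to fracture, and their z-shift.
#' @param rewiring_pairs number of microbiota-metabolite feature pairs whose
#'   correlation is `rho_pos` in subtype 1 and `rho_neg` in subtype 2.
#' @param rho_pos,rho_neg target Spearman correlations in the two subtypes.
#' @param n_variants,maf_range,geno_missing_rate genotype panel size, minor
#'   allele frequency range (within (0, 0.5)) and per-call missingness.
#' @param n_qtl_effects,qtl_beta number of planted variant->feature effects
#'   and the additive effect per alternate allele (latent-scale units).
#' @param fracture_model list with `intercept` (log-odds) and coefficients
#'   `subtype2`, `fn_bmd` (per SD) and `prior_fracture`.
#' @param seed master seed; all randomness fans out from it through named
#'   sub-streams (one per modality/component).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_normal = 91, n_osteopenia = 158, n_osteoporosis = 117,
                       subtype_fraction = 0.5,
                       n_features = c(methylation = 300, metabolite = 200,
                                      microbiota = 150),
                       n_signature = c(methylation = 10, metabolite = 10,
                                       microbiota = 10),
                       effect_size = 1.5,
                       n_group_signature = c(methylation = 20, metabolite = 15,
                                             microbiota = 15),
                       group_effect = 1.0,
                       n_fracture_features = c(methylation = 4, metabolite = 3,
                                               microbiota = 3),
                       fracture_effect = 1.0,
                       rewiring_pairs = 10, rho_pos = 0.6, rho_neg = -0.6,
                       n_variants = 400, maf_range = c(0.05, 0.45),
                       geno_missing_rate = 0.01,
                       n_qtl_effects = 5, qtl_beta = 1.0,
                       fracture_model = list(intercept = qlogis(0.07),
                                             subtype2 = 1.2, fn_bmd = -0.6,
                                             prior_fracture = 1.0),
                       seed = 1L) {
  cfg <- as.list(environment())
  if (min(n_normal, n_osteopenia, n_osteoporosis) < 1)
    stop("sim_config: group sizes must be positive")
  if (subtype_fraction <= 0 || subtype_fraction >= 1)
    stop("sim_config: subtype_fraction must lie in (0,1)")
  if (effect_size < 0) stop("sim_config: effect_size must be non-negative")
  if (maf_range[1] <= 0 || maf_range[2] >= 0.5 || maf_range[1] > maf_range[2])
    stop("sim_config: maf_range must lie within (0, 0.5)")
  if (abs(rho_pos) >= 1 || abs(rho_neg) >= 1)
    stop("sim_config: |rho| must be < 1")
  if (n_variants < 1) stop("sim_config: n_variants must be >= 1")
  stopifnot(all(n_signature + n_group_signature + n_fracture_features
                <= n_features))
  class(cfg) <- "sim_config"
  cfg
}

modalities <- c("methylation", "metabolite", "microbiota")

#' Generate a synthetic multi-omics cohort
#'
#' @param config a [sim_config()].
#' @return a list of class `synthetic_cohort` with elements `omics` (list of
#'   [omics_matrix()]), `genotypes` ([genotype_matrix()]), `phenotypes`
#'   ([phenotype_table()]) and `truth` (planted labels, signature features,
#'   rewiring pairs and QTL triples). Identical configs give identical
#'   cohorts.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_normal + config$n_osteopenia + config$n_osteoporosis
  ids <- sprintf("S%03d", seq_len(n))
  group <- rep(c("normal", "osteopenia", "osteoporosis"),
               c(config$n_normal, config$n_osteopenia, config$n_osteoporosis))
  op <- which(group == "osteoporosis")
  n1 <- round(config$subtype_fraction * length(op))
  if (n1 < 1 || n1 >= length(op))
    stop("generate_cohort: subtype_fraction leaves an empty subtype")
  subtype <- rep(NA_character_, n)
  s1 <- with_seed(substream_seed(config$seed, "subtype"),
                  sample(op, n1))
  subtype[s1] <- "S1"
  subtype[setdiff(op, s1)] <- "S2"

  ph <- simulate_phenotypes(ids, group, subtype, config)
  truth <- list(sample_id = ids, group = group, subtype = subtype)
  ph <- generate_fracture_outcomes(ph, truth, config$fracture_model,
                                   substream_seed(config$seed, "fracture"))

  genotypes <- generate_genotypes(n, config$n_variants, config$maf_range,
                                  substream_seed(config$seed, "genotypes"),
                                  missing_rate = config$geno_missing_rate,
                                  sample_ids = ids)

  # Latent Gaussian matrices per modality with planted mean shifts.
  latents <- list(); signatures <- list()
  is_s1 <- !is.na(subtype) & subtype == "S1"
  is_op <- group == "osteoporosis"
  frac <- ph$fracture == 1
  for (m in modalities) {
    p <- config$n_features[[m]]
    z <- with_seed(substream_seed(config$seed, m),
                   matrix(rnorm(p * n), nrow = p))
    rownames(z) <- paste0(substr(m, 1, 4), "_f", seq_len(p))
    colnames(z) <- ids
    idx <- 0L
    take <- function(k) { out <- idx + seq_len(k); idx <<- idx + k; out }
    sub_i <- take(config$n_signature[[m]])
    grp_i <- take(config$n_group_signature[[m]])
    frx_i <- take(config$n_fracture_features[[m]])
    sgn <- function(i) rep_len(c(1, -1), length(i))
    if (length(sub_i)) z[sub_i, is_s1] <- z[sub_i, is_s1] +
        sgn(sub_i) * config$effect_size
    if (length(grp_i)) z[grp_i, is_op] <- z[grp_i, is_op] +
        sgn(grp_i) * config$group_effect
    if (length(frx_i) && any(frac)) z[frx_i, frac] <- z[frx_i, frac] +
        sgn(frx_i) * config$fracture_effect
    latents[[m]] <- z
    signatures[[m]] <- data.frame(
      modality = m,
      feature_id = rownames(z)[c(sub_i, grp_i, frx_i)],
      kind = rep(c("subtype", "group", "fracture"),
                 c(length(sub_i), length(grp_i), length(frx_i))),
      sign = c(sgn(sub_i), sgn(grp_i), sgn(frx_i)),
      stringsAsFactors = FALSE)
  }

  # Planted genotype -> latent-feature effects (additive per alt allele).
  qtl <- NULL
  if (config$n_qtl_effects > 0) {
    qtl <- with_seed(substream_seed(config$seed, "qtl"), {
      vsel <- sample(colnames(genotypes$dosages), config$n_qtl_effects)
      msel <- sample(modalities, config$n_qtl_effects, replace = TRUE)
      data.frame(variant = vsel, modality = msel,
                 feature_id = vapply(msel, function(m) {
                   free <- setdiff(rownames(latents[[m]]),
                                   signatures[[m]]$feature_id)
                   sample(free, 1)
                 }, character(1)),
                 beta = config$qtl_beta, stringsAsFactors = FALSE)
    })
    for (i in seq_len(nrow(qtl))) {
      d <- genotypes$dosages[, qtl$variant[i]]
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      m <- qtl$modality[i]
      latents[[m]][qtl$feature_id[i], ] <-
        latents[[m]][qtl$feature_id[i], ] + qtl$beta[i] * d
    }
  }

  omics <- list(
    methylation = local({
      z <- latents$methylation
      mu <- with_seed(substream_seed(config$seed, "methylation_baseline"),
                      rnorm(nrow(z), 0, 1.5))
      omics_matrix(invlogit(mu + z), "methylation")
    }),
    metabolite = local({
      z <- latents$metabolite
      mu <- with_seed(substream_seed(config$seed, "metabolite_baseline"),
                      rnorm(nrow(z), 2, 0.5))
      omics_matrix(exp(mu + z), "metabolite")
    }),
    microbiota = local({
      z <- latents$microbiota
      mu <- with_seed(substream_seed(config$seed, "microbiota_baseline"),
                      rnorm(nrow(z), 0, 1))
      x <- exp(mu + z)
      omics_matrix(sweep(x, 2L, colSums(x), "/"), "microbiota")
    }))

  # Subtype-dependent correlation rewiring between microbiota and metabolites.
  pairs <- NULL
  if (config$rewiring_pairs > 0) {
    pairs <- with_seed(substream_seed(config$seed, "rewiring_pick"), {
      freeA <- setdiff(rownames(omics$microbiota$values),
                       c(signatures$microbiota$feature_id,
                         if (!is.null(qtl)) qtl$feature_id))
      freeB <- setdiff(rownames(omics$metabolite$values),
                       c(signatures$metabolite$feature_id,
                         if (!is.null(qtl)) qtl$feature_id))
      data.frame(modality_a = "microbiota",
                 feature_a = sample(freeA, config$rewiring_pairs),
                 modality_b = "metabolite",
                 feature_b = sample(freeB, config$rewiring_pairs),
                 stringsAsFactors = FALSE)
    })
    omics <- plant_rewiring(omics, subtype, pairs,
                            rho_pos = config$rho_pos, rho_neg = config$rho_neg,
                            seed = substream_seed(config$seed, "rewiring"))
  }

  structure(list(omics = omics, genotypes = genotypes, phenotypes = ph,
                 truth = list(sample_id = ids, group = group, subtype = subtype,
                              signatures = do.call(rbind, signatures),
                              rewiring = pairs, qtl = qtl),
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples (%s)\n",
              length(x$truth$sample_id),
              paste(table(x$truth$group)[c("normal", "osteopenia",
                                           "osteoporosis")], collapse = "/")))
  invisible(x)
}

simulate_phenotypes <- function(ids, group, subtype, config) {
  n <- length(ids)
  with_seed(substream_seed(config$seed, "phenotypes"), {
    gidx <- match(group, c("normal", "osteopenia", "osteoporosis"))
    # BMD means per group (g/cm^2): decreasing from normal to osteoporosis.
    fn_mu <- c(0.80, 0.67, 0.56)[gidx]
    th_mu <- c(0.85, 0.72, 0.60)[gidx]
    ll_mu <- c(1.05, 0.90, 0.78)[gidx]
    # Subtype contrast: subtype 1 runs lower at hip sites but higher at the
    # lumbar spine than subtype 2.
    s1 <- !is.na(subtype) & subtype == "S1"
    s2 <- !is.na(subtype) & subtype == "S2"
    fn_mu[s1] <- fn_mu[s1] - 0.025; fn_mu[s2] <- fn_mu[s2] + 0.025
    th_mu[s1] <- th_mu[s1] - 0.025; th_mu[s2] <- th_mu[s2] + 0.025
    ll_mu[s1] <- ll_mu[s1] + 0.045; ll_mu[s2] <- ll_mu[s2] - 0.045
    btm_shift <- c(0, 0.15, 0.35)[gidx]  # turnover rises with disease severity
    bmd_delta_mu <- ifelse(s1, 0.040, ifelse(s2, 0.000, 0.010))
    phenotype_table(data.frame(
      sample_id = ids, group = group,
      age = round(rnorm(n, 65, 8), 1),
      sex = rbinom(n, 1, 0.79),  # 1 = female
      bmi = round(rnorm(n, 24, 3), 1),
      fn_bmd = rnorm(n, fn_mu, 0.05),
      th_bmd = rnorm(n, th_mu, 0.05),
      l1l4_bmd = rnorm(n, ll_mu, 0.07),
      prior_fracture = rbinom(n, 1, c(0.08, 0.12, 0.22)[gidx]),
      smoking = rbinom(n, 1, 0.20),
      drinking = rbinom(n, 1, 0.25),
      ctx = exp(rnorm(n, log(0.40) + btm_shift, 0.30)),
      ost = exp(rnorm(n, log(18) + btm_shift, 0.25)),
      pinp = exp(rnorm(n, log(45) + btm_shift, 0.30)),
      bmd_delta = rnorm(n, bmd_delta_mu, 0.02),
      stringsAsFactors = FALSE))
  })
}

#' Generate a genotype matrix at Hardy-Weinberg proportions
#'
#' Each variant's minor allele frequency is drawn uniformly from
#' `maf_range`; genotypes are binomial(2, maf) and a fraction
#' `missing_rate` of calls is set missing.
#'
#' @param n_samples,n_variants dimensions.
#' @param maf_range interval within (0, 0.5).
#' @param seed integer seed.
#' @param missing_rate per-call missingness probability.
#' @param sample_ids optional ids (defaults to g1..gn).
#' @return a [genotype_matrix()].
#' @export
generate_genotypes <- function(n_samples, n_variants, maf_range, seed,
                               missing_rate = 0, sample_ids = NULL) {
  if (n_variants < 1) stop("generate_genotypes: n_variants must be >= 1")
  if (maf_range[1] <= 0 || maf_range[2] >= 0.5)
    stop("generate_genotypes: maf_range must lie within (0, 0.5)")
  with_seed(seed, {
    maf <- runif(n_variants, maf_range[1], maf_range[2])
    dos <- vapply(maf, function(f) rbinom(n_samples, 2, f),
                  numeric(n_samples))
    dos <- matrix(dos, nrow = n_samples)
    if (missing_rate > 0)
      dos[matrix(runif(length(dos)) < missing_rate, nrow = n_samples)] <- NA
    rownames(dos) <- sample_ids %||% paste0("g", seq_len(n_samples))
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, n_variants, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1), character(1))
    genotype_matrix(dos, data.frame(
      id = sprintf("rs%05d", seq_len(n_variants)),
      chrom = sample(paste0("chr", 1:22), n_variants, replace = TRUE),
      pos = sort(sample.int(5e7, n_variants)),
      ref = ref, alt = alt, stringsAsFactors = FALSE))
  })
}

#' Plant subtype-dependent correlation between feature pairs
#'
#' Within each subtype stratum the second feature of every pair is re-drawn
#' by a Gaussian-copula quantile remap so its Spearman correlation with the
#' first feature is approximately `rho_pos` in subtype 1 and `rho_neg` in
#' subtype 2 while its within-stratum marginal distribution is preserved
#' exactly (the new values are a permutation of the old). Relative-abundance
#' matrices are re-closed to the simplex afterwards.
#'
#' @param omics named list of [omics_matrix()] objects.
#' @param subtype_labels character vector over samples; values `"S1"`,
#'   `"S2"` or `NA` (samples outside the two strata are untouched).
#' @param pairs data.frame with columns `modality_a`, `feature_a`,
#'   `modality_b`, `feature_b`.
#' @param rho_pos,rho_neg target Spearman correlations, |rho| < 1.
#' @param seed integer seed.
#' @return the omics list with rewired pairs.
#' @export
plant_rewiring <- function(omics, subtype_labels, pairs, rho_pos, rho_neg,
                           seed) {
  if (abs(rho_pos) >= 1 || abs(rho_neg) >= 1)
    stop("plant_rewiring: |rho| must be < 1")
  if (is.null(pairs) || nrow(pairs) == 0L) return(omics)
  for (i in seq_len(nrow(pairs)))
    if (!pairs$feature_a[i] %in% rownames(omics[[pairs$modality_a[i]]]$values) ||
        !pairs$feature_b[i] %in% rownames(omics[[pairs$modality_b[i]]]$values))
      stop("plant_rewiring: pair ", i, " references unknown features")
  with_seed(seed, {
    for (st in c("S1", "S2")) {
      rho_s <- if (st == "S1") rho_pos else rho_neg
      r <- 2 * sin(pi * rho_s / 6)  # Pearson r giving Spearman rho_s
      idx <- which(!is.na(subtype_labels) & subtype_labels == st)
      if (length(idx) < 3) next
      for (i in seq_len(nrow(pairs))) {
        a <- omics[[pairs$modality_a[i]]]$values[pairs$feature_a[i], idx]
        b <- omics[[pairs$modality_b[i]]]$values[pairs$feature_b[i], idx]
        u <- qnorm(rank(a, ties.method = "average") / (length(a) + 1))
        znew <- r * u + sqrt(1 - r^2) * rnorm(length(a))
        omics[[pairs$modality_b[i]]]$values[pairs$feature_b[i], idx] <-
          sort(b)[rank(znew, ties.method = "first")]
      }
    }
    for (m in names(omics))
      if (omics[[m]]$value_semantics == "relative_abundance")
        omics[[m]]$values <- sweep(omics[[m]]$values, 2L,
                                   colSums(omics[[m]]$values), "/")
    omics
  })
}

#' Draw fracture outcomes from a logistic model
#'
#' Log-odds of a 4-year fracture event are
#' `intercept + subtype2 * I(subtype == "S2") + fn_bmd * scale(FN BMD) +
#' prior_fracture * PF`.
#'
#' @param phenotypes a [phenotype_table()] with `fn_bmd` and
#'   `prior_fracture` columns.
#' @param truth list with per-sample `subtype` labels (as in a cohort's
#'   `truth` element).
#' @param fracture_model list of `intercept`, `subtype2`, `fn_bmd`,
#'   `prior_fracture` coefficients on the log-odds scale.
#' @param seed integer seed.
#' @return the phenotype table with a binary `fracture` column appended.
#' @export
generate_fracture_outcomes <- function(phenotypes, truth, fracture_model,
                                       seed) {
  if (!all(c("fn_bmd", "prior_fracture") %in% names(phenotypes)))
    stop("generate_fracture_outcomes: phenotypes need fn_bmd and prior_fracture")
  s2 <- as.numeric(!is.na(truth$subtype) & truth$subtype == "S2")
  eta <- fracture_model$intercept +
    fracture_model$subtype2 * s2 +
    fracture_model$fn_bmd * as.numeric(scale(phenotypes$fn_bmd)) +
    fracture_model$prior_fracture * phenotypes$prior_fracture
  phenotypes$fracture <- with_seed(seed, rbinom(length(eta), 1, plogis(eta)))
  phenotype_table(as.data.frame(phenotypes))
}
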