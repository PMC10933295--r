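# osteomix

Integrative multi-omics analysis of osteoporosis cohorts: molecular
subtyping by deep latent space fusion (DLSF), differential association
(rewiring) analysis, multi-modal molecular signature (M3S) selection,
genotype QC and molecular-QTL scans, nested logistic risk models, and
AUC-ranked composite fracture-risk indices — with a synthetic cohort
generator that encodes the statistical structure all of these analyses
assume, so the whole pipeline is testable without patient data.

## The problem

Osteoporosis is diagnosed from bone mineral density (BMD) alone, yet
patients with identical T-scores differ widely in molecular state,
treatment response and fracture risk. Given matched methylation,
metabolite and gut-microbiota profiles plus genotypes and clinical
covariates for a three-group cohort (normal / osteopenia / osteoporosis),
this package asks: are there molecular subtypes inside the osteoporosis
group, what rewires between them, which genotypes drive their molecular
features, and do molecular signatures improve osteoporosis risk models and
fracture prediction beyond clinical covariates and bone turnover markers?

## The core method

Per modality *m*, an autoencoder encodes the standardized feature matrix
X_m to a latent Z_m; with reconstruction X̂_m = Dec_m(Z_m), training
minimizes

    Σ_m  λ_rec ‖X_m − X̂_m‖² / n  +  λ_se ‖X̂_m − X̂_m C_m‖² / n
        +  λ_reg ‖C_m‖²,     diag(C_m) = 0

where C_m is a sample-by-sample self-expression matrix solved in closed
form (zero-diagonal ridge regression) during the joint training phase.
The fused affinity S = mean_m normalize(relu(C_m) + relu(C_m)ᵀ) is cut by
normalized-cut spectral clustering; the cluster count k ∈ {2,3,4} is
selected by clinical-phenotype association count under a cluster-balance
floor. Downstream: Fisher-z differential association between subtypes,
OCLR-style one-class signature weights, exact Hardy–Weinberg QC, additive
OLS xQTL scans at P < 1e-5, mRMR + ridge-logistic risk tiers with 70/30
evaluation, decision curves, and exhaustive sum-index panel screening
(N < 5) with covariate-adjusted AUC.

See `vignettes/osteomix-methods.Rmd` for the full model, parameter
defaults and design rationale.

## Worked example

The numbered drivers under `analysis/` run the whole study on a simulated
cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R     # cohort -> results/cohort/
Rscript analysis/02_landscape.R    # QC, screens, RV index
Rscript analysis/03_subtype.R      # DLSF subtyping
Rscript analysis/04_dam_m3s.R      # rewiring + signatures
Rscript analysis/05_xqtl.R         # snpGenes and xQTL
Rscript analysis/06_risk.R         # risk-model tiers
Rscript analysis/07_fracture.R     # fracture AUC ranking + composite index
```

What they print (abridged), and what it means:

```
01: <synthetic_cohort> 366 samples (91/158/117)
    osteoporosis subtype sizes: 58 / 59
02: RV index matrix:            methylation/metabolite 0.440, ...
    # moderate shared information between modalities: fusion has something
    # to gain, no modality is redundant
03: selected k = 2 ; cluster sizes: 58 / 59
    5 phenotypes associated at P < 0.05  (fn_bmd, th_bmd, l1l4_bmd,
    bmd_delta, fracture)
    ARI against planted subtypes: 1.000
    # the fused affinity recovers the planted subtypes exactly, and the
    # labels associate with the BMD phenotypes the subtypes encode
04: 10 rewired pairs at BH-FDR 0.05; e.g. micr_f87 ~ meta_f199 has
    Spearman +0.68 in subtype 1 and -0.63 in subtype 2
05: 21 variants with group-dependent genotype distribution (P < 0.05)
    8 xQTL hits at P < 1e-5 across subtypes and modalities
06: baseline1 test AUC 0.412 | baseline2 0.778 | m3s 0.961
    # conventional risk factors carry nothing here by construction; bone
    # turnover markers help; molecular signatures close most of the gap
07: ALL population: FN BMD AUC 0.724 ... OP population: FN BMD AUC 0.654
    best composite panel (OP): 4 CpGs, AUC 0.910 (covariate-adjusted 0.888)
    best single member AUC: 0.781
    # BMD predicts fracture across the whole cohort but degrades inside
    # the osteoporosis group, where a small CpG sum-index does better than
    # any single feature
```

A minimal in-R session:

```r
library(osteomix)
coh <- generate_cohort(sim_config(seed = 1))
res <- dlsf_subtype(coh$omics, coh$phenotypes, dlsf_config(seed = 1),
                    population = "op", k = 2)
table(res$assignment$labels,
      coh$truth$subtype[match(res$assignment$sample_ids,
                              coh$truth$sample_id)])
#>      S1 S2
#>   1  58  0
#>   2   0 59
```

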