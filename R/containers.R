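#' Construct a validated single-modality omics matrix
#'
#' The package's canonical container for one molecular modality: a numeric
#' features x samples matrix tagged with its value semantics. Methylation is
#' carried as beta values in [0, 1] (`beta01`), metabolite abundances as
#' positive values (`positive_abundance`), and microbiota profiles as
#' per-sample relative abundances that close to one (`relative_abundance`).
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param modality one of `"methylation"`, `"metabolite"`, `"microbiota"`.
#' @param value_semantics one of `"beta01"`, `"positive_abundance"`,
#'   `"relative_abundance"`; defaults to the modality's conventional scale.
#' @param feature_ids,sample_ids optional character vectors overriding the
#'   dimnames of `values`.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, modality,
                         value_semantics = c(methylation = "beta01",
                                             metabolite = "positive_abundance",
                                             microbiota = "relative_abundance")[[modality]],
                         feature_ids = rownames(values),
                         sample_ids = colnames(values)) {
  modality <- match.arg(modality, c("methylation", "metabolite", "microbiota"))
  value_semantics <- match.arg(value_semantics,
                               c("beta01", "positive_abundance", "relative_abundance"))
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("omics_matrix: values must be numeric")
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  if (anyDuplicated(feature_ids))
    stop("omics_matrix: duplicated feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)])[1:3], collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("omics_matrix: duplicated sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)])[1:3], collapse = ", "))
  if (length(feature_ids) != nrow(values) || length(sample_ids) != ncol(values))
    stop("omics_matrix: id lengths do not match matrix dimensions")
  if (anyNA(values)) stop("omics_matrix: missing values are not permitted")
  dimnames(values) <- list(feature_ids, sample_ids)
  x <- structure(list(values = values, modality = modality,
                      value_semantics = value_semantics),
                 class = "omics_matrix")
  validate_omics(x)
  x
}

validate_omics <- function(x) {
  v <- x$values
  if (x$value_semantics == "beta01") {
    bad <- which(v < 0 | v > 1, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("omics_matrix: beta value outside [0,1] for feature '",
           rownames(v)[bad[1, 1]], "'")
  } else if (x$value_semantics == "positive_abundance") {
    bad <- which(v < 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("omics_matrix: negative abundance for feature '",
           rownames(v)[bad[1, 1]], "'")
  } else if (x$value_semantics == "relative_abundance") {
    cs <- colSums(v)
    off <- which(abs(cs - 1) > 1e-6)
    if (length(off) > 0)
      stop("omics_matrix: relative abundances of sample '",
           colnames(v)[off[1]], "' sum to ", format(cs[off[1]]), ", not 1")
  }
  invisible(x)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s (%s): %d features x %d samples\n",
              x$modality, x$value_semantics, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Sample ids carried by a data object
#' @param x an [omics_matrix()], [genotype_matrix()] or data.frame with a
#'   `sample_id` column.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(x) UseMethod("sample_ids")
#' @export
sample_ids.omics_matrix <- function(x) colnames(x$values)
#' @export
sample_ids.genotype_matrix <- function(x) rownames(x$dosages)
#' @export
sample_ids.data.frame <- function(x) x$sample_id

#' Restrict a data object to the given samples, in the given order
#' @param x an [omics_matrix()], [genotype_matrix()] or data.frame with a
#'   `sample_id` column.
#' @param ids sample ids to keep, in the desired order.
#' @return the object restricted to `ids`.
#' @export
subset_samples <- function(x, ids) UseMethod("subset_samples")
#' @export
subset_samples.omics_matrix <- function(x, ids) {
  x$values <- x$values[, ids, drop = FALSE]
  x
}
#' @export
subset_samples.genotype_matrix <- function(x, ids) {
  x$dosages <- x$dosages[ids, , drop = FALSE]
  x
}
#' @export
subset_samples.data.frame <- function(x, ids) {
  x[match(ids, x$sample_id), , drop = FALSE]
}

#' Construct a genotype matrix of additive dosages
#'
#' @param dosages numeric matrix, samples in rows and variants in columns,
#'   entries in \{0, 1, 2\} or `NA` for missing calls.
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, one row per variant column.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)),
            nrow(variants) == ncol(dosages))
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("genotype_matrix: dosages must be in {0,1,2,NA}")
  if (any(variants$pos < 1)) stop("genotype_matrix: pos must be >= 1")
  if (anyDuplicated(variants$id)) stop("genotype_matrix: duplicated variant ids")
  colnames(dosages) <- variants$id
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("s", seq_len(nrow(dosages)))
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Construct a validated phenotype table
#'
#' One row per sample. The `group` column must be one of
#' normal/osteopenia/osteoporosis; declared binary columns are coerced to
#' 0/1 integers and continuous columns to numeric, failing loudly on
#' non-conforming values.
#'
#' @param df data.frame containing at least `sample_id` and `group`.
#' @param binary_cols,continuous_cols optional character vectors of columns
#'   whose types should be enforced on construction.
#' @return a `data.frame` with class `phenotype_table` prepended.
#' @export
phenotype_table <- function(df,
                            binary_cols = intersect(c("sex", "prior_fracture",
                                                      "smoking", "drinking",
                                                      "fracture"), names(df)),
                            continuous_cols = intersect(c("age", "bmi", "fn_bmd",
                                                          "th_bmd", "l1l4_bmd",
                                                          "bmd_delta", "ctx",
                                                          "ost", "pinp"),
                                                        names(df))) {
  stopifnot(is.data.frame(df), "sample_id" %in% names(df), "group" %in% names(df))
  if (anyDuplicated(df$sample_id)) stop("phenotype_table: duplicated sample ids")
  if (anyNA(df$group)) stop("phenotype_table: group label missing for some samples")
  bad <- setdiff(unique(df$group), c("normal", "osteopenia", "osteoporosis"))
  if (length(bad) > 0)
    stop("phenotype_table: unknown group label(s): ", paste(bad, collapse = ", "))
  for (cl in binary_cols) {
    v <- df[[cl]]
    if (!all(v %in% c(0, 1, NA)))
      stop("phenotype_table: column '", cl, "' is not binary 0/1")
    df[[cl]] <- as.integer(v)
  }
  for (cl in continuous_cols) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    if (any(is.na(v) & !is.na(df[[cl]])))
      stop("phenotype_table: column '", cl, "' is not numeric")
    df[[cl]] <- v
  }
  class(df) <- c("phenotype_table", "data.frame")
  df
}

#' Construct a gene interval set (BED-style, 0-based half-open)
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `gene_id` and
#'   optional `feature_class` (values `exon` / `intron` / `gene`).
#' @return data.frame with class `gene_intervals`, sorted by chrom and start.
#' @export
gene_intervals <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end", "gene_id") %in% names(df)))
  if (any(df$start >= df$end)) stop("gene_intervals: start must be < end")
  if (any(df$start < 0)) stop("gene_intervals: negative start")
  if (is.null(df$feature_class)) df$feature_class <- "gene"
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_intervals", "data.frame")
  df
}

#' Restrict a set of sample-bearing objects to their shared samples
#'
#' Takes the intersection of sample ids across all arguments and returns
#' every object subset to those samples in the order they appear in the
#' first argument. Omics matrices, genotype matrices and phenotype tables
#' (any data.frame with a `sample_id` column) are supported.
#'
#' @param ... two or more objects carrying sample ids.
#' @return a list of the input objects restricted to the common samples,
#'   with attribute `dropped`: a list of the ids dropped from each input.
#' @export
align_samples <- function(...) {
  objs <- list(...)
  if (length(objs) < 2L) stop("align_samples: need at least two objects")
  ids <- lapply(objs, sample_ids)
  shared <- Reduce(intersect, ids)
  if (length(shared) == 0L) stop("align_samples: no shared samples")
  shared <- ids[[1]][ids[[1]] %in% shared]  # keep first argument's order
  out <- lapply(objs, subset_samples, ids = shared)
  names(out) <- names(objs)
  attr(out, "dropped") <- lapply(ids, function(i) setdiff(i, shared))
  out
}
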