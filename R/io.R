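# On-disk formats: omics TSV (features x samples), minimal VCF v4.2 (GT only),
# dosage TSV, phenotype CSV, BED3+1 intervals. All floats are serialized at 10
# significant digits so write/read round trips are byte-stable.

fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 10)
  gsub(" ", "", out)
}

#' Read a single-modality omics TSV
#'
#' Expects a tab-separated file with feature ids in the first column and a
#' header row of sample ids.
#'
#' @param path file path.
#' @param modality,value_semantics passed to [omics_matrix()].
#' @param impute `"none"` (default; missing cells are an error) or
#'   `"median"` to replace missing cells by the feature's median.
#' @return an [omics_matrix()].
#' @export
read_omics <- function(path, modality, value_semantics = NULL,
                       impute = c("none", "median")) {
  impute <- match.arg(impute)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   row.names = NULL, colClasses = "character")
  fid <- df[[1]]
  raw <- as.matrix(df[, -1, drop = FALSE])
  m <- raw
  suppressWarnings(storage.mode(m) <- "double")
  nonnum <- is.na(m) & !(raw %in% c("NA", "") | is.na(raw))
  if (any(nonnum)) {
    w <- which(nonnum, arr.ind = TRUE)[1, ]
    stop("read_omics: non-numeric cell at feature '", fid[w[1]], "', sample '",
         colnames(m)[w[2]], "'")
  }
  if (anyNA(m)) {
    if (impute == "median") {
      for (i in which(rowSums(is.na(m)) > 0))
        m[i, is.na(m[i, ])] <- median(m[i, ], na.rm = TRUE)
    } else {
      stop("read_omics: missing values present (use impute = 'median')")
    }
  }
  rownames(m) <- fid
  args <- list(values = m, modality = modality)
  if (!is.null(value_semantics)) args$value_semantics <- value_semantics
  do.call(omics_matrix, args)
}

#' Write a single-modality omics TSV
#'
#' @param x an [omics_matrix()].
#' @param path output path.
#' @export
write_omics <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  v <- x$values
  body <- cbind(feature_id = rownames(v),
                matrix(fmt_num(v), nrow = nrow(v),
                       dimnames = list(NULL, colnames(v))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(colnames(body), collapse = "\t"), con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read genotypes from a minimal VCF or a dosage TSV
#'
#' VCF input is restricted to the GT-only subset this package writes
#' (v4.2 header, single ALT allele). Genotypes `0/0`, `0/1`, `1/0`, `1/1`
#' map to dosages 0, 1, 1, 2; `./.` is missing. Multi-allelic records are
#' rejected. A dosage TSV (variants in rows: id, chrom, pos, ref, alt, then
#' one column per sample) is detected by extension `.tsv`.
#'
#' @param path input file.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.tsv$", path)) return(read_dosage_tsv(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT)))
    stop("read_genotypes: multi-allelic records are not supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  phased <- gsub("\\|", "/", gt)
  dos <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  code <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2)
  known <- phased %in% c(names(code), "./.", NA)
  if (!all(known)) stop("read_genotypes: malformed GT field '",
                        phased[!known][1], "'")
  dos[] <- t(matrix(code[phased], nrow = nrow(gt)))
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_matrix(dos, variants)
}

read_dosage_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  meta <- df[, c("id", "chrom", "pos", "ref", "alt")]
  dos <- t(as.matrix(df[, setdiff(names(df), names(meta)), drop = FALSE]))
  colnames(dos) <- meta$id
  genotype_matrix(dos, meta)
}

#' Write genotypes as a minimal VCF v4.2 (GT only)
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @export
write_genotypes_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g$dosages)), collapse = "\t")),
             con)
  gtcode <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(g$variants))) {
    d <- g$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gtcode[d + 1])
    writeLines(paste(c(g$variants$chrom[j], g$variants$pos[j], g$variants$id[j],
                       g$variants$ref[j], g$variants$alt[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write genotypes as a dosage TSV
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @export
write_dosage_tsv <- function(g, path) {
  df <- cbind(g$variants[, c("id", "chrom", "pos", "ref", "alt")],
              as.data.frame(t(g$dosages)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype CSV
#' @param path file path.
#' @return a [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  phenotype_table(read.table(path, sep = ",", header = TRUE,
                             stringsAsFactors = FALSE))
}

#' Write a phenotype CSV
#' @param ph a [phenotype_table()].
#' @param path output path.
#' @export
write_phenotypes <- function(ph, path) {
  df <- as.data.frame(ph)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene intervals from a BED3+1(+1) file
#'
#' Columns: chrom, start, end, gene_id, optional feature_class
#' (exon/intron/gene). Coordinates are 0-based half-open as in BED.
#'
#' @param path file path.
#' @return a [gene_intervals()] data.frame.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:4] <- c("chrom", "start", "end", "gene_id")
  if (ncol(df) >= 5) names(df)[5] <- "feature_class"
  gene_intervals(df)
}

#' Write a synthetic cohort to the package's standard on-disk layout
#'
#' One TSV per modality, genotypes as minimal VCF plus a dosage TSV,
#' phenotypes as CSV, and the ground truth as a separate CSV that analysis
#' stages never read.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (om in cohort$omics)
    write_omics(om, file.path(dir, paste0(om$modality, ".tsv")))
  write_genotypes_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  write_dosage_tsv(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  write_phenotypes(cohort$phenotypes, file.path(dir, "phenotypes.csv"))
  tr <- cohort$truth
  write.table(data.frame(sample_id = tr$sample_id, group = tr$group,
                         subtype = tr$subtype),
              file.path(dir, "truth.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
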