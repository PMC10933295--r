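#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate anova aov as.dist binomial chisq.test coef
#'   complete.cases cor cor.test cutree dist ecdf fisher.test glm hclust
#'   kmeans kruskal.test ks.test lm lm.fit mad median model.matrix na.omit
#'   p.adjust pchisq pf plogis pnorm prcomp predict pt qlogis qnorm quantile
#'   rbinom resid rnorm runif sd setNames t.test var wilcox.test
#' @importFrom utils combn read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

logit <- function(p) qlogis(p)
invlogit <- function(x) plogis(x)

#' Centred log-ratio transform of a relative-abundance matrix
#'
#' Standard compositional-data transform: each sample (column) is log-divided
#' by its geometric mean. Zeros are replaced by a pseudocount equal to half
#' the smallest positive value of the matrix before taking logs.
#'
#' @param x numeric matrix, features x samples, non-negative entries.
#' @return numeric matrix of the same shape with zero column means.
#' @export
clr_transform <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("clr_transform: negative abundances")
  pos <- x[x > 0]
  if (length(pos) == 0L) stop("clr_transform: all-zero matrix")
  pc <- min(pos) / 2
  lx <- log(x + pc)
  sweep(lx, 2L, colMeans(lx), "-")
}

# z-score each row; rows with zero variance become all-zero
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1L, sd)
  s[s == 0 | !is.finite(s)] <- 1
  (x - mu) / s
}

# Named deterministic sub-stream seeds: one master seed fans out to
# independent component streams so enlarging one modality's simulation does
# not perturb another's draws.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

om_log <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(..., collapse = "")))
}
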