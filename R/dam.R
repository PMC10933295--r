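# Differential association matrix (DAM) analysis: stratum-specific Spearman
# association matrices between modalities, Fisher-z rewiring statistics, and
# stemness-like M3S signature selection.

#' Cross-modal Spearman association matrix within a stratum
#'
#' @param x,y [omics_matrix()] objects or feature x sample matrices
#'   (analysis-scale transform applied to omics matrices).
#' @param stratum_mask logical or id vector selecting the stratum samples
#'   (>= 5 required).
#' @param stratum_label optional label stored with the result.
#' @return list of class `association_matrix`: `rho`, `p` (asymptotic
#'   t-approximation), `n_stratum`, `stratum`. Features constant within the
#'   stratum yield `NA` entries.
#' @export
association_matrix <- function(x, y, stratum_mask = NULL,
                               stratum_label = "all") {
  vx <- if (inherits(x, "omics_matrix")) analysis_scale(x) else as.matrix(x)
  vy <- if (inherits(y, "omics_matrix")) analysis_scale(y) else as.matrix(y)
  if (!is.null(stratum_mask)) {
    vx <- vx[, stratum_mask, drop = FALSE]
    vy <- vy[, stratum_mask, drop = FALSE]
  }
  n <- ncol(vx)
  if (n < 5) stop("association_matrix: stratum has fewer than 5 samples")
  if (ncol(vy) != n) stop("association_matrix: sample mismatch")
  constx <- apply(vx, 1L, function(r) length(unique(r)) == 1L)
  consty <- apply(vy, 1L, function(r) length(unique(r)) == 1L)
  sm <- suppressWarnings(spearman_matrix(vx, vy, n = n))
  sm$rho[constx, ] <- NA; sm$p[constx, ] <- NA
  sm$rho[, consty] <- NA; sm$p[, consty] <- NA
  structure(list(rho = sm$rho, p = sm$p, n_stratum = n,
                 stratum = stratum_label),
            class = "association_matrix")
}

#' Differential association (rewiring) between two strata
#'
#' For each feature pair, compares the stratum-specific Spearman
#' correlations with the Fisher-z statistic
#' z = (atanh(rho1) - atanh(rho2)) / sqrt(1/(n1-3) + 1/(n2-3)) and a
#' two-sided normal p-value. A pair is a sign flip when the correlations
#' have opposite signs and both exceed `flip_threshold` in magnitude.
#'
#' @param a1,a2 [association_matrix()] results over identical feature sets
#'   from disjoint strata.
#' @param flip_threshold minimum |rho| in both strata for the sign-flip flag.
#' @return data.frame: row_feature, col_feature, rho1, rho2, delta, z,
#'   p_rewire, q_rewire (BH), sign_flip.
#' @export
differential_association <- function(a1, a2, flip_threshold = 0.3) {
  stopifnot(inherits(a1, "association_matrix"),
            inherits(a2, "association_matrix"),
            all(dim(a1$rho) == dim(a2$rho)))
  if (a1$n_stratum <= 3 || a2$n_stratum <= 3)
    stop("differential_association: stratum with n <= 3")
  idx <- expand.grid(i = seq_len(nrow(a1$rho)), j = seq_len(ncol(a1$rho)))
  r1 <- a1$rho[cbind(idx$i, idx$j)]
  r2 <- a2$rho[cbind(idx$i, idx$j)]
  se <- sqrt(1 / (a1$n_stratum - 3) + 1 / (a2$n_stratum - 3))
  z <- (atanh(pmin(pmax(r1, -1 + 1e-12), 1 - 1e-12)) -
        atanh(pmin(pmax(r2, -1 + 1e-12), 1 - 1e-12))) / se
  p <- 2 * pnorm(abs(z), lower.tail = FALSE)
  out <- data.frame(
    row_feature = rownames(a1$rho)[idx$i],
    col_feature = colnames(a1$rho)[idx$j],
    rho1 = r1, rho2 = r2, delta = r1 - r2, z = z, p_rewire = p,
    sign_flip = !is.na(r1) & !is.na(r2) & r1 * r2 < 0 &
      abs(r1) >= flip_threshold & abs(r2) >= flip_threshold,
    stringsAsFactors = FALSE)
  out$q_rewire <- p.adjust(out$p_rewire, "BH")
  out[order(out$p_rewire), ]
}

#' Stemness-like one-class feature weights and per-sample index
#'
#' Fits a one-class least-squares regression (OCLR-style) on a reference
#' stratum: the unit-norm weight vector w solves the ridge problem of
#' mapping the standardized reference profiles to a constant positive
#' response, so features systematically elevated (or depressed) in the
#' reference stratum receive large |w|. Each sample is then scored by the
#' Spearman correlation between w and its standardized feature vector;
#' standardizing first makes the index invariant to per-feature scaling.
#'
#' @param x an [omics_matrix()] or feature x sample matrix (all samples).
#' @param reference_ids sample ids (or indices) of the reference stratum,
#'   >= 5 samples.
#' @param ridge ridge penalty of the one-class fit; default scales with the
#'   reference size so the fit is dominated neither by the penalty nor by
#'   the reference covariance.
#' @return list: `weights` (named, unit norm, ranked by |w| in `ranking`),
#'   `index` (named per-sample score).
#' @export
stemness_like_weights <- function(x, reference_ids, ridge = NULL) {
  v <- if (inherits(x, "omics_matrix")) analysis_scale(x) else as.matrix(x)
  ref <- v[, reference_ids, drop = FALSE]
  if (ncol(ref) < 5) stop("stemness_like_weights: reference needs >= 5 samples")
  z <- standardize_rows(v)
  zr <- z[, reference_ids, drop = FALSE]
  if (is.null(ridge)) ridge <- ncol(zr)
  # one-class ridge: w = (Z Z' + ridge I)^-1 Z 1   (response fixed at 1)
  p <- nrow(zr)
  w <- solve(tcrossprod(zr) + ridge * diag(p), rowSums(zr))
  nw <- sqrt(sum(w^2))
  if (nw == 0) stop("stemness_like_weights: degenerate reference")
  w <- as.numeric(w / nw)
  names(w) <- rownames(v)
  index <- apply(z, 2L, function(s) cor(w, s, method = "spearman"))
  list(weights = w, ranking = names(w)[order(-abs(w))], index = index)
}

#' Select multi-modal molecular signatures (M3S)
#'
#' Per modality, intersects the top-q features by |stemness-like weight|
#' with the Wilcoxon-significant features from the differential screen,
#' ordered by |weight|. An empty intersection falls back to the top-q by
#' weight with a warning.
#'
#' @param weights named list per modality of weight vectors (as returned in
#'   `weights` by [stemness_like_weights()]).
#' @param screens named list per modality of [wilcoxon_screen()] results.
#' @param top_q number of top-|weight| features considered per modality.
#' @return data.frame of class `signature_set`: modality, feature_id,
#'   weight, rank.
#' @export
select_m3s <- function(weights, screens, top_q = 20) {
  stopifnot(all(names(weights) %in% names(screens)) || is.null(names(weights)))
  rows <- lapply(names(weights), function(m) {
    w <- weights[[m]]
    top <- names(w)[order(-abs(w))][seq_len(min(top_q, length(w)))]
    sig <- screens[[m]]$results$feature_id[screens[[m]]$results$significant]
    sel <- intersect(top, sig)
    if (length(sel) == 0) {
      warning("select_m3s: empty intersection for '", m,
              "'; falling back to top-", top_q, " by weight")
      sel <- top
    }
    sel <- sel[order(-abs(w[sel]))]
    data.frame(modality = m, feature_id = sel, weight = w[sel],
               rank = seq_along(sel), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("signature_set", "data.frame")
  out
}
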