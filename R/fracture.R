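# Fracture-risk biomarker assessment: per-feature AUC ranking in the ALL
# and OP populations, covariate-adjusted AUC by least-squares
# residualization, and exhaustive composite sum-index panel screening.

feature_orientation <- function(values, labels) {
  a <- auc(values, labels)$auc
  if (a >= 0.5) list(orientation = 1, auc = a)
  else list(orientation = -1, auc = 1 - a)
}

#' Rank features by fracture-risk AUC
#'
#' Scores each feature directly as a risk index; orientation is chosen so
#' the reported AUC is >= 0.5 and is recorded (+1: larger values riskier,
#' -1: smaller values riskier, as for BMD). Features clearing
#' `candidate_threshold` are flagged as candidate indicators.
#'
#' @param features numeric feature x sample matrix, [omics_matrix()], or
#'   data.frame of clinical columns (samples in rows).
#' @param labels binary fracture outcome over samples.
#' @param population_mask optional logical/index vector restricting the
#'   population (e.g. the osteoporosis group).
#' @param population label stored in the output.
#' @param candidate_threshold AUC bar for the candidate flag.
#' @return data.frame ranked by AUC: feature_id, population, orientation,
#'   auc, candidate.
#' @export
feature_auc_ranking <- function(features, labels, population_mask = NULL,
                                population = "ALL",
                                candidate_threshold = 0.6) {
  v <- if (inherits(features, "omics_matrix")) analysis_scale(features)
       else if (is.data.frame(features)) t(as.matrix(features))
       else as.matrix(features)
  labels <- as.numeric(labels)
  if (!is.null(population_mask)) {
    v <- v[, population_mask, drop = FALSE]
    labels <- labels[population_mask]
  }
  if (length(unique(labels)) < 2)
    stop("feature_auc_ranking: single-class population")
  rows <- lapply(seq_len(nrow(v)), function(i) {
    fo <- feature_orientation(v[i, ], labels)
    data.frame(feature_id = rownames(v)[i] %||% paste0("f", i),
               population = population, orientation = fo$orientation,
               auc = fo$auc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$candidate <- out$auc > candidate_threshold
  out <- out[order(-out$auc), ]
  rownames(out) <- NULL
  out
}

#' Covariate-adjusted feature AUC
#'
#' Residualizes the feature on a covariate scheme by least squares within
#' the population and recomputes the oriented AUC on the residuals. The
#' three standard schemes are (1) age + gender, (2) age + gender + prior
#' fracture, (3) age + gender + prior fracture + FN BMD.
#'
#' @param feature numeric feature values over the population samples.
#' @param labels binary fracture outcome.
#' @param covariates data.frame with columns `age`, `sex`,
#'   `prior_fracture`, `fn_bmd` (as required by the scheme).
#' @param scheme 1, 2 or 3.
#' @return list: `auc` (adjusted, oriented), `orientation`, `scheme_vars`.
#' @export
adjusted_auc <- function(feature, labels, covariates, scheme = 1) {
  vars <- switch(as.character(scheme),
                 "1" = c("age", "sex"),
                 "2" = c("age", "sex", "prior_fracture"),
                 "3" = c("age", "sex", "prior_fracture", "fn_bmd"),
                 stop("adjusted_auc: scheme must be 1, 2 or 3"))
  miss <- setdiff(vars, names(covariates))
  if (length(miss)) stop("adjusted_auc: missing covariates: ",
                         paste(miss, collapse = ", "))
  X <- as.matrix(covariates[, vars, drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("adjusted_auc: collinear covariates")
  res <- resid(lm.fit(cbind(1, X), feature))
  fo <- feature_orientation(res, as.numeric(labels))
  list(auc = fo$auc, orientation = fo$orientation, scheme_vars = vars)
}

#' Exhaustive composite sum-index panel screening
#'
#' Enumerates every subset of 1..`max_size` candidate features, scores each
#' panel by the sum of its members' values (each member z-scored within the
#' population and sign-corrected by its own orientation first, unless
#' `raw_sum = TRUE`), and ranks panels by AUC. Deterministic and invariant
#' to the candidate input order.
#'
#' @param features numeric feature x sample matrix (or [omics_matrix()])
#'   restricted to the candidate features, or with `candidates` naming them.
#' @param labels binary fracture outcome over the population samples.
#' @param candidates optional feature ids to enumerate (default: all rows).
#' @param max_size maximum panel size (panels of N < 5 by default).
#' @param raw_sum sum raw member values instead of oriented z-scores.
#' @param covariates,scheme optional: also report the adjusted AUC of each
#'   panel score via [adjusted_auc()].
#' @return data.frame ranked by AUC: panel (feature ids joined by `+`),
#'   size, auc, and `auc_adjusted` when covariates are given.
#' @export
composite_screen <- function(features, labels, candidates = NULL,
                             max_size = 4, raw_sum = FALSE,
                             covariates = NULL, scheme = 3) {
  v <- if (inherits(features, "omics_matrix")) analysis_scale(features)
       else as.matrix(features)
  labels <- as.numeric(labels)
  if (is.null(candidates)) candidates <- rownames(v)
  if (length(candidates) == 0) stop("composite_screen: no candidates")
  if (length(candidates) > 20)
    warning("composite_screen: ", length(candidates),
            " candidates; exhaustive enumeration may be slow")
  candidates <- sort(candidates)
  v <- v[candidates, , drop = FALSE]
  member <- if (raw_sum) v else {
    t(vapply(candidates, function(f) {
      o <- feature_orientation(v[f, ], labels)$orientation
      as.numeric(scale(o * v[f, ]))
    }, numeric(ncol(v))))
  }
  rownames(member) <- candidates
  rows <- list()
  for (size in seq_len(min(max_size, length(candidates)))) {
    sets <- combn(candidates, size, simplify = FALSE)
    for (s in sets) {
      sc <- colSums(member[s, , drop = FALSE])
      fo <- feature_orientation(sc, labels)
      row <- data.frame(panel = paste(s, collapse = "+"), size = size,
                        auc = fo$auc, stringsAsFactors = FALSE)
      if (!is.null(covariates))
        row$auc_adjusted <- adjusted_auc(fo$orientation * sc, labels,
                                         covariates, scheme)$auc
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc, out$panel), ]
  rownames(out) <- NULL
  out
}

#' Published composite fracture-risk CpG panel
#'
#' Returns the four-CpG methylation panel reported as an effective
#' composite fracture-risk index, shipped so users can score their own
#' beta-value tables with it. These are probe ids on real arrays; any
#' values scored against them here are the user's own.
#'
#' @return character vector of CpG probe ids.
#' @export
published_fracture_panel <- function() {
  read_signature_file(system.file("extdata", "published_fracture_panel.tsv",
                                  package = "osteomix"))$feature_id
}

#' Published optimal M3S subsets for the risk models
#'
#' The reported optimal signature subsets: a five-feature panel
#' (microbiota genera and metabolites) for osteoporosis identification and
#' a sixteen-feature panel for subtype recognition.
#'
#' @param which `"osteoporosis"` or `"subtype"`.
#' @return data.frame: modality, feature_id.
#' @export
published_m3s_panel <- function(which = c("osteoporosis", "subtype")) {
  which <- match.arg(which)
  df <- read_signature_file(system.file("extdata", "published_m3s_panels.tsv",
                                        package = "osteomix"))
  df[df$panel == which, c("modality", "feature_id")]
}

read_signature_file <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
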