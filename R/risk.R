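# Logistic-regression risk models: nested tiers (Baseline I: conventional
# risk factors; Baseline II: + bone turnover markers; M3S model: + selected
# molecular signatures), mRMR feature selection on the training split only,
# ROC/AUC with DeLong confidence intervals, and decision-curve net benefit.

#' Specification of a nested risk-model tier
#'
#' @param tier `"baseline1"` (age, BMI, drinking, smoking), `"baseline2"`
#'   (baseline1 + beta-CTX, OST, PINP) or `"m3s"` (baseline2 + molecular
#'   signature features).
#' @param m3s_features character vector of molecular feature ids available
#'   to the m3s tier (mRMR picks among them on the training split).
#' @param n_m3s number of signature features mRMR retains.
#' @param include_gender add sex to every tier.
#' @param split_fraction training fraction of the stratified split.
#' @param seed split / selection seed.
#' @return list of class `risk_model_spec`.
#' @export
risk_model_spec <- function(tier = c("m3s", "baseline1", "baseline2"),
                            m3s_features = character(0), n_m3s = 5,
                            include_gender = FALSE, split_fraction = 0.7,
                            seed = 1L) {
  tier <- match.arg(tier)
  base1 <- c("age", "bmi", "drinking", "smoking")
  if (include_gender) base1 <- c(base1, "sex")
  base2 <- c(base1, "ctx", "ost", "pinp")
  features <- switch(tier, baseline1 = base1, baseline2 = base2,
                     m3s = base2)
  structure(list(tier = tier, clinical_features = features,
                 m3s_features = m3s_features, n_m3s = n_m3s,
                 include_gender = include_gender,
                 split_fraction = split_fraction, seed = seed),
            class = "risk_model_spec")
}

# -- mutual information on equal-frequency 4-bin discretization ------------

discretize_ef <- function(x, bins = 4) {
  if (length(unique(x)) <= bins) return(match(x, sort(unique(x))))
  qs <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                        type = 7))
  findInterval(x, qs[-c(1, length(qs))]) + 1L
}

mutual_information <- function(x, y, bins = 4) {
  dx <- if (is.numeric(x) && length(unique(x)) > bins)
    discretize_ef(x, bins) else as.integer(factor(x))
  dy <- if (is.numeric(y) && length(unique(y)) > bins)
    discretize_ef(y, bins) else as.integer(factor(y))
  tab <- table(dx, dy) / length(dx)
  px <- rowSums(tab); py <- colSums(tab)
  nz <- tab > 0
  sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
}

#' Greedy mRMR feature selection (MID criterion)
#'
#' First pick maximizes mutual information with the label; each subsequent
#' pick maximizes MI(feature; label) minus the mean MI with the already
#' selected features. MI is estimated on equal-frequency 4-bin
#' discretization; ties break lexicographically on the feature id, so the
#' selection is deterministic.
#'
#' @param features numeric sample x feature matrix or data.frame.
#' @param labels binary outcome vector.
#' @param n_select number of features to rank.
#' @param bins discretization bins.
#' @return character vector of selected feature names, in selection order.
#' @export
mrmr_select <- function(features, labels, n_select, bins = 4) {
  X <- as.matrix(features)
  stopifnot(n_select <= ncol(X), nrow(X) == length(labels))
  nms <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  colnames(X) <- nms
  rel <- vapply(nms, function(f) mutual_information(X[, f], labels, bins),
                numeric(1))
  selected <- character(0)
  red_cache <- matrix(NA_real_, ncol(X), ncol(X), dimnames = list(nms, nms))
  for (step in seq_len(n_select)) {
    pool <- setdiff(nms, selected)
    score <- vapply(pool, function(f) {
      if (length(selected) == 0) return(rel[f])
      red <- vapply(selected, function(s) {
        if (is.na(red_cache[f, s]))
          red_cache[f, s] <<- red_cache[s, f] <<-
            mutual_information(X[, f], X[, s], bins)
        red_cache[f, s]
      }, numeric(1))
      rel[f] - mean(red)
    }, numeric(1))
    best <- pool[order(-score, pool)][1]
    selected <- c(selected, best)
  }
  selected
}

# -- ridge-stabilized logistic regression ----------------------------------

#' Fit a logistic regression with a small ridge penalty
#'
#' IRLS maximum likelihood with an L2 penalty of `ridge` on the
#' standardized-scale slopes (the intercept is unpenalized), which keeps
#' the fit defined under perfect separation (a warning is raised).
#' Continuous inputs are standardized internally; coefficients are
#' reported on the original scale.
#'
#' @param x numeric sample x feature matrix.
#' @param y binary 0/1 outcome.
#' @param ridge L2 weight (default 1e-6).
#' @param max_iter,tol IRLS controls.
#' @return list of class `ridge_logistic`: `coefficients` (original
#'   scale, incl. intercept), `se` (Wald standard errors of the slopes on
#'   the original scale; `NA` for the intercept), `scaler`
#'   (centers/scales), `converged`.
#' @export
fit_logistic <- function(x, y, ridge = 1e-6, max_iter = 100, tol = 1e-10) {
  X <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), length(unique(y)) == 2)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd); scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  n <- nrow(Xs); p <- ncol(Xs)
  Z <- cbind(1, Xs)
  beta <- numeric(p + 1)
  pen <- diag(c(0, rep(ridge, p)))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Z, Z * w) + pen
    g <- crossprod(Z, y - mu) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(Z %*% beta)
  if (any(abs(eta) > 30))
    warning("fit_logistic: near-perfect separation; ridge-stabilized fit")
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  cov_std <- solve(crossprod(Z, Z * w) + pen)
  se_std <- sqrt(diag(cov_std))
  slopes <- beta[-1] / scl
  intercept <- beta[1] - sum(beta[-1] * ctr / scl)
  nms <- colnames(X) %||% paste0("x", seq_len(p))
  cf <- c(`(Intercept)` = intercept, setNames(slopes, nms))
  se <- c(`(Intercept)` = NA_real_, setNames(se_std[-1] / scl, nms))
  structure(list(coefficients = cf, se = se,
                 scaler = list(center = ctr, scale = scl),
                 converged = converged, features = colnames(X)),
            class = "ridge_logistic")
}

#' @export
predict.ridge_logistic <- function(object, newdata, type = "response", ...) {
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  eta <- drop(cbind(1, X) %*% object$coefficients)
  if (type == "response") plogis(eta) else eta
}

#' Area under the ROC curve with DeLong confidence interval
#'
#' AUC is the Mann-Whitney U statistic scaled by n1*n0, counting ties as
#' one half; the 95\% confidence interval uses DeLong's method (via
#' \pkg{pROC}).
#'
#' @param scores numeric risk scores.
#' @param labels binary 0/1 outcome.
#' @param ci compute the DeLong interval.
#' @return list: `auc`, `ci` (length-2 or NULL), `n_pos`, `n_neg`.
#' @export
auc <- function(scores, labels, ci = FALSE) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("auc: one class absent")
  r <- rank(scores)                      # midranks handle ties as 1/2
  a <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  interval <- NULL
  if (ci) {
    ro <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
    interval <- as.numeric(pROC::ci.auc(ro, method = "delong"))[c(1, 3)]
  }
  list(auc = a, ci = interval, n_pos = n1, n_neg = n0)
}

#' ROC curve points
#' @param scores,labels as in [auc()].
#' @return data.frame of (fpr, tpr) sorted with monotone non-decreasing tpr.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.numeric(labels)
  o <- order(scores, decreasing = TRUE)
  tp <- cumsum(labels[o] == 1); fp <- cumsum(labels[o] == 0)
  data.frame(fpr = c(0, fp / sum(labels == 0)),
             tpr = c(0, tp / sum(labels == 1)))
}

#' Decision-curve net benefit
#'
#' NB(pt) = TP/n - (FP/n) * pt/(1-pt) for the rule score >= pt, with the
#' treat-all and treat-none reference policies.
#'
#' @param scores predicted probabilities.
#' @param labels binary outcome.
#' @param thresholds probability thresholds in (0, 1).
#' @return data.frame: threshold, net_benefit, treat_all, treat_none.
#' @export
decision_curve <- function(scores, labels,
                           thresholds = seq(0.05, 0.6, by = 0.05)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("decision_curve: thresholds must lie strictly in (0, 1)")
  labels <- as.numeric(labels)
  n <- length(labels)
  prev <- mean(labels)
  out <- lapply(thresholds, function(pt) {
    flag <- scores >= pt
    tp <- sum(flag & labels == 1); fp <- sum(flag & labels == 0)
    odds <- pt / (1 - pt)
    data.frame(threshold = pt,
               net_benefit = tp / n - (fp / n) * odds,
               treat_all = prev - (1 - prev) * odds,
               treat_none = 0)
  })
  do.call(rbind, out)
}

#' Train and evaluate a risk-model tier on a stratified split
#'
#' Draws a seed-fixed stratified 70/30 split, runs mRMR on the training
#' split only (m3s tier), fits the ridge-stabilized logistic model on the
#' training data and reports all metrics on the held-out split (and on an
#' optional external table).
#'
#' @param spec a [risk_model_spec()].
#' @param data data.frame containing the outcome column, the tier's
#'   clinical columns and any m3s feature columns.
#' @param outcome name of the binary outcome column.
#' @param external optional external data.frame with the same columns.
#' @return list of class `model_evaluation`: `tier`, `model`,
#'   `selected_m3s`, `train_auc`, `test_auc` (each with DeLong CI),
#'   `roc`, `decision_curve`, `split` (train/test ids),
#'   `external_auc` (or NULL).
#' @export
train_eval <- function(spec, data, outcome = "outcome", external = NULL) {
  y <- data[[outcome]]
  stopifnot(all(y %in% 0:1))
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  if (length(idx1) < 4 || length(idx0) < 4)
    stop("train_eval: too few samples per class for a stratified split")
  tr <- with_seed(spec$seed, c(
    sample(idx1, round(spec$split_fraction * length(idx1))),
    sample(idx0, round(spec$split_fraction * length(idx0)))))
  tr <- sort(tr); te <- setdiff(seq_along(y), tr)
  if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2)
    stop("train_eval: a split lost one outcome class")
  feats <- spec$clinical_features
  selected <- character(0)
  if (spec$tier == "m3s" && length(spec$m3s_features) > 0) {
    n_sel <- min(spec$n_m3s, length(spec$m3s_features))
    selected <- mrmr_select(data[tr, spec$m3s_features, drop = FALSE],
                            y[tr], n_sel)
    feats <- c(feats, selected)
  }
  model <- fit_logistic(data[tr, feats, drop = FALSE], y[tr])
  p_tr <- predict(model, data[tr, feats, drop = FALSE])
  p_te <- predict(model, data[te, feats, drop = FALSE])
  ext_auc <- NULL
  if (!is.null(external)) {
    p_ext <- predict(model, external[, feats, drop = FALSE])
    ext_auc <- auc(p_ext, external[[outcome]], ci = TRUE)
  }
  structure(list(tier = spec$tier, model = model, selected_m3s = selected,
                 train_auc = auc(p_tr, y[tr], ci = TRUE),
                 test_auc = auc(p_te, y[te], ci = TRUE),
                 roc = roc_points(p_te, y[te]),
                 decision_curve = decision_curve(p_te, y[te]),
                 split = list(train = tr, test = te),
                 external_auc = ext_auc),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("<model_evaluation> tier = %s: train AUC %.3f, test AUC %.3f\n",
              x$tier, x$train_auc$auc, x$test_auc$auc))
  invisible(x)
}
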