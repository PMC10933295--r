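# Independent brute-force oracles used to validate the fast implementations.

# AUC by explicit pair counting over all positive-negative pairs.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Exact Hardy-Weinberg p-value by direct evaluation of the conditional
# probability of every feasible heterozygote configuration via lgamma.
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab; nb <- 2 * n_bb + n_ab
  rare <- min(na, nb)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (rare - h) / 2; hc <- (na + nb - rare - h) / 2
    lgamma(n + 1) - lgamma(hr + 1) - lgamma(hc + 1) - lgamma(h + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(na + nb - rare + 1) -
      lgamma(na + nb + 1)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[hets == n_ab]
  sum(p[p <= obs * (1 + 1e-12)])
}

# Two-sided exact Wilcoxon rank-sum p-value by enumeration of all
# choose(n1+n2, n1) assignments of ranks to group 1 (untied data).
oracle_wilcoxon_exact <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(n, n1)
  w_all <- apply(combos, 2L, function(i) sum(i) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# RV coefficient by naive elementwise double loops over the trace formulas.
oracle_rv <- function(x, y) {
  x <- sweep(x, 2, colMeans(x)); y <- sweep(y, 2, colMeans(y))
  sx <- x %*% t(x); sy <- y %*% t(y)
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(nrow(sx))) for (j in seq_len(ncol(sx))) {
    num <- num + sx[i, j] * sy[j, i]
    dx <- dx + sx[i, j] * sx[j, i]
    dy <- dy + sy[i, j] * sy[j, i]
  }
  num / sqrt(dx * dy)
}

# Spearman rho and p per pair via cor.test on ranked data.
oracle_spearman <- function(x, y) {
  out_r <- matrix(NA_real_, nrow(x), nrow(y))
  out_p <- out_r
  for (i in seq_len(nrow(x))) for (j in seq_len(nrow(y))) {
    rho <- cor(x[i, ], y[j, ], method = "spearman")
    n <- ncol(x)
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    out_r[i, j] <- rho
    out_p[i, j] <- 2 * pt(abs(tt), n - 2, lower.tail = FALSE)
  }
  list(rho = out_r, p = out_p)
}

# OLS beta and se of the first regressor from the normal equations.
oracle_ols <- function(y, X) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  s2 <- sum(res^2) / (length(y) - ncol(X))
  se <- sqrt(s2 * solve(XtX)[1, 1])
  c(beta = b[1], se = se)
}

# ARI by brute-force counting of concordant/discordant sample pairs.
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- choose(n, 2)
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(0)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# Zero-diagonal ridge self-expression by per-column constrained solves.
oracle_self_expression <- function(Z, alpha) {
  n <- ncol(Z)
  C <- matrix(0, n, n)
  for (j in seq_len(n)) {
    Zj <- Z[, -j, drop = FALSE]
    cj <- solve(t(Zj) %*% Zj + alpha * diag(n - 1), t(Zj) %*% Z[, j])
    C[-j, j] <- cj
  }
  C
}
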