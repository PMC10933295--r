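# Deep latent space fusion (DLSF): per-modality autoencoders with a
# self-expression layer. Each modality m is encoded to a latent Z_m and
# decoded back; writing Xhat_m = Dec_m(Z_m), training minimizes
#
#   sum_m  lambda_rec ||X_m - Xhat_m||^2 / n
#        + lambda_se  ||Xhat_m - Xhat_m C_m||^2 / n
#        + lambda_reg ||C_m||^2,        diag(C_m) = 0,
#
# in two phases: reconstruction-only pretraining, then joint optimization in
# which the network weights take Adam gradient steps while each C_m is reset
# to its exact ridge minimizer (zero-diagonal least-squares regression).
# The self-expression acts on the decoder image of the latent code rather
# than on the raw code coordinates: the code is identified only up to an
# invertible mixing, which scrambles inner products, whereas the decoder
# output inherits the data's variance structure through the reconstruction
# loss and therefore carries a meaningful sample geometry. The positive
# parts of the C_m are fused into one sample affinity that spectral
# clustering cuts into candidate subtypes.

#' DLSF training configuration
#'
#' @param latent_dim latent dimension per modality.
#' @param hidden_dim hidden layer width (capped at the modality's feature
#'   count).
#' @param epochs_pretrain,epochs_joint epochs of the reconstruction-only and
#'   joint phases.
#' @param learning_rate Adam step size.
#' @param lambda_rec,lambda_se,lambda_reg loss weights (reconstruction,
#'   self-expression, coefficient ridge).
#' @param k_range candidate cluster counts for [select_k()].
#' @param balance_floor minimum cluster balance a k must reach in
#'   [select_k()].
#' @param seed integer seed controlling initialization.
#' @return list of class `dlsf_config`.
#' @export
dlsf_config <- function(latent_dim = 32, hidden_dim = 128,
                        epochs_pretrain = 200, epochs_joint = 300,
                        learning_rate = 1e-3,
                        lambda_rec = 1, lambda_se = 1, lambda_reg = 20,
                        k_range = 2:4, balance_floor = 0.25, seed = 1L) {
  stopifnot(latent_dim >= 2, hidden_dim >= latent_dim,
            lambda_rec >= 0, lambda_se >= 0, lambda_reg >= 0,
            all(k_range >= 2))
  structure(as.list(environment()), class = "dlsf_config")
}

adam_init <- function(par) list(m = lapply(par, function(p) p * 0),
                                v = lapply(par, function(p) p * 0), t = 0)

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grad)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grad[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

init_autoencoder <- function(p, h, d, seed) {
  with_seed(seed, {
    xavier <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / (nr + nc))),
                                      nr, nc)
    list(W1 = xavier(h, p), b1 = numeric(h),
         W2 = xavier(d, h), b2 = numeric(d),
         W3 = xavier(h, d), b3 = numeric(h),
         W4 = xavier(p, h), b4 = numeric(p))
  })
}

ae_forward <- function(par, X) {
  H1 <- tanh(par$W1 %*% X + par$b1)
  Z <- par$W2 %*% H1 + par$b2
  H2 <- tanh(par$W3 %*% Z + par$b3)
  Xhat <- par$W4 %*% H2 + par$b4
  list(H1 = H1, Z = Z, H2 = H2, Xhat = Xhat)
}

# Full-batch gradients. dXhat_extra is an externally supplied gradient on
# the reconstruction (the self-expression pull); NULL during pretraining.
ae_backward <- function(par, X, fw, lambda_rec, dXhat_extra = NULL) {
  n <- ncol(X)
  G <- (2 * lambda_rec / n) * (fw$Xhat - X)
  if (!is.null(dXhat_extra)) G <- G + dXhat_extra
  gW4 <- G %*% t(fw$H2); gb4 <- rowSums(G)
  dA3 <- (t(par$W4) %*% G) * (1 - fw$H2^2)
  gW3 <- dA3 %*% t(fw$Z); gb3 <- rowSums(dA3)
  dZ <- t(par$W3) %*% dA3
  gW2 <- dZ %*% t(fw$H1); gb2 <- rowSums(dZ)
  dA1 <- (t(par$W2) %*% dZ) * (1 - fw$H1^2)
  gW1 <- dA1 %*% t(X); gb1 <- rowSums(dA1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

#' Exact zero-diagonal ridge self-expression
#'
#' Solves min_C ||Z - Z C||^2 + alpha ||C||^2 subject to diag(C) = 0 in
#' closed form (Lagrange correction of the unconstrained ridge solution,
#' working through whichever Gram matrix -- feature side or sample side --
#' is smaller).
#'
#' @param Z representation matrix, dimensions x samples.
#' @param alpha ridge weight (> 0).
#' @return n x n coefficient matrix with zero diagonal.
#' @export
self_expression_ridge <- function(Z, alpha) {
  stopifnot(alpha > 0)
  n <- ncol(Z)
  K <- crossprod(Z)                            # Z'Z, n x n
  if (nrow(Z) < n) {
    small <- solve(tcrossprod(Z) + alpha * diag(nrow(Z)))  # (ZZ'+aI)^-1
    A <- (diag(n) - crossprod(Z, small %*% Z)) / alpha     # (Z'Z+aI)^-1
  } else {
    A <- solve(K + alpha * diag(n))
  }
  Cstar <- A %*% K
  # impose c_jj = 0 column-wise: c_j <- c_j - (c*_jj / A_jj) * A[, j]
  corr <- diag(Cstar) / diag(A)
  C <- Cstar - sweep(A, 2L, corr, "*")
  diag(C) <- 0
  dimnames(C) <- list(colnames(Z), colnames(Z))
  C
}

#' Train the DLSF model
#'
#' @param omics list of [omics_matrix()] objects (or plain feature x sample
#'   matrices) over identical, aligned samples. Each modality is moved to
#'   its analysis scale and feature-standardized before encoding.
#' @param config a [dlsf_config()].
#' @return list of class `dlsf_fit`: `latents` (latent_dim x n per
#'   modality), `C` (zero-diagonal self-expression matrix per modality,
#'   solved in the decoder's reconstruction space), `losses` (per-epoch
#'   totals per modality), `config`.
#' @export
train_dlsf <- function(omics, config = dlsf_config()) {
  stopifnot(length(omics) >= 1)
  mats <- lapply(omics, function(o) {
    v <- if (inherits(o, "omics_matrix")) analysis_scale(o) else as.matrix(o)
    standardize_rows(v)
  })
  ns <- vapply(mats, ncol, integer(1))
  if (length(unique(ns)) != 1) stop("train_dlsf: sample counts differ")
  n <- ns[1]
  if (n < config$latent_dim)
    stop("train_dlsf: fewer samples than latent dimensions")
  fits <- vector("list", length(mats))
  names(fits) <- names(mats)
  for (mi in seq_along(mats)) {
    X <- mats[[mi]]
    p <- nrow(X); h <- min(config$hidden_dim, p); d <- config$latent_dim
    par <- init_autoencoder(p, h, d, config$seed + 1000L * mi)
    st <- adam_init(par)
    Cm <- matrix(0, n, n)
    losses <- numeric(config$epochs_pretrain + config$epochs_joint)
    alpha <- n * config$lambda_reg / max(config$lambda_se, 1e-12)
    for (ep in seq_along(losses)) {
      joint <- ep > config$epochs_pretrain
      fw <- ae_forward(par, X)
      dXhat_extra <- NULL
      l_se <- 0
      if (joint && config$lambda_se > 0) {
        if (ep %% 10 == 1 || ep == config$epochs_pretrain + 1)
          Cm <- self_expression_ridge(fw$Xhat, alpha)
        Rm <- fw$Xhat - fw$Xhat %*% Cm
        dXhat_extra <- (2 * config$lambda_se / n) * (Rm %*% t(diag(n) - Cm))
        l_se <- config$lambda_se * sum(Rm^2) / n +
          config$lambda_reg * sum(Cm^2)
      }
      l_rec <- config$lambda_rec * sum((fw$Xhat - X)^2) / n
      losses[ep] <- l_rec + l_se
      if (!is.finite(losses[ep]))
        stop("train_dlsf: non-finite loss at epoch ", ep,
             " (modality ", names(mats)[mi] %||% mi, ")")
      gr <- ae_backward(par, X, fw, config$lambda_rec, dXhat_extra)
      up <- adam_step(par, gr, st, config$learning_rate)
      par <- up$par; st <- up$state
    }
    fw <- ae_forward(par, X)
    Z <- fw$Z
    colnames(Z) <- colnames(X)
    if (config$lambda_se > 0) Cm <- self_expression_ridge(fw$Xhat, alpha)
    dimnames(Cm) <- list(colnames(X), colnames(X))
    fits[[mi]] <- list(Z = Z, C = Cm, losses = losses)
  }
  structure(list(latents = lapply(fits, `[[`, "Z"),
                 C = lapply(fits, `[[`, "C"),
                 losses = lapply(fits, `[[`, "losses"),
                 config = config),
            class = "dlsf_fit")
}

#' Fuse per-modality self-expression matrices into one sample affinity
#'
#' Each coefficient matrix is symmetrized on its positive part,
#' S_m = relu(C_m) + relu(C_m)', scaled to unit maximum, and the fused
#' affinity is the mean over modalities. Only positive self-expression
#' weights are treated as evidence of similarity: a sample represented
#' with a negative coefficient sits on the opposite side of the latent
#' configuration, so folding it in by absolute value would wire
#' mean-separated clusters together. The result is symmetric,
#' non-negative, zero-diagonal.
#'
#' @param C_list list of n x n self-expression matrices.
#' @return list of class `fused_affinity`: `S` and `provenance` (the
#'   normalized per-modality contributions).
#' @export
fuse_affinities <- function(C_list) {
  if (is.matrix(C_list)) C_list <- list(C_list)
  stopifnot(length(C_list) >= 1)
  n <- ncol(C_list[[1]])
  contrib <- lapply(C_list, function(C) {
    if (!is.matrix(C) || ncol(C) != n || nrow(C) != n)
      stop("fuse_affinities: dimension mismatch")
    W <- pmax(C, 0) + t(pmax(C, 0))
    diag(W) <- 0
    mx <- max(W)
    if (mx > 0) W <- W / mx
    W
  })
  S <- Reduce(`+`, contrib) / length(contrib)
  structure(list(S = S, provenance = contrib), class = "fused_affinity")
}

graph_components <- function(S) {
  n <- nrow(S)
  comp <- integer(n); cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cur
      queue <- c(queue, which(S[v, ] > 0 & comp == 0L))
    }
  }
  comp
}

#' Normalized-cut spectral clustering of a fused affinity
#'
#' Symmetric-normalized Laplacian, bottom-k eigenvectors, row normalization,
#' then k-means with a fixed seed and 50 restarts.
#'
#' @param S a `fused_affinity` or symmetric non-negative matrix.
#' @param k number of clusters (>= 2).
#' @param seed seed for the k-means restarts.
#' @return list of class `subtype_assignment`: `sample_ids`, `labels`
#'   (integers 1..k), `k`, `affinity`.
#' @export
spectral_cluster <- function(S, k, seed = 1L) {
  if (inherits(S, "fused_affinity")) S <- S$S
  n <- nrow(S)
  if (k < 2) stop("spectral_cluster: k must be >= 2")
  if (k > n) stop("spectral_cluster: k exceeds sample count")
  comp <- graph_components(S)
  if (max(comp) > k)
    stop("spectral_cluster: affinity graph has ", max(comp),
         " connected components but k = ", k,
         " (components of sizes ", paste(tabulate(comp), collapse = ", "), ")")
  deg <- pmax(rowSums(S), 1e-12)
  Dhalf <- 1 / sqrt(deg)
  M <- S * tcrossprod(Dhalf)       # D^-1/2 S D^-1/2
  ev <- eigen(M, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2)); rn[rn == 0] <- 1
  U <- U / rn
  km <- with_seed(seed, kmeans(U, centers = k, nstart = 50, iter.max = 100))
  labels <- km$cluster
  # stable relabeling: clusters numbered by first appearance
  labels <- match(labels, unique(labels))
  structure(list(sample_ids = rownames(S) %||% paste0("s", seq_len(n)),
                 labels = labels, k = k, affinity = S),
            class = "subtype_assignment")
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat(sprintf("<subtype_assignment> k = %d; cluster sizes: %s\n", x$k,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

#' Choose the cluster count by balance and phenotype associations
#'
#' For each candidate k, clusters the fused affinity, computes the balance
#' index and the number of clinical phenotypes associated at alpha; picks
#' the k with the most associations among those whose balance clears
#' `balance_floor` (ties break to the smaller k).
#'
#' @param S a `fused_affinity` or affinity matrix.
#' @param k_range candidate cluster counts.
#' @param phenotypes a [phenotype_table()] over the clustered samples.
#' @param pheno_cols phenotype columns to test (defaults to all clinical
#'   columns present).
#' @param alpha association threshold.
#' @param balance_floor minimum acceptable balance.
#' @param seed clustering seed.
#' @return list: `k_star`, `report` (per-k data.frame), `assignments`
#'   (per-k `subtype_assignment`s).
#' @export
select_k <- function(S, k_range, phenotypes, pheno_cols = NULL,
                     alpha = 0.05, balance_floor = 0.25, seed = 1L) {
  if (length(k_range) == 0) stop("select_k: empty k_range")
  assignments <- list(); rows <- list()
  for (k in sort(k_range)) {
    asg <- spectral_cluster(S, k, seed = seed)
    bal <- balance_index(asg$labels)
    assoc <- phenotype_association_count(asg$labels, phenotypes,
                                         pheno_cols = pheno_cols,
                                         alpha = alpha)
    assignments[[as.character(k)]] <- asg
    rows[[as.character(k)]] <- data.frame(k = k, balance = bal,
                                          n_associated = assoc$count)
  }
  report <- do.call(rbind, rows)
  eligible <- report$balance >= balance_floor
  if (!any(eligible)) {
    warning("select_k: no k reaches balance_floor; selecting among all k")
    eligible <- rep(TRUE, nrow(report))
  }
  cand <- report[eligible, , drop = FALSE]
  k_star <- cand$k[order(-cand$n_associated, cand$k)][1]
  list(k_star = k_star, report = report, assignments = assignments)
}

#' End-to-end DLSF subtyping of a multi-omics cohort
#'
#' Aligns the modalities and phenotypes, optionally restricts to the
#' osteoporosis group, trains the DLSF model, fuses the self-expression
#' affinities and selects k.
#'
#' @param omics named list of [omics_matrix()] objects.
#' @param phenotypes a [phenotype_table()].
#' @param config a [dlsf_config()].
#' @param population `"op"` (osteoporosis samples only, the default) or
#'   `"all"`.
#' @param k fixed cluster count; if `NULL`, chosen by [select_k()].
#' @return list of class `dlsf_result`: `assignment`, `fit`, `affinity`,
#'   `selection` (NULL when k fixed), `population`.
#' @export
dlsf_subtype <- function(omics, phenotypes, config = dlsf_config(),
                         population = c("op", "all"), k = NULL) {
  population <- match.arg(population)
  al <- do.call(align_samples, c(list(phenotypes), unname(omics)))
  phenotypes <- al[[1]]; omics_al <- al[-1]
  names(omics_al) <- names(omics)
  if (population == "op") {
    keep <- phenotypes$sample_id[phenotypes$group == "osteoporosis"]
    phenotypes <- subset_samples(phenotypes, keep)
    omics_al <- lapply(omics_al, subset_samples, ids = keep)
  }
  fit <- train_dlsf(omics_al, config)
  S <- fuse_affinities(fit$C)
  rownames(S$S) <- colnames(S$S) <- phenotypes$sample_id
  selection <- NULL
  if (is.null(k)) {
    selection <- select_k(S, config$k_range, phenotypes,
                          balance_floor = config$balance_floor,
                          seed = config$seed)
    assignment <- selection$assignments[[as.character(selection$k_star)]]
  } else {
    assignment <- spectral_cluster(S, k, seed = config$seed)
  }
  structure(list(assignment = assignment, fit = fit, affinity = S,
                 selection = selection, population = population),
            class = "dlsf_result")
}
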