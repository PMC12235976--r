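#' One-hot allele-count design matrix
#'
#' Expands a genotype matrix to individuals x alleles counts (0/1/2).
#' Missing calls become `NA` across the locus's columns and are imputed
#' with the column mean.
#'
#' @param m a [genotype_matrix()].
#' @return numeric matrix with columns named `<locus>.<allele>`.
#' @export
allele_design <- function(m) {
  cols <- list()
  for (j in seq_len(ncol(m$a1))) {
    al <- sort(unique(stats::na.omit(c(m$a1[, j], m$a2[, j]))))
    if (!length(al)) next
    block <- matrix(NA_real_, nrow(m$a1), length(al),
                    dimnames = list(gm_samples(m),
                                    paste(gm_loci(m)[j], al, sep = ".")))
    typed <- !is.na(m$a1[, j])
    for (k in seq_along(al)) {
      block[typed, k] <- (m$a1[typed, j] == al[k]) + (m$a2[typed, j] == al[k])
    }
    cols[[length(cols) + 1L]] <- block
  }
  x <- do.call(cbind, cols)
  # column-mean imputation of missing cells
  for (k in seq_len(ncol(x))) {
    nas <- is.na(x[, k])
    if (any(nas)) x[nas, k] <- mean(x[!nas, k])
  }
  x
}

#' Discriminant analysis of principal components
#'
#' PCA on the centered one-hot allele-count matrix, retaining `n_pca` axes,
#' followed by linear discriminant analysis of the retained scores on the
#' group labels. Membership probabilities are the Gaussian
#' class-conditional posteriors with pooled covariance (the LDA posterior).
#' Axis sign indeterminacy is resolved by forcing the largest-magnitude
#' loading of every PCA and DA axis positive, so runs are reproducible.
#'
#' @param m a [genotype_matrix()].
#' @param groups factor/character of group labels; defaults to the
#'   populations of `m`.
#' @param n_pca number of PCA axes to retain (default 4; reduced with a
#'   warning if the design rank is lower).
#' @param n_da number of discriminant axes (default 4; capped at
#'   `min(n_groups - 1, n_pca)`).
#' @return object of class `dapc_model`: `coordinates` (individuals x DA
#'   axes), `membership` (rows sum to 1), `assigned`, `pca_loadings`,
#'   `da_loadings`, `groups`, `n_pca`, `n_da`, `pca_scores`,
#'   `explained_var`.
#' @export
dapc_fit <- function(m, groups = gm_populations(m), n_pca = 4L, n_da = 4L) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  x <- allele_design(m)
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  sv <- svd(xc)
  rank <- sum(sv$d > max(dim(xc)) * .Machine$double.eps * sv$d[1])
  if (rank < 1L) stop("degenerate design: no variation between individuals")
  if (n_pca > rank) {
    warning("n_pca reduced to design rank ", rank)
    n_pca <- rank
  }
  load <- sv$v[, seq_len(n_pca), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (k in seq_len(ncol(load))) {
    i <- which.max(abs(load[, k]))
    if (load[i, k] < 0) load[, k] <- -load[, k]
  }
  scores <- xc %*% load
  colnames(scores) <- paste0("PC", seq_len(n_pca))
  n_da <- min(n_da, nlevels(groups) - 1L, n_pca)
  fit <- MASS::lda(scores, grouping = groups)
  da_load <- fit$scaling[, seq_len(n_da), drop = FALSE]
  for (k in seq_len(ncol(da_load))) {
    i <- which.max(abs(da_load[, k]))
    if (da_load[i, k] < 0) da_load[, k] <- -da_load[, k]
  }
  pr <- stats::predict(fit, as.data.frame(scores))
  # scores are column-centered already (xc is centered), so DA coordinates
  # are a plain projection
  coords <- scores %*% da_load
  colnames(coords) <- paste0("LD", seq_len(n_da))
  membership <- pr$posterior
  structure(list(
    coordinates = coords,
    membership = membership,
    assigned = factor(colnames(membership)[max.col(membership)],
                      levels = levels(groups)),
    pca_loadings = load,
    da_loadings = da_load,
    centering = ctr,
    groups = groups,
    n_pca = n_pca, n_da = n_da,
    pca_scores = scores,
    explained_var = sv$d^2 / sum(sv$d^2)
  ), class = "dapc_model")
}

#' @export
print.dapc_model <- function(x, ...) {
  acc <- mean(x$assigned == x$groups)
  cat(sprintf("DAPC: %d individuals, %d groups, %d PCA + %d DA axes\n",
              nrow(x$coordinates), nlevels(x$groups), x$n_pca, x$n_da))
  cat(sprintf("  reassignment to own group: %.1f%%\n", 100 * acc))
  invisible(x)
}

#' @export
plot.dapc_model <- function(x, axes = c(1, 2), ...) {
  a <- min(axes[1], ncol(x$coordinates))
  b <- min(axes[2], ncol(x$coordinates))
  plot(x$coordinates[, a], x$coordinates[, b],
       col = as.integer(x$groups), pch = 19,
       xlab = colnames(x$coordinates)[a], ylab = colnames(x$coordinates)[b],
       ...)
  invisible(x)
}

#' DAPC on populations downsampled to equal size
#'
#' Each group larger than `n_per_group` is sampled down to `n_per_group`
#' individuals without replacement (seeded); groups at or below the target
#' are kept whole.
#'
#' @inheritParams dapc_fit
#' @param n_per_group target group size (default 5).
#' @param seed RNG seed for the subsampling.
#' @return a `dapc_model` with an extra element `sampled_ids`.
#' @export
dapc_downsample <- function(m, groups = gm_populations(m), n_per_group = 5L,
                            seed = 1L, n_pca = 4L, n_da = 4L) {
  groups <- factor(groups)
  set.seed(seed)
  keep <- integer()
  for (g in levels(groups)) {
    idx <- which(groups == g)
    if (length(idx) > n_per_group) idx <- sort(sample(idx, n_per_group))
    keep <- c(keep, idx)
  }
  keep <- sort(keep)
  fit <- dapc_fit(m[keep, ], groups = groups[keep], n_pca = n_pca, n_da = n_da)
  fit$sampled_ids <- gm_samples(m)[keep]
  fit
}

#' Evanno delta-K from clustering run log-likelihoods
#'
#' `DeltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`,
#' defined for interior K with positive run-to-run standard deviation.
#' Consumes any admixture program's output as a K -> log-likelihoods table.
#'
#' @param runs named list mapping K (coercible to integer) to a numeric
#'   vector of per-run log-likelihoods (>= 2 runs per K), or a data.frame
#'   with columns `K` and `logL`.
#' @return data.frame `K`, `n_runs`, `mean_L`, `sd_L`, `delta_K` with
#'   attribute `best_K` (argmax of delta_K among defined values).
#' @export
evanno_delta_k <- function(runs) {
  if (is.data.frame(runs)) {
    runs <- split(runs$logL, runs$K)
  }
  ks <- as.integer(names(runs))
  ord <- order(ks)
  ks <- ks[ord]; runs <- runs[ord]
  if (length(ks) < 3L) stop("need at least three consecutive K values")
  if (any(diff(ks) != 1L)) stop("K values must be consecutive")
  if (any(lengths(runs) < 2L)) stop("need >= 2 runs per K to estimate sd")
  mu <- vapply(runs, mean, 0)
  sdv <- vapply(runs, stats::sd, 0)
  dk <- rep(NA_real_, length(ks))
  for (i in seq(2L, length(ks) - 1L)) {
    if (sdv[i] > 0) {
      dk[i] <- abs(mu[i + 1] - 2 * mu[i] + mu[i - 1]) / sdv[i]
    }
  }
  out <- data.frame(K = ks, n_runs = lengths(runs), mean_L = mu, sd_L = sdv,
                    delta_K = dk, row.names = NULL)
  if (any(!is.na(dk))) attr(out, "best_K") <- ks[which.max(dk)]
  out
}
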