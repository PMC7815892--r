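# Local-similarity imputers: k-nearest neighbours and local least squares.
# Both treat proteins (rows) as the objects among which similarity is
# measured, matching the "number of similar proteins" parameter semantics.

#' k-nearest-neighbour imputation
#'
#' For a protein missing in sample `j`, candidate neighbours are proteins
#' observed in `j` that share at least one co-observed sample with the
#' target. Distance is the Euclidean distance over co-observed samples,
#' scaled by `sqrt(n_samples / n_co-observed)` to make distances comparable
#' across different overlap sizes. The imputed value is the unweighted mean
#' of the `k` nearest candidates' values in sample `j`. Fewer than `k`
#' candidates: all are used; none: the row mean of the target's observed
#' values (counted as a fallback).
#'
#' @inheritParams impute_lod
#' @return An `imputed_matrix`; `diagnostics$fallbacks` counts row-mean
#'   fallback entries.
#' @export
impute_knn <- function(md, config = imputation_config("KNN")) {
  md <- as_masked(md)
  X <- md$observed
  n <- nrow(X); p <- ncol(X)
  if (config$k_neighbors >= n) stop("`k_neighbors` must be below the row count")

  # Pairwise scaled squared distances over co-observed columns, by
  # cross-products on the zero-filled matrix.
  W <- 1 * !is.na(X)
  X0 <- X; X0[is.na(X)] <- 0
  A <- X0 * X0
  shared <- W %*% t(W)
  ss <- A %*% t(W) + W %*% t(A) - 2 * X0 %*% t(X0)
  ss[ss < 0] <- 0                     # numerical noise
  d2 <- ifelse(shared > 0, ss * (p / pmax(shared, 1L)), Inf)
  diag(d2) <- Inf

  vals <- X
  fallbacks <- 0L
  row_means <- rowMeans(X, na.rm = TRUE)
  targets <- which(rowSums(md$mask) > 0L)
  for (i in targets) {
    di <- d2[i, ]
    for (j in which(md$mask[i, ])) {
      cand <- which(!is.na(X[, j]) & is.finite(di))
      if (length(cand) == 0L) {
        vals[i, j] <- row_means[i]
        fallbacks <- fallbacks + 1L
        next
      }
      k <- min(config$k_neighbors, length(cand))
      nearest <- cand[order(di[cand])[seq_len(k)]]
      vals[i, j] <- mean(X[nearest, j])
    }
  }
  new_imputed(vals, config, list(fallbacks = fallbacks))
}

#' Local least squares imputation
#'
#' For each protein with missing entries, the `k_similar` most similar
#' proteins are selected by absolute Pearson correlation over the target's
#' observed samples, and the target's observed values are expressed as a
#' linear combination of the neighbours' values in those samples. The
#' (generally underdetermined) least-squares system is solved by the
#' minimum-norm pseudoinverse solution, and missing entries are predicted
#' from the neighbours' values in the missing samples.
#'
#' Because few proteins are fully observed at realistic missingness rates,
#' neighbour values are taken from a working copy of the matrix whose own
#' missing entries are initialized with row means (all-variables strategy);
#' only the target's genuinely observed values constrain the regression.
#' Targets with fewer than two usable neighbours fall back to row-mean
#' imputation, counted in the diagnostics.
#'
#' @inheritParams impute_lod
#' @return An `imputed_matrix`; `diagnostics$fallbacks` counts row-mean
#'   fallback entries.
#' @export
impute_lls <- function(md, config = imputation_config("LLS")) {
  md <- as_masked(md)
  X <- md$observed
  n <- nrow(X); p <- ncol(X)
  row_means <- rowMeans(X, na.rm = TRUE)
  Wk <- X
  for (i in seq_len(n)) Wk[i, is.na(X[i, ])] <- row_means[i]

  Wc <- Wk - rowMeans(Wk)             # row-centered for correlations
  vals <- X
  fallbacks <- 0L
  targets <- which(rowSums(md$mask) > 0L)
  for (i in targets) {
    oc <- which(!md$mask[i, ])
    mc <- which(md$mask[i, ])
    if (length(oc) < 2L) {
      vals[i, mc] <- row_means[i]
      fallbacks <- fallbacks + length(mc)
      next
    }
    y <- X[i, oc]
    # |Pearson correlation| between the target and every protein over the
    # target's observed samples.
    B <- Wk[, oc, drop = FALSE]
    Bc <- B - rowMeans(B)
    bnorm <- sqrt(rowSums(Bc^2))
    yc <- y - mean(y)
    ynorm <- sqrt(sum(yc^2))
    r <- if (ynorm == 0) rep(NA_real_, n) else (Bc %*% yc)[, 1L] / (bnorm * ynorm)
    r[i] <- NA_real_
    r[!is.finite(r)] <- NA_real_
    usable <- which(!is.na(r))
    if (length(usable) < 2L) {
      vals[i, mc] <- row_means[i]
      fallbacks <- fallbacks + length(mc)
      next
    }
    k <- min(config$k_similar, length(usable))
    nbrs <- usable[order(-abs(r[usable]))[seq_len(k)]]
    A <- t(Wk[nbrs, oc, drop = FALSE])   # |oc| x k
    w <- pinv(A) %*% y
    pred <- t(Wk[nbrs, mc, drop = FALSE]) %*% w
    vals[i, mc] <- pred[, 1L]
  }
  new_imputed(vals, config, list(fallbacks = fallbacks))
}
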