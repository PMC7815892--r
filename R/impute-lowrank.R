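# Global-structure imputers: iterative truncated SVD and Bayesian PCA.

#' Iterative SVD imputation
#'
#' Expectation-maximization style low-rank completion: missing entries are
#' initialized with row means, then the matrix is repeatedly column-centered,
#' approximated by its rank-`npcs` truncated SVD, and the missing entries
#' replaced by the reconstruction (plus the centers), until the relative
#' change of the imputed entries falls below `tol` or `max_iter` sweeps.
#'
#' @inheritParams impute_lod
#' @return An `imputed_matrix`; diagnostics carry the convergence trace and
#'   a `converged` flag.
#' @export
impute_svd <- function(md, config = imputation_config("SVD")) {
  md <- as_masked(md)
  X <- md$observed
  q <- config$npcs
  if (q >= min(dim(X))) stop("`npcs` must be below min(nrow, ncol)")
  mask <- md$mask
  if (!any(mask)) {
    return(new_imputed(X, config, list(iterations = 0L, converged = TRUE)))
  }

  W <- X
  rm_ <- rowMeans(X, na.rm = TRUE)
  for (i in seq_len(nrow(X))) W[i, mask[i, ]] <- rm_[i]

  trace <- numeric(0)
  converged <- FALSE
  old <- W[mask]
  for (it in seq_len(config$max_iter)) {
    mu <- colMeans(W)
    C <- sweep(W, 2L, mu)
    s <- svd(C, nu = q, nv = q)
    R <- s$u %*% (diag(s$d[seq_len(q)], q) %*% t(s$v))
    R <- sweep(R, 2L, mu, `+`)
    W[mask] <- R[mask]
    new <- W[mask]
    delta <- sqrt(sum((new - old)^2)) /
      max(sqrt(sum(old^2)), .Machine$double.eps)
    trace <- c(trace, delta)
    old <- new
    if (delta < config$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("SVD imputation did not converge within max_iter sweeps")
  }
  new_imputed(W, config,
              list(iterations = length(trace), trace = trace,
                   converged = converged))
}

#' Bayesian PCA imputation
#'
#' Variational-Bayes probabilistic PCA with an automatic relevance
#' determination (ARD) prior on the factor loadings, in the style of Oba et
#' al.'s BPCA missing-value estimator. Samples (columns) are the variables
#' and proteins (rows) the observations. Each EM sweep computes, per row,
#' the posterior factor scores given that row's observed entries, fills its
#' missing entries with their posterior expectation, then re-estimates the
#' loading matrix (ARD-regularized ridge solution), the noise precision and
#' the ARD precisions. Initialization is the SVD of a row-mean-imputed
#' matrix; convergence is declared when the relative change of the noise
#' precision drops below `tol`.
#'
#' The ARD prior shrinks unneeded loading columns toward zero, so the
#' effective rank is selected automatically below the `npcs` cap.
#'
#' @inheritParams impute_lod
#' @return An `imputed_matrix`; diagnostics carry the noise-precision trace,
#'   final ARD precisions and a `converged` flag.
#' @export
impute_bpca <- function(md, config = imputation_config("BPCA")) {
  md <- as_masked(md)
  X <- md$observed
  n <- nrow(X); d <- ncol(X)
  q <- config$npcs
  if (q >= min(n, d)) stop("`npcs` must be below min(nrow, ncol)")
  mask <- md$mask
  if (!any(mask)) {
    return(new_imputed(X, config, list(iterations = 0L, converged = TRUE)))
  }

  # Init from the SVD of a row-mean-imputed matrix.
  W0 <- X
  rm_ <- rowMeans(X, na.rm = TRUE)
  for (i in seq_len(n)) W0[i, mask[i, ]] <- rm_[i]
  mu <- colMeans(W0)
  C <- sweep(W0, 2L, mu)
  s <- svd(C, nu = q, nv = q)
  # Loadings d x q scaled so that scores have roughly unit variance.
  Wl <- s$v %*% diag(s$d[seq_len(q)] / sqrt(n), q)
  resid_var <- max((sum(C^2) - sum(s$d[seq_len(q)]^2)) / (n * d), 1e-8)
  tau <- 1 / resid_var
  alpha <- rep(1, q)

  obs_list <- lapply(seq_len(n), function(i) which(!mask[i, ]))
  mis_any <- rowSums(mask) > 0L

  trace <- numeric(0)
  converged <- FALSE
  Y <- W0
  for (it in seq_len(config$max_iter)) {
    Iq <- diag(q)
    # E-step: posterior scores per row; shared solve for complete rows.
    Sx <- matrix(0, q, q)    # sum of E[x x'] over rows
    Txy <- matrix(0, d, q)   # sum of (y - mu) E[x]' over rows
    res_ss <- 0              # observed-entry residual sum of squares
    n_obs_entries <- 0L
    M_full <- solve(Iq + tau * crossprod(Wl), tol = 1e-30)
    scores <- matrix(0, n, q)
    for (i in seq_len(n)) {
      o <- obs_list[[i]]
      if (mis_any[i]) {
        Wo <- Wl[o, , drop = FALSE]
        Cx <- solve(Iq + tau * crossprod(Wo), tol = 1e-30)
      } else {
        Wo <- Wl
        Cx <- M_full
      }
      yo <- X[i, o] - mu[o]
      xi <- tau * (Cx %*% crossprod(Wo, yo))
      scores[i, ] <- xi
      if (mis_any[i]) {
        m <- which(mask[i, ])
        Y[i, m] <- (Wl[m, , drop = FALSE] %*% xi) + mu[m]
      }
      Sx <- Sx + Cx + tcrossprod(xi)
      yc <- Y[i, ] - mu
      Txy <- Txy + tcrossprod(yc, xi)
      ro <- yo - Wo %*% xi
      res_ss <- res_ss + sum(ro^2) + sum(diag(Wo %*% Cx %*% t(Wo)))
      n_obs_entries <- n_obs_entries + length(o)
    }
    # M-step: ARD-regularized loadings, noise precision, ARD precisions.
    Wl <- t(solve(Sx + (1 / tau) * diag(alpha, q), t(Txy), tol = 1e-30))
    tau_new <- n_obs_entries / max(res_ss, 1e-12)
    alpha <- d / (colSums(Wl^2) + 1e-10)
    mu <- colMeans(Y)
    delta <- abs(tau_new - tau) / tau
    tau <- tau_new
    trace <- c(trace, delta)
    if (delta < config$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("BPCA imputation did not converge within max_iter sweeps")
  }
  vals <- X
  vals[mask] <- Y[mask]
  new_imputed(vals, config,
              list(iterations = length(trace), trace = trace,
                   converged = converged, alpha = alpha,
                   loading_norms = sqrt(colSums(Wl^2))))
}
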