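#' Iterative random-forest imputation
#'
#' missForest-style chained random-forest imputation with samples (columns)
#' as variables and proteins (rows) as cases. Missing entries are
#' initialized with column means; columns are visited in increasing order
#' of missing count, and for each a random-forest regression of that column
#' on all other columns is fit on the rows observed in it (`ntree` trees,
#' `mtry = floor(sqrt(n_cols - 1))`), then used to predict its missing
#' rows. Full sweeps repeat until the normalized squared difference between
#' successive imputations increases (the previous sweep's matrix is then
#' returned), falls below `tol` (converged), or `max_iter` is reached.
#'
#' Forests are fit with the `ranger` engine, single-threaded and seeded,
#' so the result is deterministic for a fixed seed.
#'
#' @inheritParams impute_lod
#' @return An `imputed_matrix`; diagnostics carry the per-sweep difference
#'   trace and the number of sweeps run.
#' @export
impute_rf <- function(md, config = imputation_config("RF")) {
  md <- as_masked(md)
  X <- md$observed
  p <- ncol(X)
  if (p < 2L) stop("random-forest imputation needs at least 2 columns")
  mask <- md$mask
  cols <- colnames(X) %||% paste0("S", seq_len(p))
  safe <- make.names(cols, unique = TRUE)

  W <- X
  cm <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(p)) W[mask[, j], j] <- cm[j]

  visit <- order(colSums(mask))
  visit <- visit[colSums(mask)[visit] > 0L]
  if (length(visit) == 0L) {
    return(new_imputed(X, config, list(iterations = 0L, trace = numeric(0))))
  }
  mtry <- max(1L, floor(sqrt(p - 1L)))
  base_seed <- config$seed %||% 1L

  trace <- numeric(0)
  prev_diff <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    W_old <- W
    for (j in visit) {
      obs <- !mask[, j]
      df <- as.data.frame(W[, -j, drop = FALSE])
      names(df) <- safe[-j]
      fit <- ranger::ranger(
        x = df[obs, , drop = FALSE], y = W[obs, j],
        num.trees = config$ntree, mtry = min(mtry, p - 1L),
        seed = derive_seed(base_seed, 1000L * it, j),
        num.threads = 1L, verbose = FALSE
      )
      W[!obs, j] <- stats::predict(fit, df[!obs, , drop = FALSE],
                                   num.threads = 1L)$predictions
    }
    diff <- sum((W[mask] - W_old[mask])^2) / max(sum(W[mask]^2),
                                                 .Machine$double.eps)
    trace <- c(trace, diff)
    if (diff > prev_diff) {
      W <- W_old                       # criterion: return previous sweep
      break
    }
    if (diff < config$tol || it >= config$max_iter) break
    prev_diff <- diff
  }
  new_imputed(W, config, list(iterations = it, trace = trace))
}
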