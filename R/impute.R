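#' Imputation method configuration
#'
#' Hyperparameters for the seven imputation methods. Defaults follow the
#' settings found to perform best on the spike-in benchmark: k = 6
#' neighbours for kNN, k = 150 similar proteins for local least squares
#' (LLS), 100 trees for the random-forest (RF) imputer, and 2 principal
#' components for SVD and Bayesian PCA (BPCA). The downshifted-normal (ND)
#' imputer draws from `Normal(mu_m - nd_shift * sd_m, nd_width * sd_m)`
#' where `mu_m`/`sd_m` are the mean and standard deviation of the observed
#' values.
#'
#' @param method one of `"LOD"`, `"ND"`, `"KNN"`, `"LLS"`, `"RF"`,
#'   `"SVD"`, `"BPCA"` (case-insensitive).
#' @param k_neighbors number of nearest neighbour proteins for kNN.
#' @param k_similar number of similar proteins for the LLS regression.
#' @param ntree number of trees per random forest.
#' @param npcs number of principal components for SVD/BPCA.
#' @param nd_shift,nd_width downshift and width of the ND distribution, in
#'   multiples of the observed standard deviation.
#' @param nd_per_sample if `TRUE`, ND computes mean/sd per sample (column)
#'   instead of globally.
#' @param max_iter iteration cap for the iterative methods (default 100;
#'   10 for RF, whose stopping rule usually triggers much earlier).
#' @param tol relative-change convergence threshold for SVD/BPCA.
#' @param seed integer seed for the stochastic methods (ND, RF).
#' @return An object of class `imputation_config`.
#' @export
imputation_config <- function(method,
                              k_neighbors = 6L,
                              k_similar = 150L,
                              ntree = 100L,
                              npcs = 2L,
                              nd_shift = 2.2,
                              nd_width = 0.3,
                              nd_per_sample = FALSE,
                              max_iter = if (toupper(method) == "RF") 10L else 100L,
                              tol = 1e-3,
                              seed = 1L) {
  method <- toupper(method)
  methods <- c("LOD", "ND", "KNN", "LLS", "RF", "SVD", "BPCA")
  if (!method %in% methods) {
    stop("unknown method '", method, "'; expected one of ",
         paste(methods, collapse = ", "))
  }
  if (k_neighbors < 1L) stop("`k_neighbors` must be >= 1")
  if (k_similar < 1L) stop("`k_similar` must be >= 1")
  if (ntree < 1L) stop("`ntree` must be >= 1")
  if (npcs < 1L) stop("`npcs` must be >= 1")
  if (nd_width <= 0) stop("`nd_width` must be > 0")
  if (max_iter < 1L) stop("`max_iter` must be >= 1")
  structure(list(method = method,
                 k_neighbors = as.integer(k_neighbors),
                 k_similar = as.integer(k_similar),
                 ntree = as.integer(ntree),
                 npcs = as.integer(npcs),
                 nd_shift = nd_shift,
                 nd_width = nd_width,
                 nd_per_sample = isTRUE(nd_per_sample),
                 max_iter = as.integer(max_iter),
                 tol = tol,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "imputation_config")
}

#' Impute the missing entries of a masked dataset
#'
#' Single dispatch entry point over the seven method-specific imputers.
#' Observed entries always pass through bit-identically; only entries
#' flagged missing are filled.
#'
#' @param md a `masked_dataset` from [simulate_missingness()], or any list
#'   with an `observed` matrix containing `NA`s.
#' @param config an [imputation_config()], or a method name (then further
#'   arguments are forwarded to [imputation_config()]).
#' @param ... passed to [imputation_config()] when `config` is a name.
#' @return An object of class `imputed_matrix`: `values` (completed log2
#'   matrix), `method`, `config` and `diagnostics` (iterations, convergence
#'   trace, fallback counts).
#' @export
impute <- function(md, config, ...) {
  if (is.character(config)) config <- imputation_config(config, ...)
  stopifnot(inherits(config, "imputation_config"))
  md <- as_masked(md)
  if (any(rowSums(!is.na(md$observed)) == 0L)) {
    stop("every row must have at least one observed entry ",
         "(simulate_missingness drops all-missing rows)")
  }
  switch(config$method,
         LOD = impute_lod(md, config),
         ND = impute_nd(md, config),
         KNN = impute_knn(md, config),
         LLS = impute_lls(md, config),
         RF = impute_rf(md, config),
         SVD = impute_svd(md, config),
         BPCA = impute_bpca(md, config))
}

# Accept a masked_dataset, an abundance_matrix with NAs, or a bare matrix.
as_masked <- function(md) {
  if (inherits(md, "masked_dataset")) return(md)
  if (inherits(md, "abundance_matrix")) {
    return(list(observed = md$values, mask = is.na(md$values),
                species = md$species, groups = md$groups))
  }
  if (is.matrix(md) && is.numeric(md)) {
    return(list(observed = md, mask = is.na(md)))
  }
  if (is.list(md) && is.matrix(md$observed)) {
    md$mask <- md$mask %||% is.na(md$observed)
    return(md)
  }
  stop("`md` must be a masked_dataset, abundance_matrix or numeric matrix")
}

new_imputed <- function(values, config, diagnostics = list()) {
  stopifnot(!anyNA(values))
  structure(list(values = values, method = config$method, config = config,
                 diagnostics = diagnostics),
            class = "imputed_matrix")
}

#' @export
print.imputed_matrix <- function(x, ...) {
  cat(sprintf("Imputed matrix: %d x %d, method %s\n",
              nrow(x$values), ncol(x$values), x$method))
  d <- x$diagnostics
  if (!is.null(d$iterations)) cat("  iterations:", d$iterations, "\n")
  if (!is.null(d$fallbacks) && d$fallbacks > 0) {
    cat("  fallback-imputed entries:", d$fallbacks, "\n")
  }
  if (isTRUE(d$converged == FALSE)) cat("  warning: did not converge\n")
  invisible(x)
}

#' Lowest-of-detection imputation
#'
#' Replaces every missing entry with the global minimum of the observed
#' values, the crudest left-censored strategy.
#'
#' @param md a `masked_dataset` (or matrix with `NA`s).
#' @param config an [imputation_config()]; only used for bookkeeping.
#' @return An `imputed_matrix`.
#' @export
impute_lod <- function(md, config = imputation_config("LOD")) {
  md <- as_masked(md)
  obs <- md$observed[!md$mask]
  if (length(obs) == 0L) stop("no observed values to take the minimum of")
  vals <- md$observed
  vals[md$mask] <- min(obs)
  new_imputed(vals, config)
}

#' Downshifted-normal imputation
#'
#' Left-censored imputation by random draws from a narrowed normal
#' distribution placed in the left tail of the observed abundance
#' distribution: missing entries are drawn independently from
#' `Normal(mu_m - nd_shift * sd_m, nd_width * sd_m)` with `mu_m`, `sd_m`
#' the mean and (sample) standard deviation of all observed values
#' (defaults: shift 2.2, width 0.3). With `nd_per_sample = TRUE` the
#' statistics are computed per column instead.
#'
#' @inheritParams impute_lod
#' @return An `imputed_matrix`.
#' @export
impute_nd <- function(md, config = imputation_config("ND")) {
  md <- as_masked(md)
  vals <- md$observed
  draw <- function(n, mu, sdev) {
    if (sdev == 0) {
      warning("observed standard deviation is zero; ND imputes the constant mean")
      return(rep(mu, n))
    }
    stats::rnorm(n, mu - config$nd_shift * sdev, config$nd_width * sdev)
  }
  with_seed(config$seed, {
    if (config$nd_per_sample) {
      for (j in seq_len(ncol(vals))) {
        mis <- md$mask[, j]
        if (!any(mis)) next
        obs <- vals[!mis, j]
        if (length(obs) < 2L) stop("need >= 2 observed values per sample for ND")
        vals[mis, j] <- draw(sum(mis), mean(obs), stats::sd(obs))
      }
    } else {
      obs <- vals[!md$mask]
      if (length(obs) < 2L) stop("need >= 2 observed values for ND")
      vals[md$mask] <- draw(sum(md$mask), mean(obs), stats::sd(obs))
    }
  })
  new_imputed(vals, config)
}
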