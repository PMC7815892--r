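#' Missingness specification
#'
#' Parameters of the controlled amputation procedure: `alpha` is the total
#' fraction of entries set missing, `beta` the share of those that are
#' missing not at random (MNAR, abundance-dependent censoring); the
#' remainder are missing at random (MAR, uniform). `sigma_T` is the standard
#' deviation of the stochastic censoring threshold, in the same units as the
#' log2 data.
#'
#' @param alpha total missing-value rate, in `[0, 1)`.
#' @param beta MNAR share of the missing values, in `[0, 1]`.
#' @param sigma_T threshold-matrix standard deviation (default 0.3, log2
#'   units).
#' @param seed integer seed; amputation is deterministic given
#'   `(matrix, spec)`.
#' @return An object of class `missingness_spec`.
#' @export
missingness_spec <- function(alpha, beta, sigma_T = 0.3, seed = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha >= 1) {
    stop("`alpha` must be a single number in [0, 1)")
  }
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta < 0 || beta > 1) {
    stop("`beta` must be a single number in [0, 1]")
  }
  if (!is.numeric(sigma_T) || sigma_T <= 0) stop("`sigma_T` must be > 0")
  structure(list(alpha = alpha, beta = beta, sigma_T = sigma_T,
                 seed = as.integer(seed)),
            class = "missingness_spec")
}

#' Simulate missing values with controlled MV and MNAR rates
#'
#' Amputes a complete log2-scale matrix so that exactly `round(N * alpha)`
#' of its `N` entries are missing, of which exactly
#' `round(N * alpha * beta)` are MNAR. MNAR entries are selected by
#' stochastic left-censoring: a threshold matrix `T ~ Normal(q, sigma_T)`
#' with `q` the `alpha`-quantile of all values, and a Bernoulli(`beta`)
#' success matrix `P`; an entry is an MNAR candidate when its value lies
#' below its threshold and its Bernoulli trial succeeded. Candidates are
#' uniformly subsampled to the exact MNAR target; if too few exist the
#' threshold quantile is raised in steps of 0.01 and the threshold matrix
#' redrawn. MAR entries are then drawn uniformly from the still-observed
#' entries. Rows left with no observed value are removed.
#'
#' The exact-count enforcement makes realized rates deterministic: the
#' missing fraction is `round(N * alpha) / N` and the MNAR share is
#' `round(N * alpha * beta) / round(N * alpha)` for every seed (before row
#' dropping).
#'
#' @param x a complete [abundance_matrix()] on the log2 scale (use
#'   [log2_transform()] first), or a bare numeric matrix of log2
#'   intensities.
#' @param spec a [missingness_spec()].
#' @return An object of class `masked_dataset` with elements `observed`
#'   (matrix with `NA` at missing entries, all-missing rows dropped),
#'   `mask` (logical, `TRUE` = missing), `provenance` (integer matrix, 0 =
#'   observed, 1 = MNAR, 2 = MAR), `truth` (the complete matrix restricted
#'   to retained rows), `dropped_rows`, `species`/`groups` labels for the
#'   retained rows, and the `spec`.
#' @export
simulate_missingness <- function(x, spec) {
  stopifnot(inherits(spec, "missingness_spec"))
  species <- NULL; groups <- NULL
  if (inherits(x, "abundance_matrix")) {
    if (x$scale != "log2") {
      stop("amputation operates on log2 intensities; call log2_transform() first")
    }
    species <- x$species
    groups <- x$groups
    D <- x$values
  } else if (is.matrix(x) && is.numeric(x)) {
    D <- x
  } else {
    stop("`x` must be an abundance_matrix or a numeric matrix")
  }
  if (anyNA(D)) stop("input matrix must be complete (no missing entries)")

  N <- length(D)
  target_total <- round(N * spec$alpha)
  target_mnar <- round(N * spec$alpha * spec$beta)
  target_mar <- target_total - target_mnar
  v <- as.vector(D)

  idx <- with_seed(spec$seed, {
    mnar_idx <- integer(0)
    if (target_mnar > 0) {
      P <- stats::rbinom(N, 1L, spec$beta)
      q <- spec$alpha
      repeat {
        thr <- stats::rnorm(N, stats::quantile(v, q, names = FALSE),
                            spec$sigma_T)
        cand <- which(v < thr & P == 1L)
        if (length(cand) >= target_mnar) {
          mnar_idx <- if (length(cand) == target_mnar) cand else
            cand[sample.int(length(cand), target_mnar)]
          break
        }
        if (q >= 1) {
          stop("cannot realize the requested MNAR count: only ",
               length(cand), " candidate entries below the threshold at ",
               "quantile 1; reduce alpha * beta")
        }
        q <- min(1, q + 0.01)
      }
    }
    mar_idx <- integer(0)
    if (target_mar > 0) {
      remaining <- setdiff(seq_len(N), mnar_idx)
      mar_idx <- remaining[sample.int(length(remaining), target_mar)]
    }
    list(mnar = mnar_idx, mar = mar_idx)
  })

  provenance <- matrix(0L, nrow(D), ncol(D), dimnames = dimnames(D))
  provenance[idx$mnar] <- 1L
  provenance[idx$mar] <- 2L
  mask <- provenance > 0L
  observed <- D
  observed[mask] <- NA_real_

  keep <- rowSums(!mask) > 0L
  dropped <- rownames(D)[!keep] %||% which(!keep)
  structure(
    list(observed = observed[keep, , drop = FALSE],
         mask = mask[keep, , drop = FALSE],
         provenance = provenance[keep, , drop = FALSE],
         truth = D[keep, , drop = FALSE],
         dropped_rows = if (all(keep)) character(0) else dropped,
         species = if (!is.null(species)) species[keep] else NULL,
         groups = groups,
         spec = spec),
    class = "masked_dataset"
  )
}

#' Summarize the realized missingness of a masked dataset
#'
#' @param md a `masked_dataset` from [simulate_missingness()].
#' @return A list: `mv_rate` (missing fraction of the retained matrix),
#'   `mnar_share` (MNAR fraction of the missing entries; 0 when nothing is
#'   missing), `per_sample_rates` (per-column missing fractions) and
#'   `per_protein_counts` (per-row missing counts).
#' @export
missingness_summary <- function(md) {
  stopifnot(inherits(md, "masked_dataset"))
  n_missing <- sum(md$mask)
  list(
    mv_rate = n_missing / length(md$mask),
    mnar_share = if (n_missing == 0) 0 else
      sum(md$provenance == 1L) / n_missing,
    per_sample_rates = colMeans(md$mask),
    per_protein_counts = rowSums(md$mask)
  )
}

#' @export
print.masked_dataset <- function(x, ...) {
  s <- missingness_summary(x)
  cat(sprintf("Masked dataset: %d proteins x %d samples\n",
              nrow(x$observed), ncol(x$observed)))
  cat(sprintf("  missing: %.1f%% of entries (MNAR share %.1f%%), %d rows dropped\n",
              100 * s$mv_rate, 100 * s$mnar_share, length(x$dropped_rows)))
  cat(sprintf("  spec: alpha = %g, beta = %g, sigma_T = %g, seed = %d\n",
              x$spec$alpha, x$spec$beta, x$spec$sigma_T, x$spec$seed))
  invisible(x)
}
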