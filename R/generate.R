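#' Generate a complete synthetic spike-in benchmark
#'
#' Draws a complete (no missing values) protein abundance matrix whose
#' ground-truth structure follows a spike-in design: every protein has a
#' log-normal baseline abundance shared across samples, every sample applies
#' a per-species scaling factor equal to the designed mass fraction times a
#' mean-centered perturbation, and optional multiplicative log-normal
#' measurement noise is added per entry.
#'
#' The intragroup perturbations are mean-centered within each group, so the
#' group mean of the per-sample scaling factors equals the designed
#' proportion exactly (not just in expectation). With `noise_sd = 0` the
#' arithmetic group-mean ratio of every protein therefore reproduces the
#' designed intergroup fold change to machine precision.
#'
#' @param design a [group_design()]; defaults to the standard three-species
#'   layout of [benchmark_design()].
#' @param n_proteins named integer vector of protein counts per species;
#'   names must match the design's species. The default mirrors the
#'   composition of the real spike-in benchmark (1184 E. coli, 1081 yeast,
#'   4424 human proteins) and can be scaled down for quick experiments.
#' @param log2_location,log2_scale location and scale of the per-protein
#'   baseline abundance distribution on the log2 scale (baselines are
#'   `2^Normal(log2_location, log2_scale)`).
#' @param noise_sd standard deviation (log2 scale) of the per-entry
#'   multiplicative measurement noise; 0 disables entry noise.
#' @param seed integer seed; the output is a pure function of
#'   `(design, n_proteins, parameters, seed)`.
#' @param max_resample how many times a group's perturbation vector may be
#'   redrawn when the CV is so large that a scaling factor would be
#'   non-positive, before failing.
#'
#' @return A complete linear-scale [abundance_matrix()] with the realized
#'   species x sample scaling matrix attached (`$scaling`), sample names
#'   `<group>_<replicate>` and per-row species labels.
#' @export
generate_benchmark <- function(design = benchmark_design(),
                               n_proteins = c(ecoli = 1184L,
                                              yeast = 1081L,
                                              human = 4424L),
                               log2_location = 20,
                               log2_scale = 2,
                               noise_sd = 0.3,
                               seed = 1L,
                               max_resample = 100L) {
  stopifnot(inherits(design, "group_design"))
  if (is.null(names(n_proteins)) ||
      !setequal(names(n_proteins), design$species)) {
    stop("`n_proteins` must be named by the design's species: ",
         paste(design$species, collapse = ", "))
  }
  n_proteins <- n_proteins[design$species]
  if (any(n_proteins < 1)) stop("all protein counts must be >= 1")
  if (!is.finite(log2_location) || !is.finite(log2_scale) || log2_scale < 0) {
    stop("baseline log-normal parameters must be finite, scale >= 0")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be finite and >= 0")
  }

  reps <- design$replicates_per_group
  groups <- rep(design$group_ids, each = reps)
  sample_ids <- paste(groups, rep(seq_len(reps), times = length(design$group_ids)),
                      sep = "_")
  species <- rep(design$species, times = n_proteins)
  n <- sum(n_proteins)
  protein_ids <- unlist(lapply(design$species, function(s) {
    sprintf("%s_%04d", toupper(s), seq_len(n_proteins[[s]]))
  }), use.names = FALSE)

  with_seed(seed, {
    baseline <- 2^stats::rnorm(n, log2_location, log2_scale)

    # Per-sample species scaling: designed proportion x (1 + perturbation),
    # perturbations mean-centered within each group so the group mean equals
    # the designed proportion exactly.
    scaling <- matrix(NA_real_, length(design$species), length(sample_ids),
                      dimnames = list(design$species, sample_ids))
    for (s in design$species) {
      for (g in design$group_ids) {
        prop <- design$proportions[s, g]
        for (try in seq_len(max_resample)) {
          e <- stats::rnorm(reps, 0, design$intragroup_cv)
          e <- e - mean(e)
          f <- prop * (1 + e)
          if (all(f > 0)) break
          f <- NULL
        }
        if (is.null(f)) {
          stop("could not draw positive scaling factors for species ", s,
               " in group ", g, " after ", max_resample,
               " attempts; reduce `intragroup_cv`")
        }
        scaling[s, groups == g] <- f
      }
    }

    values <- baseline * scaling[species, , drop = FALSE]
    if (noise_sd > 0) {
      values <- values * 2^matrix(stats::rnorm(length(values), 0, noise_sd),
                                  nrow(values), ncol(values))
    }
    dimnames(values) <- list(protein_ids, sample_ids)

    abundance_matrix(values, species = species, groups = groups,
                     scale = "linear", design = design, scaling = scaling)
  })
}

#' Audit the statistical significance of a generated design
#'
#' Checks the design contract that spike-in species differ significantly
#' between each non-control group and the control: per-sample species totals
#' (linear sums, then log2) are compared by the same pooled-variance two-sample
#' t-test used by the evaluation stage. A generated dataset whose intended
#' contrasts fail this audit can be rejected and regenerated under a new
#' seed.
#'
#' @param x a complete [abundance_matrix()].
#' @param design the [group_design()]; defaults to the one attached to `x`.
#' @return A data frame with one row per (species, comparison): the
#'   comparison id (`<group>/<control>`), the t statistic and the two-sided
#'   p-value. Zero within-group variance with unequal means is reported as
#'   p = 0 (perfect separation), with equal means as p = 1.
#' @export
significance_audit <- function(x, design = x$design) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (is.null(design)) stop("no design attached and none supplied")
  if (anyNA(x$values)) stop("`significance_audit` requires a complete matrix")
  if (design$replicates_per_group < 2L) stop("need >= 2 replicates per group")
  lin <- linear_transform(x)
  totals <- rowsum(lin$values, lin$species)        # species x sample mass
  ltot <- log2(totals)
  ctrl <- design$control_group
  test_groups <- setdiff(design$group_ids, ctrl)
  out <- expand.grid(species = rownames(totals), comparison = test_groups,
                     stringsAsFactors = FALSE)
  out$comparison <- paste0(out$comparison, "/", ctrl)
  stats <- t(mapply(function(sp, grp) {
    a <- ltot[sp, x$groups == ctrl]
    b <- ltot[sp, x$groups == grp]
    pooled_t(a, b)
  }, out$species, sub("/.*$", "", out$comparison)))
  out$t <- stats[, 1L]
  out$p <- stats[, 2L]
  rownames(out) <- NULL
  out
}
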