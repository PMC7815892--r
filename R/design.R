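#' Experimental design of a spike-in benchmark
#'
#' A `group_design` describes the composition of a multi-species spike-in
#' experiment: which sample groups exist, how many replicates each has, and
#' the fraction of total protein mass contributed by each species in each
#' group. Intergroup fold changes follow directly from those fractions, so a
#' dataset generated from the design has fully known ground truth.
#'
#' @param species_proportions numeric matrix with one row per species and one
#'   column per group; each column must sum to 1 (fraction of total protein
#'   mass per species).
#' @param replicates_per_group positive integer, number of samples per group
#'   (at least 2).
#' @param intragroup_cv coefficient of variation (unitless, >= 0) of the
#'   per-sample species scaling factors around the designed proportion.
#' @param control_group group id used as the denominator for intergroup
#'   ratios.
#'
#' @return An object of class `group_design`.
#' @seealso [benchmark_design()] for the standard three-species design,
#'   [designated_ratio_table()], [generate_benchmark()].
#' @export
group_design <- function(species_proportions,
                         replicates_per_group = 8L,
                         intragroup_cv = 0.05,
                         control_group = colnames(species_proportions)[1L]) {
  if (!is.matrix(species_proportions) || !is.numeric(species_proportions)) {
    stop("`species_proportions` must be a numeric species x group matrix")
  }
  if (is.null(rownames(species_proportions)) ||
      is.null(colnames(species_proportions))) {
    stop("`species_proportions` needs species rownames and group colnames")
  }
  if (any(species_proportions < 0) || any(species_proportions > 1)) {
    stop("species proportions must lie in [0, 1]")
  }
  csums <- colSums(species_proportions)
  if (any(abs(csums - 1) > 1e-9)) {
    stop("species proportions must sum to 1 within 1e-9 in every group; got ",
         paste(signif(csums, 12), collapse = ", "))
  }
  replicates_per_group <- as.integer(replicates_per_group)
  if (is.na(replicates_per_group) || replicates_per_group < 2L) {
    stop("`replicates_per_group` must be an integer >= 2")
  }
  if (!is.numeric(intragroup_cv) || length(intragroup_cv) != 1L ||
      is.na(intragroup_cv) || intragroup_cv < 0) {
    stop("`intragroup_cv` must be a single non-negative number")
  }
  if (!control_group %in% colnames(species_proportions)) {
    stop("`control_group` must be one of the group ids")
  }
  structure(
    list(
      group_ids = colnames(species_proportions),
      species = rownames(species_proportions),
      proportions = species_proportions,
      replicates_per_group = replicates_per_group,
      intragroup_cv = intragroup_cv,
      control_group = control_group
    ),
    class = "group_design"
  )
}

#' Standard three-species spike-in design
#'
#' The benchmark layout this package emulates: four groups (A--D) of eight
#' replicates, a constant 70% human background, E. coli rising across groups
#' (5, 7.5, 10, 12.5% of protein mass) and yeast falling (25, 22.5, 20,
#' 17.5%), so that the designed fold changes of groups B--D versus the control
#' group A are 1.5/2/2.5 for E. coli, 0.9/0.8/0.7 for yeast and 1 for human.
#'
#' @param replicates_per_group samples per group (default 8).
#' @param intragroup_cv coefficient of variation of per-sample species
#'   scaling (default 0.05); see [generate_benchmark()].
#' @return A [group_design()] object.
#' @export
benchmark_design <- function(replicates_per_group = 8L, intragroup_cv = 0.05) {
  props <- rbind(
    human = c(0.70, 0.700, 0.70, 0.700),
    ecoli = c(0.05, 0.075, 0.10, 0.125),
    yeast = c(0.25, 0.225, 0.20, 0.175)
  )
  colnames(props) <- c("A", "B", "C", "D")
  group_design(props,
               replicates_per_group = replicates_per_group,
               intragroup_cv = intragroup_cv,
               control_group = "A")
}

#' Designed intergroup ratio table
#'
#' Fold change of each species in each group relative to the control group,
#' computed from the designed mass fractions:
#' `ratio(species, g) = proportion(species, g) / proportion(species, control)`.
#'
#' @param design a [group_design()].
#' @return Numeric species x group matrix of linear ratios; the control
#'   column is identically 1.
#' @export
designated_ratio_table <- function(design) {
  stopifnot(inherits(design, "group_design"))
  ctrl <- design$proportions[, design$control_group]
  if (any(ctrl == 0)) {
    stop("control-group proportion is zero for species: ",
         paste(design$species[ctrl == 0], collapse = ", "))
  }
  sweep(design$proportions, 1L, ctrl, `/`)
}

#' @export
print.group_design <- function(x, ...) {
  cat("Spike-in group design\n")
  cat("  groups     :", paste(x$group_ids, collapse = ", "),
      sprintf("(%d replicates each, control = %s)\n",
              x$replicates_per_group, x$control_group))
  cat("  intragroup CV:", x$intragroup_cv, "\n")
  cat("  species mass fractions:\n")
  print(x$proportions)
  invisible(x)
}
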