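#' Labeled protein abundance matrix
#'
#' The container every pipeline stage operates on: an intensity matrix with
#' proteins as rows and samples as columns, a species label per protein and a
#' group label per sample, plus a flag recording whether values are on the
#' linear or the log2 scale.
#'
#' @param values numeric matrix, proteins x samples. May contain `NA`
#'   (missing values) for data loaded from real acquisitions; generated
#'   benchmarks are complete.
#' @param species character vector of per-row species labels.
#' @param groups character vector of per-column group labels.
#' @param scale `"linear"` or `"log2"`.
#' @param design optional [group_design()] the matrix was generated from.
#' @param scaling optional species x sample matrix of realized scaling
#'   factors (attached by [generate_benchmark()]).
#'
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, species, groups,
                             scale = c("linear", "log2"),
                             design = NULL, scaling = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (length(species) != nrow(values)) {
    stop("`species` length (", length(species),
         ") must match the number of rows (", nrow(values), ")")
  }
  if (length(groups) != ncol(values)) {
    stop("`groups` length (", length(groups),
         ") must match the number of columns (", ncol(values), ")")
  }
  if (scale == "linear" && any(values <= 0, na.rm = TRUE)) {
    stop("linear-scale intensities must be strictly positive")
  }
  structure(
    list(values = values,
         species = as.character(species),
         groups = as.character(groups),
         scale = scale,
         design = design,
         scaling = scaling),
    class = "abundance_matrix"
  )
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Switch an abundance matrix between linear and log2 scale
#'
#' All amputation, imputation and abundance-error computations in this
#' package operate on the log2 scale; generation and ratio bookkeeping are
#' linear. These helpers convert between the two and are no-ops when the
#' matrix is already on the requested scale.
#'
#' @param x an [abundance_matrix()].
#' @return The converted `abundance_matrix`.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (x$scale == "log2") return(x)
  x$values <- log2(x$values)
  x$scale <- "log2"
  x
}

#' @rdname log2_transform
#' @export
linear_transform <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  if (x$scale == "linear") return(x)
  x$values <- 2^x$values
  x$scale <- "linear"
  x
}

#' @export
print.abundance_matrix <- function(x, ...) {
  n_na <- sum(is.na(x$values))
  cat(sprintf("Labeled abundance matrix: %d proteins x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat("  species:",
      paste(sprintf("%s (%d)", names(table(x$species)), table(x$species)),
            collapse = ", "), "\n")
  cat("  groups :",
      paste(sprintf("%s (%d)", names(table(x$groups)), table(x$groups)),
            collapse = ", "), "\n")
  if (n_na > 0) {
    cat(sprintf("  missing: %d entries (%.1f%%)\n", n_na,
                100 * n_na / length(x$values)))
  }
  invisible(x)
}
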