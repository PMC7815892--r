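# File I/O: labeled abundance TSVs, MaxQuant proteinGroups tables, and
# masked-dataset serialization. Missing entries are written as empty fields.

#' Write a labeled abundance matrix as TSV
#'
#' Layout: first column `protein`, second column `species`, remaining
#' columns one per sample, named `<group>_<replicate>`. Missing entries are
#' written as empty fields. When the matrix carries a [group_design()], a
#' companion JSON sidecar `<path>.design.json` records it.
#'
#' @param x an [abundance_matrix()].
#' @param path output file path.
#' @param design_sidecar write the design sidecar when a design is attached
#'   (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_abundance_tsv <- function(x, path, design_sidecar = TRUE) {
  stopifnot(inherits(x, "abundance_matrix"))
  df <- data.frame(protein = rownames(x$values) %||%
                     as.character(seq_len(nrow(x$values))),
                   species = x$species,
                   x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  if (design_sidecar && !is.null(x$design)) {
    d <- x$design
    jsonlite::write_json(
      list(group_ids = d$group_ids,
           species = d$species,
           proportions = as.data.frame(d$proportions),
           replicates_per_group = d$replicates_per_group,
           intragroup_cv = d$intragroup_cv,
           control_group = d$control_group,
           scale = x$scale),
      paste0(path, ".design.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a labeled abundance matrix from TSV
#'
#' Reads the layout written by [write_abundance_tsv()]: a `protein` id
#' column, an optional `species` column, and numeric sample columns whose
#' names encode the group as `<group>_<replicate>`. Empty fields become
#' missing values. Malformed input (ragged rows, duplicate protein ids,
#' non-numeric cells) raises descriptive errors with line numbers.
#'
#' @param path TSV file path.
#' @param scale scale the stored values are on (default `"linear"`, or read
#'   from the design sidecar when present).
#' @return An [abundance_matrix()] (possibly containing `NA`s).
#' @export
read_abundance_tsv <- function(path, scale = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", blank.lines.skip = FALSE)
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("ragged TSV: line ", bad, " has ", nf[bad], " fields, expected ",
         nf[1L])
  }
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", quote = "")
  if (!"protein" %in% names(df)) stop("missing required column 'protein'")
  dup <- duplicated(df$protein)
  if (any(dup)) {
    i <- which(dup)[1L]
    stop("duplicate protein id '", df$protein[i], "' at line ", i + 1L)
  }
  has_species <- "species" %in% names(df)
  sample_cols <- setdiff(names(df), c("protein", "species"))
  if (length(sample_cols) == 0L) stop("no sample columns found")
  vals <- matrix(NA_real_, nrow(df), length(sample_cols),
                 dimnames = list(df$protein, sample_cols))
  for (j in seq_along(sample_cols)) {
    raw <- df[[sample_cols[j]]]
    empty <- is.na(raw) | raw == ""
    num <- suppressWarnings(as.numeric(raw))
    bad <- !empty & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("non-numeric value '", raw[i], "' in column '", sample_cols[j],
           "' at line ", i + 1L)
    }
    vals[, j] <- num
  }
  groups <- sub("_[0-9]+$", "", sample_cols)
  sidecar <- paste0(path, ".design.json")
  design <- NULL
  if (is.null(scale)) scale <- "linear"
  if (file.exists(sidecar)) {
    sj <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    props <- as.matrix(sj$proportions)
    rownames(props) <- sj$species
    design <- group_design(props,
                           replicates_per_group = sj$replicates_per_group,
                           intragroup_cv = sj$intragroup_cv,
                           control_group = sj$control_group)
    scale <- sj$scale %||% scale
  }
  abundance_matrix(vals,
                   species = if (has_species) df$species else
                     rep(NA_character_, nrow(df)),
                   groups = groups, scale = scale, design = design)
}

#' Read a MaxQuant proteinGroups table
#'
#' Extracts label-free quantification (LFQ) intensity columns from a
#' MaxQuant `proteinGroups.txt` table: rows flagged as reverse hits or
#' potential contaminants are removed, intensity zeros are converted to
#' missing values, and values are optionally log2-transformed on load.
#'
#' @param path tab-separated proteinGroups file.
#' @param intensity_prefix column-name prefix of the intensity columns
#'   (default `"LFQ intensity "`).
#' @param log2 log2-transform intensities on load (default `TRUE`).
#' @return An [abundance_matrix()] with `NA` for unquantified entries and
#'   sample groups inferred from the column names (`<group>_<replicate>`).
#' @export
read_maxquant_proteingroups <- function(path,
                                        intensity_prefix = "LFQ intensity ",
                                        log2 = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE, quote = "",
                          stringsAsFactors = FALSE)
  icols <- names(df)[startsWith(names(df), intensity_prefix)]
  if (length(icols) == 0L) {
    stop("no columns start with '", intensity_prefix, "'; available: ",
         paste(names(df), collapse = ", "))
  }
  for (flag in c("Reverse", "Potential contaminant", "Contaminant")) {
    if (flag %in% names(df)) df <- df[df[[flag]] != "+" | is.na(df[[flag]]), ]
  }
  id_col <- intersect(c("Majority protein IDs", "Protein IDs"), names(df))[1L]
  ids <- if (!is.na(id_col)) df[[id_col]] else df[[1L]]
  vals <- as.matrix(df[icols])
  mode(vals) <- "numeric"
  vals[vals == 0] <- NA_real_
  samples <- sub(paste0("^", intensity_prefix), "", icols)
  dimnames(vals) <- list(make.unique(as.character(ids)), samples)
  if (log2) vals <- log2(vals)
  abundance_matrix(vals, species = rep(NA_character_, nrow(vals)),
                   groups = sub("_[0-9]+$", "", samples),
                   scale = if (log2) "log2" else "linear")
}

#' Restrict to the fully observed rows
#'
#' Keeps only proteins quantified in every sample -- the standard strategy
#' for building a complete amputation substrate out of real data with
#' missing values.
#'
#' @param x an [abundance_matrix()].
#' @return The filtered `abundance_matrix`.
#' @export
complete_subset <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  keep <- rowSums(is.na(x$values)) == 0L
  if (!any(keep)) stop("no fully observed rows remain")
  x$values <- x$values[keep, , drop = FALSE]
  x$species <- x$species[keep]
  x
}

#' Serialize a masked dataset to a directory
#'
#' Writes `observed.tsv` (missing = empty field), `mask.tsv` (0/1),
#' `provenance.tsv` (0 = observed, 1 = MNAR, 2 = MAR), `truth.tsv` and
#' `spec.json`.
#'
#' @param md a `masked_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_masked_dataset <- function(md, dir) {
  stopifnot(inherits(md, "masked_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(m, f) {
    df <- data.frame(protein = rownames(m) %||%
                       as.character(seq_len(nrow(m))),
                     m, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  wr(md$observed, "observed.tsv")
  wr(1 * md$mask, "mask.tsv")
  wr(md$provenance, "provenance.tsv")
  wr(md$truth, "truth.tsv")
  jsonlite::write_json(
    list(alpha = md$spec$alpha, beta = md$spec$beta,
         sigma_T = md$spec$sigma_T, seed = md$spec$seed,
         species = md$species, groups = md$groups,
         dropped_rows = md$dropped_rows),
    file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a masked dataset written by [write_masked_dataset()]
#'
#' @param dir directory containing the serialized files.
#' @return A `masked_dataset`.
#' @export
read_masked_dataset <- function(dir) {
  rd <- function(f) {
    df <- utils::read.delim(file.path(dir, f), check.names = FALSE, quote = "")
    m <- as.matrix(df[, -1L, drop = FALSE])
    mode(m) <- "numeric"
    rownames(m) <- df[[1L]]
    m
  }
  sj <- jsonlite::read_json(file.path(dir, "spec.json"),
                            simplifyVector = TRUE)
  structure(
    list(observed = rd("observed.tsv"),
         mask = rd("mask.tsv") > 0,
         provenance = {
           p <- rd("provenance.tsv"); mode(p) <- "integer"; p
         },
         truth = rd("truth.tsv"),
         dropped_rows = as.character(sj$dropped_rows %||% character(0)),
         species = sj$species,
         groups = sj$groups,
         spec = missingness_spec(sj$alpha, sj$beta, sj$sigma_T, sj$seed)),
    class = "masked_dataset"
  )
}
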