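#' Configuration of a full imputation benchmark run
#'
#' Describes the condition grid (missing-value rates x MNAR shares x
#' repeats), the methods to compare, and the data source -- either a
#' [group_design()] from which a synthetic benchmark is generated, or a
#' complete [abundance_matrix()] supplied directly.
#'
#' @param mv_rates total missing-value rates (default 0.1, 0.2, 0.3).
#' @param mnar_rates MNAR shares (default 0.2, 0.5, 0.8).
#' @param n_repeats mask repeats per condition (default 10).
#' @param methods subset of the seven method names.
#' @param base_seed integer; repeat `r` uses amputation seed
#'   `base_seed + r`, shared across methods so every method sees the
#'   identical mask.
#' @param design [group_design()] used when `source` is `NULL`.
#' @param n_proteins,log2_location,log2_scale,noise_sd forwarded to
#'   [generate_benchmark()] when synthesizing.
#' @param source optional complete [abundance_matrix()] to benchmark on
#'   instead of synthesizing (pre-filter real data with
#'   [complete_subset()]).
#' @param sigma_T threshold standard deviation for amputation.
#' @param de_alpha adjusted-p cutoff for significance calls.
#' @param positive_species spiked species treated as ground-truth positives.
#' @param compute_roc if `TRUE`, repeat-averaged ROC curves are collected
#'   per (condition, method, comparison).
#' @param method_args named list of per-method overrides passed to
#'   [imputation_config()], e.g. `list(KNN = list(k_neighbors = 10))`.
#' @param verbose log per-stage progress to stderr.
#' @return An object of class `benchmark_config`.
#' @export
benchmark_config <- function(mv_rates = c(0.1, 0.2, 0.3),
                             mnar_rates = c(0.2, 0.5, 0.8),
                             n_repeats = 10L,
                             methods = c("LOD", "ND", "KNN", "LLS",
                                         "RF", "SVD", "BPCA"),
                             base_seed = 1L,
                             design = benchmark_design(),
                             n_proteins = c(ecoli = 1184L, yeast = 1081L,
                                            human = 4424L),
                             log2_location = 20,
                             log2_scale = 2,
                             noise_sd = 0.3,
                             source = NULL,
                             sigma_T = 0.3,
                             de_alpha = 0.05,
                             positive_species = c("ecoli", "yeast"),
                             compute_roc = FALSE,
                             method_args = list(),
                             verbose = TRUE) {
  if (any(mv_rates <= 0 | mv_rates >= 1)) stop("`mv_rates` must lie in (0, 1)")
  if (any(mnar_rates < 0 | mnar_rates > 1)) stop("`mnar_rates` must lie in [0, 1]")
  if (n_repeats < 1L) stop("`n_repeats` must be >= 1")
  methods <- toupper(methods)
  if (length(methods) == 0L) stop("`methods` must be nonempty")
  for (m in methods) imputation_config(m)   # validates names
  structure(
    list(mv_rates = mv_rates, mnar_rates = mnar_rates,
         n_repeats = as.integer(n_repeats), methods = methods,
         base_seed = as.integer(base_seed), design = design,
         n_proteins = n_proteins, log2_location = log2_location,
         log2_scale = log2_scale, noise_sd = noise_sd, source = source,
         sigma_T = sigma_T, de_alpha = de_alpha,
         positive_species = positive_species, compute_roc = compute_roc,
         method_args = method_args, verbose = isTRUE(verbose)),
    class = "benchmark_config"
  )
}

#' Run the full imputation benchmark grid
#'
#' Executes the complete study design: one complete dataset (synthesized or
#' supplied), amputed once per (condition, repeat) -- the identical masked
#' dataset is handed to every method -- then imputed with every requested
#' method and scored. Scores are NRMSE of abundances (log2), NRMSE of
#' intergroup ratios against the designed fold changes, and per-comparison
#' TP/FP/FADR of the DE test; optionally repeat-averaged ROC curves.
#' Failures of a single (condition, method, repeat) cell are recorded and
#' do not abort the grid.
#'
#' @param cfg a [benchmark_config()].
#' @return An object of class `benchmark_report`: `accuracy` (one row per
#'   condition x repeat x method with the two NRMSEs), `de` (one row per
#'   condition x repeat x method x comparison with TP/FP/FADR/TPR/FPR),
#'   `roc` (list, if requested), `failed` (error records), and the config.
#' @export
run_benchmark <- function(cfg) {
  stopifnot(inherits(cfg, "benchmark_config"))
  log_msg <- function(...) if (cfg$verbose) message(sprintf(...))

  if (is.null(cfg$source)) {
    log_msg("generating synthetic benchmark (seed %d)", cfg$base_seed)
    x <- generate_benchmark(cfg$design, n_proteins = cfg$n_proteins,
                            log2_location = cfg$log2_location,
                            log2_scale = cfg$log2_scale,
                            noise_sd = cfg$noise_sd, seed = cfg$base_seed)
  } else {
    x <- cfg$source
    stopifnot(inherits(x, "abundance_matrix"))
    if (anyNA(x$values)) {
      stop("source matrix has missing entries; pre-filter with complete_subset()")
    }
  }
  lx <- log2_transform(x)
  design <- x$design %||% cfg$design
  has_labels <- !is.null(x$species) && !any(is.na(x$species))
  ctrl <- design$control_group
  test_groups <- intersect(setdiff(design$group_ids, ctrl), unique(x$groups))

  grid <- expand.grid(alpha = cfg$mv_rates, beta = cfg$mnar_rates,
                      KEEP.OUT.ATTRS = FALSE)
  acc <- list(); de_rows <- list(); failed <- list()
  adjp_store <- if (cfg$compute_roc) list() else NULL

  for (r in seq_len(cfg$n_repeats)) {
    rep_seed <- derive_seed(cfg$base_seed, r)
    for (gi in seq_len(nrow(grid))) {
      alpha <- grid$alpha[gi]; beta <- grid$beta[gi]
      md <- simulate_missingness(
        lx, missingness_spec(alpha, beta, sigma_T = cfg$sigma_T,
                             seed = rep_seed))
      mask_id <- sprintf("%d:%.0f", sum(md$mask),
                         sum(as.double(which(md$mask)) %% 2^31))
      log_msg("repeat %d | MV %.0f%% MNAR %.0f%% | %d missing entries",
              r, 100 * alpha, 100 * beta, sum(md$mask))
      for (m in cfg$methods) {
        args <- c(list(method = m, seed = rep_seed), cfg$method_args[[m]])
        icfg <- do.call(imputation_config, args)
        cell <- tryCatch({
          t0 <- proc.time()[["elapsed"]]
          imp <- impute(md, icfg)
          elapsed <- proc.time()[["elapsed"]] - t0
          nr_ab <- nrmse_abundance(imp, md$truth, md$mask)
          nr_ratio <- NA_real_
          if (has_labels) {
            ratios <- intergroup_ratios(imp$values, md$groups, ctrl)
            nr_ratio <- nrmse_ratios(
              ratios[, paste0(test_groups, "/", ctrl), drop = FALSE],
              design, md$species)
          }
          log_msg("  %-4s NRMSE %.3f (%.1fs)", m, nr_ab, elapsed)
          list(imp = imp, nr_ab = nr_ab, nr_ratio = nr_ratio)
        }, error = function(e) e)
        if (inherits(cell, "error")) {
          failed[[length(failed) + 1L]] <- data.frame(
            alpha = alpha, beta = beta, rep = r, method = m,
            error = conditionMessage(cell), stringsAsFactors = FALSE)
          next
        }
        acc[[length(acc) + 1L]] <- data.frame(
          alpha = alpha, beta = beta, rep = r, method = m,
          mask_id = mask_id, nrmse_abundance = cell$nr_ab,
          nrmse_ratio = cell$nr_ratio, stringsAsFactors = FALSE)
        if (has_labels) {
          for (g in test_groups) {
            de <- de_test(cell$imp$values,
                          control_cols = md$groups == ctrl,
                          test_cols = md$groups == g,
                          species = md$species,
                          comparison = paste0(g, "/", ctrl))
            cc <- confusion_counts(de, cfg$positive_species, cfg$de_alpha)
            de_rows[[length(de_rows) + 1L]] <- data.frame(
              alpha = alpha, beta = beta, rep = r, method = m,
              comparison = paste0(g, "/", ctrl),
              TP = cc$TP, FP = cc$FP, FN = cc$FN, TN = cc$TN,
              FADR = cc$FADR, TPR = cc$TPR, FPR = cc$FPR,
              stringsAsFactors = FALSE)
            if (cfg$compute_roc) {
              key <- sprintf("%g|%g|%s|%s", alpha, beta, m,
                             paste0(g, "/", ctrl))
              adjp_store[[key]] <- c(adjp_store[[key]], list(de))
            }
          }
        }
      }
    }
  }

  roc <- NULL
  if (cfg$compute_roc && length(adjp_store)) {
    roc <- lapply(adjp_store, roc_curve,
                  positive_species = cfg$positive_species)
  }
  structure(
    list(accuracy = do.call(rbind, acc),
         de = if (length(de_rows)) do.call(rbind, de_rows) else NULL,
         roc = roc,
         failed = if (length(failed)) do.call(rbind, failed) else NULL,
         config = cfg,
         provenance = list(
           package_version = as.character(utils::packageVersion("imputeBench")),
           base_seed = cfg$base_seed)),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Benchmark report: %d conditions x %d repeats x %d methods\n",
              length(cfg$mv_rates) * length(cfg$mnar_rates),
              cfg$n_repeats, length(cfg$methods)))
  cat(sprintf("  %d accuracy cells, %d DE rows, %d failures\n",
              NROW(x$accuracy), NROW(x$de), NROW(x$failed)))
  invisible(x)
}

#' Aggregate a benchmark report over repeats
#'
#' @param object a `benchmark_report`.
#' @param ... unused.
#' @return A list of data frames: `by_condition` (mean and sd of both
#'   NRMSEs per condition x method), `overall` (per-method means across the
#'   whole grid) and, when DE results exist, `de_by_condition` and
#'   `de_overall` with mean TP and FADR.
#' @export
summary.benchmark_report <- function(object, ...) {
  acc <- object$accuracy
  agg <- function(df, keys, vars) {
    if (is.null(df)) return(NULL)
    means <- stats::aggregate(df[vars], df[keys], mean)
    sds <- stats::aggregate(df[vars], df[keys], stats::sd)
    names(means)[-seq_along(keys)] <- paste0(vars, "_mean")
    names(sds)[-seq_along(keys)] <- paste0(vars, "_sd")
    merge(means, sds, by = keys, sort = TRUE)
  }
  out <- list(
    by_condition = agg(acc, c("alpha", "beta", "method"),
                       c("nrmse_abundance", "nrmse_ratio")),
    overall = agg(acc, "method", c("nrmse_abundance", "nrmse_ratio")),
    de_by_condition = agg(object$de,
                          c("alpha", "beta", "method", "comparison"),
                          c("TP", "FP", "FADR")),
    de_overall = agg(object$de, "method", c("TP", "FP", "FADR"))
  )
  class(out) <- "summary.benchmark_report"
  out
}

#' @export
print.summary.benchmark_report <- function(x, ...) {
  cat("Overall NRMSE by method:\n")
  print(x$overall, digits = 4)
  if (!is.null(x$de_overall)) {
    cat("\nOverall DE detection by method:\n")
    print(x$de_overall, digits = 4)
  }
  invisible(x)
}

#' @export
plot.benchmark_report <- function(x, metric = c("nrmse_abundance",
                                                "nrmse_ratio", "FADR"), ...) {
  metric <- match.arg(metric)
  if (metric == "FADR") {
    if (is.null(x$de)) stop("report has no DE results")
    s <- stats::aggregate(list(value = x$de$FADR),
                          list(method = x$de$method), mean)
  } else {
    s <- stats::aggregate(list(value = x$accuracy[[metric]]),
                          list(method = x$accuracy$method), mean)
  }
  graphics::barplot(s$value, names.arg = s$method, ylab = metric,
                    main = sprintf("Mean %s over the condition grid", metric),
                    ...)
  invisible(x)
}

#' Write a benchmark report to disk
#'
#' Writes `report.json` (machine-readable: config scalars, accuracy and DE
#' tables, provenance) and TSV summaries (`accuracy.tsv`, `de.tsv`,
#' `summary_nrmse.tsv`, `summary_de.tsv`) into `dir`.
#'
#' @param report a `benchmark_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark_report <- function(report, dir) {
  stopifnot(inherits(report, "benchmark_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- summary(report)
  cfg <- report$config
  payload <- list(
    config = list(mv_rates = cfg$mv_rates, mnar_rates = cfg$mnar_rates,
                  n_repeats = cfg$n_repeats, methods = cfg$methods,
                  base_seed = cfg$base_seed, sigma_T = cfg$sigma_T,
                  de_alpha = cfg$de_alpha),
    provenance = report$provenance,
    accuracy = report$accuracy,
    de = report$de,
    failed = report$failed
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  wr <- function(df, f) if (!is.null(df)) {
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(report$accuracy, "accuracy.tsv")
  wr(report$de, "de.tsv")
  wr(s$by_condition, "summary_nrmse.tsv")
  wr(s$de_by_condition, "summary_de.tsv")
  invisible(dir)
}
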