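# Scoring of imputations: NRMSE on abundances and intergroup ratios,
# pooled-variance DE testing with BH adjustment, confusion counts / FADR,
# and repeat-averaged ROC curves.

# Pooled-variance two-sample t-test on two numeric vectors; returns
# c(t, p). Degenerate zero pooled variance: equal means -> p = 1,
# unequal means -> p = 0 (perfect separation).
pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  dfree <- na + nb - 2L
  sp2 <- ((na - 1L) * stats::var(a) + (nb - 1L) * stats::var(b)) / dfree
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  d <- mean(b) - mean(a)
  if (se == 0) {
    return(c(t = if (d == 0) 0 else sign(d) * Inf,
             p = if (d == 0) 1 else 0))
  }
  tt <- d / se
  c(t = tt, p = 2 * stats::pt(-abs(tt), dfree))
}

#' NRMSE of imputed abundances
#'
#' Root mean squared error between imputed and true values at the
#' originally-missing entries, normalized by the (sample, n-1) standard
#' deviation of the true values at those entries. 0 means perfect
#' imputation; values near 1 are no better than imputing the mean of the
#' missing truths. Computed on the log2 scale throughout the pipeline.
#' Evaluation is restricted to masked entries because observed entries pass
#' through imputation unchanged and would dilute the error toward zero.
#'
#' @param imputed an `imputed_matrix`, or a completed numeric matrix.
#' @param truth the complete matrix before amputation (same shape).
#' @param mask logical matrix, `TRUE` at the originally-missing entries.
#' @return A single number.
#' @export
nrmse_abundance <- function(imputed, truth, mask) {
  if (inherits(imputed, "imputed_matrix")) imputed <- imputed$values
  stopifnot(is.matrix(imputed), all(dim(imputed) == dim(truth)),
            all(dim(mask) == dim(truth)))
  if (!any(mask)) stop("mask selects no entries")
  err <- imputed[mask] - truth[mask]
  v <- stats::var(truth[mask])
  if (!is.finite(v) || v == 0) {
    stop("true values at missing entries have zero variance; NRMSE undefined")
  }
  sqrt(mean(err^2) / v)
}

#' Intergroup protein ratios
#'
#' Linear-scale fold change of every protein in each non-control group
#' relative to the control: `2^(mean log2 in group - mean log2 in control)`.
#'
#' @param m complete numeric matrix on the log2 scale (imputed or original).
#' @param groups character vector of per-column group labels.
#' @param control_group the control group id.
#' @return Numeric matrix, proteins x comparisons, with columns named
#'   `<group>/<control>`.
#' @export
intergroup_ratios <- function(m, groups, control_group) {
  if (inherits(m, "imputed_matrix")) m <- m$values
  if (inherits(m, "abundance_matrix")) {
    m_ <- log2_transform(m); groups <- m$groups; m <- m_$values
  }
  stopifnot(is.matrix(m), length(groups) == ncol(m))
  if (anyNA(m)) stop("ratios require a complete matrix; impute first")
  if (!control_group %in% groups) stop("control group not present")
  ctrl_mean <- rowMeans(m[, groups == control_group, drop = FALSE])
  test_groups <- setdiff(unique(groups), control_group)
  out <- vapply(test_groups, function(g) {
    2^(rowMeans(m[, groups == g, drop = FALSE]) - ctrl_mean)
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m),
                                paste0(test_groups, "/", control_group)))
  out
}

#' NRMSE of intergroup ratios against the designed ratios
#'
#' Compares observed post-imputation fold changes with the fold changes the
#' spike-in design dictates, over all (protein, comparison) pairs, on the
#' linear ratio scale, with the same variance-normalized RMSE as
#' [nrmse_abundance()]. All labeled proteins take part, including the
#' background species whose designed ratio is 1.
#'
#' @param observed_ratios proteins x comparisons matrix from
#'   [intergroup_ratios()] (comparison columns named `<group>/<control>`).
#' @param design the [group_design()] the data was generated from.
#' @param species per-protein species labels (rows of `observed_ratios`).
#' @return A single number.
#' @export
nrmse_ratios <- function(observed_ratios, design, species) {
  stopifnot(inherits(design, "group_design"),
            length(species) == nrow(observed_ratios))
  tab <- designated_ratio_table(design)
  comps <- colnames(observed_ratios)
  grp <- sub("/.*$", "", comps)
  if (!all(grp %in% colnames(tab))) stop("unknown comparison group in columns")
  truth <- vapply(grp, function(g) tab[species, g], numeric(length(species)))
  truth <- matrix(truth, nrow = length(species))
  err <- as.vector(observed_ratios) - as.vector(truth)
  v <- stats::var(as.vector(truth))
  if (!is.finite(v) || v == 0) {
    stop("designed ratios are constant; ratio NRMSE undefined")
  }
  sqrt(mean(err^2) / v)
}

#' Differential-expression test between two groups
#'
#' Per-protein two-sample pooled-variance (equal-variance) Student's t-test
#' on log2 intensities, two-sided, with Benjamini-Hochberg adjustment
#' across all proteins of the comparison. Zero pooled variance is resolved
#' as p = 1 for equal means and p = 0 for unequal means.
#'
#' @param m complete numeric matrix on the log2 scale.
#' @param control_cols,test_cols column indices (or logical vectors) of the
#'   control and test group samples (>= 2 each).
#' @param species optional per-protein species labels carried through.
#' @param comparison optional comparison id (e.g. `"B/A"`).
#' @return A data frame of class `de_result`: per protein the group means
#'   (log2), linear ratio, t statistic, degrees of freedom, raw and
#'   BH-adjusted p-values.
#' @export
de_test <- function(m, control_cols, test_cols, species = NULL,
                    comparison = "") {
  if (inherits(m, "imputed_matrix")) m <- m$values
  stopifnot(is.matrix(m))
  if (anyNA(m)) stop("DE testing requires a complete matrix; impute first")
  A <- m[, control_cols, drop = FALSE]
  B <- m[, test_cols, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  if (na < 2L || nb < 2L) stop("need >= 2 samples per group")
  dfree <- na + nb - 2L
  ma <- rowMeans(A); mb <- rowMeans(B)
  sp2 <- ((na - 1L) * row_vars(A) + (nb - 1L) * row_vars(B)) / dfree
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  d <- mb - ma
  tt <- d / se
  p <- 2 * stats::pt(-abs(tt), dfree)
  degen <- se == 0
  if (any(degen)) {
    tt[degen] <- ifelse(d[degen] == 0, 0, sign(d[degen]) * Inf)
    p[degen] <- ifelse(d[degen] == 0, 1, 0)
  }
  out <- data.frame(
    protein = rownames(m) %||% as.character(seq_len(nrow(m))),
    species = if (is.null(species)) NA_character_ else as.character(species),
    mean_control = ma,
    mean_test = mb,
    ratio = 2^d,
    t = tt,
    df = dfree,
    p = p,
    adj_p = stats::p.adjust(p, method = "BH"),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  attr(out, "comparison") <- comparison
  class(out) <- c("de_result", class(out))
  out
}

#' Confusion counts and FADR of a DE result
#'
#' Classifies significance calls (BH-adjusted p below `alpha`) against the
#' spike-in ground truth: proteins of the positive (spiked) species are
#' true positives when called, false negatives otherwise; background
#' proteins called significant are false positives. The false
#' altered-protein discovery rate is `FADR = FP / (TP + FP)`, defined as 0
#' when nothing is called.
#'
#' @param de a `de_result` from [de_test()] (with species labels).
#' @param positive_species character vector of spiked species labels.
#' @param alpha significance cutoff on the adjusted p-value (default 0.05).
#' @return A list of class `confusion_counts`: `TP`, `FP`, `FN`, `TN`,
#'   `FADR`, `TPR`, `FPR`.
#' @export
confusion_counts <- function(de, positive_species = c("ecoli", "yeast"),
                             alpha = 0.05) {
  if (any(is.na(de$species))) stop("species labels required")
  sig <- de$adj_p < alpha
  pos <- de$species %in% positive_species
  tp <- sum(sig & pos); fp <- sum(sig & !pos)
  fn <- sum(!sig & pos); tn <- sum(!sig & !pos)
  structure(list(
    TP = tp, FP = fp, FN = fn, TN = tn,
    FADR = if (tp + fp == 0) 0 else fp / (tp + fp),
    TPR = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    FPR = if (fp + tn == 0) NA_real_ else fp / (fp + tn)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d | FADR %.3f  TPR %.3f  FPR %.3f\n",
              x$TP, x$FP, x$FN, x$TN, x$FADR, x$TPR, x$FPR))
  invisible(x)
}

#' Repeat-averaged ROC curve of DE detection
#'
#' Sweeps a threshold over the adjusted p-values: at each threshold the
#' true- and false-positive rates are computed per repeat and then averaged
#' component-wise across repeats (vertical averaging at shared thresholds).
#' The curve is anchored at (0, 0) and reaches (1, 1) at threshold 1; the
#' area under the averaged curve is computed by the trapezoidal rule.
#'
#' @param de_results a `de_result` or list of them (one per repeat; same
#'   proteins and labels in each).
#' @param positive_species spiked species labels (ground-truth positives).
#' @param thresholds increasing adjusted-p thresholds in `[0, 1]`,
#'   containing 0 and 1.
#' @return An object of class `roc_curve`: data frame of `(threshold, FPR,
#'   TPR)` points and an `auc` attribute.
#' @export
roc_curve <- function(de_results, positive_species = c("ecoli", "yeast"),
                      thresholds = c(0, 10^seq(-8, -1, by = 0.25),
                                     seq(0.15, 1, by = 0.05))) {
  if (is.data.frame(de_results)) de_results <- list(de_results)
  stopifnot(length(de_results) >= 1L)
  thresholds <- sort(unique(pmin(pmax(thresholds, 0), 1)))
  if (thresholds[1L] != 0 || thresholds[length(thresholds)] != 1) {
    stop("`thresholds` must include 0 and 1")
  }
  rates <- lapply(de_results, function(de) {
    if (any(is.na(de$species))) stop("species labels required")
    pos <- de$species %in% positive_species
    n_pos <- sum(pos); n_neg <- sum(!pos)
    if (n_pos == 0L || n_neg == 0L) {
      stop("ROC needs at least one positive and one negative protein")
    }
    t(vapply(thresholds, function(th) {
      sig <- de$adj_p <= th
      c(FPR = sum(sig & !pos) / n_neg, TPR = sum(sig & pos) / n_pos)
    }, c(FPR = 0, TPR = 0)))
  })
  avg <- Reduce(`+`, rates) / length(rates)
  pts <- data.frame(threshold = c(-Inf, thresholds),
                    FPR = c(0, avg[, "FPR"]),
                    TPR = c(0, avg[, "TPR"]))
  auc <- sum(diff(pts$FPR) * (utils::head(pts$TPR, -1) +
                                utils::tail(pts$TPR, -1)) / 2)
  structure(pts, auc = auc, class = c("roc_curve", class(pts)))
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$FPR, x$TPR, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  graphics::legend("bottomright", bty = "n",
                   legend = sprintf("AUC = %.3f", attr(x, "auc")))
  invisible(x)
}
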