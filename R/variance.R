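# Variance attribution: PCA of cohort expression, correlation of components
# with pathway activity, and nested linear models quantifying how much PC
# variance a labelling scheme (phenotype, subgroup, receptor status) adds.

#' Principal components of a cohort expression matrix
#'
#' Gene-wise centered, unscaled PCA over samples (prcomp convention) on
#' log2(TPM+1) data. Total variance is conserved: the per-PC variances sum
#' to the total centered variance of the data.
#'
#' @param expr Gene x sample matrix with at least `n_pcs + 1` samples.
#' @param n_pcs Components to retain (default 5).
#' @return List of class `gfrn_pca`: `scores` (sample x PC),
#'   `variance_fraction` (per retained PC), `sdev` (all PCs), and the full
#'   `prcomp` fit (loadings available as `$fit$rotation`).
#' @export
pca_samples <- function(expr, n_pcs = 5) {
  if (ncol(expr) < n_pcs + 1) {
    stop("need at least n_pcs + 1 samples", call. = FALSE)
  }
  fit <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(fit$x))
  out <- list(
    scores = fit$x[, seq_len(k), drop = FALSE],
    variance_fraction = (fit$sdev^2 / sum(fit$sdev^2))[seq_len(k)],
    sdev = fit$sdev,
    fit = fit
  )
  class(out) <- "gfrn_pca"
  out
}

#' @export
print.gfrn_pca <- function(x, ...) {
  cat("Sample PCA:", nrow(x$scores), "samples,", ncol(x$scores),
      "retained PCs\n")
  cat("  variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction), collapse = " "), "\n")
  cat("  cumulative:", sprintf("%.1f%%", 100 * sum(x$variance_fraction)),
      "\n")
  invisible(x)
}

#' Spearman correlation of principal components with pathway activity
#'
#' @param pcs A `gfrn_pca` (or a sample x PC score matrix).
#' @param act Pathway x sample activity matrix (raw or scaled).
#' @return List with matrices `rho` and `p` (PC x pathway).
#' @export
correlate_pcs_with_activity <- function(pcs, act) {
  scores <- if (inherits(pcs, "gfrn_pca")) pcs$scores else as.matrix(pcs)
  shared <- intersect(rownames(scores), colnames(act))
  if (length(shared) < 3) {
    stop("fewer than 3 matched samples", call. = FALSE)
  }
  scores <- scores[shared, , drop = FALSE]
  act <- act[, shared, drop = FALSE]
  rho <- p <- matrix(NA_real_, ncol(scores), nrow(act),
                     dimnames = list(colnames(scores), rownames(act)))
  for (i in seq_len(ncol(scores))) {
    for (j in seq_len(nrow(act))) {
      ct <- suppressWarnings(
        stats::cor.test(scores[, i], act[j, ], method = "spearman"))
      rho[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(rho = rho, p = p)
}

#' Compare nested linear models of a principal component
#'
#' Fits `pc ~ base` and `pc ~ base + added` by least squares (categorical
#' labels expanded to treatment-coded indicators, first level by
#' lexicographic order) and reports both R-squared values and the partial
#' F-test for the added terms. Used to quantify how much cohort variance a
#' subgrouping scheme explains beyond, e.g., receptor status.
#'
#' @param pc_values Numeric response (PC scores), one per sample.
#' @param base Vector or data.frame of baseline labels.
#' @param added Vector or data.frame of additional labels.
#' @return List of class `model_comparison`: R2_base, R2_full, F, p, df,
#'   and the two fits.
#' @export
nested_model_comparison <- function(pc_values, base, added) {
  as_df <- function(x, nm) {
    if (is.data.frame(x)) x
    else stats::setNames(data.frame(x, stringsAsFactors = FALSE), nm)
  }
  bd <- as_df(base, "base")
  ad <- as_df(added, "added")
  bd[] <- lapply(bd, function(v) if (is.numeric(v)) v else factor(v))
  ad[] <- lapply(ad, function(v) if (is.numeric(v)) v else factor(v))
  df <- cbind(pc = pc_values, bd, ad)
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  f0 <- stats::lm(stats::reformulate(colnames(bd), response = "pc"),
                  data = df)
  f1 <- stats::lm(stats::reformulate(c(colnames(bd), colnames(ad)),
                                     response = "pc"), data = df)
  if (any(is.na(stats::coef(f1)))) {
    warning("rank-deficient design; aliased columns dropped", call. = FALSE)
  }
  an <- stats::anova(f0, f1)
  out <- list(
    base_terms = colnames(bd), added_terms = colnames(ad),
    R2_base = suppressWarnings(summary(f0)$r.squared),
    R2_full = suppressWarnings(summary(f1)$r.squared),
    F = an[["F"]][2], p = an[["Pr(>F)"]][2],
    df = an[["Df"]][2], fit_base = f0, fit_full = f1
  )
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Nested model comparison: pc ~", paste(x$base_terms, collapse = " + "),
      " vs + ", paste(x$added_terms, collapse = " + "), "\n")
  cat(sprintf("  R2 %.4f -> %.4f (gain %.4f), F = %.2f, p = %.3g\n",
              x$R2_base, x$R2_full, x$R2_full - x$R2_base, x$F, x$p))
  invisible(x)
}

#' Correlation of per-sample mean expression with each PC
#'
#' The leading component of bulk expression data often tracks the average
#' expression level of each sample (a library-size-like technical signal);
#' this reports the Spearman correlation between per-sample mean expression
#' and each retained PC.
#'
#' @param expr Gene x sample matrix.
#' @param pcs A `gfrn_pca` on the same samples.
#' @return data.frame with columns pc, rho, p. Degenerate (constant) means
#'   yield NA with a warning.
#' @export
mean_expression_correlation <- function(expr, pcs) {
  scores <- pcs$scores
  m <- colMeans(expr[, rownames(scores), drop = FALSE])
  if (stats::sd(m) == 0) {
    warning("per-sample mean expression is constant; correlation undefined",
            call. = FALSE)
    return(data.frame(pc = colnames(scores), rho = NA_real_, p = NA_real_))
  }
  res <- lapply(seq_len(ncol(scores)), function(i) {
    ct <- suppressWarnings(
      stats::cor.test(m, scores[, i], method = "spearman"))
    data.frame(pc = colnames(scores)[i], rho = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
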