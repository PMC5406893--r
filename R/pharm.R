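# Dose-response pharmacology: two-parameter logistic EC50 fitting with fixed
# asymptotes (Ymin = 0, Ymax = 1), drug-sensitivity derivation
# (-logEC50), activity-sensitivity correlation structure, and subgroup drug
# tests with FDR control.

# response model: Y = 1 / (1 + 10^((logEC50 - X) * HillSlope))
.hill <- function(x, logec50, hillslope) {
  1 / (1 + 10^((logec50 - x) * hillslope))
}

#' Fit a two-parameter logistic dose-response curve
#'
#' Nonlinear least squares on
#' `Y = 1 / (1 + 10^((logEC50 - X) * HillSlope))` with asymptotes fixed at
#' 0 and 1 (variable slope). Robustness comes from a multi-start grid:
#' five logEC50 starts spanning the observed dose range crossed with Hill
#' slopes 0.5, 1 and 2; the converged fit with the lowest residual sum of
#' squares is kept. Sensitivity is only considered finite when the fitted
#' logEC50 lies within the dose range plus an extrapolation margin.
#'
#' @param dose Numeric doses in log10 molar (>= 4 distinct values).
#' @param viability Response fraction per point; values are clipped to
#'   [0, 1.5] with a warning when outside [0, 1].
#' @param extrapolation Allowed logEC50 distance beyond the dose range
#'   before the fit is flagged out-of-range (default 2 log10 units).
#' @return Object of class `dose_response_fit`: logec50, hillslope,
#'   converged, flag ("ok", "no_convergence", "no_response",
#'   "out_of_range"), rss, and the fitting data.
#' @export
#' @examples
#' x <- seq(-9, -4, length.out = 6)
#' y <- 1 / (1 + 10^((-6 - x) * 1))
#' fit <- fit_dose_response(x, y)
#' coef(fit)
fit_dose_response <- function(dose, viability, extrapolation = 2) {
  stopifnot(length(dose) == length(viability))
  if (length(unique(dose)) < 4) {
    stop("need >= 4 distinct doses", call. = FALSE)
  }
  if (any(viability < 0 | viability > 1, na.rm = TRUE)) {
    warning("viability outside [0, 1]; clipped to [0, 1.5]", call. = FALSE)
  }
  y <- pmin(pmax(viability, 0), 1.5)
  keep <- is.finite(dose) & is.finite(y)
  x <- dose[keep]; y <- y[keep]
  res <- structure(
    list(logec50 = NA_real_, hillslope = NA_real_, converged = FALSE,
         flag = "no_convergence", rss = NA_real_,
         data = data.frame(dose = x, viability = y)),
    class = "dose_response_fit")
  if (stats::sd(y) < 1e-8) {
    res$flag <- "no_response"
    return(res)
  }
  starts <- expand.grid(
    logec50 = seq(min(x), max(x), length.out = 5),
    hillslope = c(0.5, 1, 2))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ 1 / (1 + 10^((logec50 - x) * hillslope)),
        start = as.list(starts[i, ]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(coef = stats::coef(fit), rss = rss)
    }
  }
  if (is.null(best)) return(res)
  res$logec50 <- unname(best$coef["logec50"])
  res$hillslope <- unname(best$coef["hillslope"])
  res$rss <- best$rss
  res$converged <- TRUE
  res$flag <- if (res$logec50 < min(x) - extrapolation ||
                  res$logec50 > max(x) + extrapolation) {
    "out_of_range"
  } else {
    "ok"
  }
  res
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "Dose-response fit: logEC50 = %.3f, HillSlope = %.3f (%s, RSS %.3g)\n",
      x$logec50, x$hillslope, x$flag, x$rss))
  } else {
    cat("Dose-response fit: not converged (", x$flag, ")\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(logec50 = object$logec50, hillslope = object$hillslope)
}

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$dose
       else if (is.list(newdata)) newdata$dose else newdata
  .hill(x, object$logec50, object$hillslope)
}

#' @export
residuals.dose_response_fit <- function(object, ...) {
  object$data$viability - predict(object)
}

#' @export
plot.dose_response_fit <- function(x, ...) {
  plot(x$data$dose, x$data$viability, xlab = "dose (log10 M)",
       ylab = "response", ylim = c(0, max(1, x$data$viability)), ...)
  if (x$converged) {
    xs <- seq(min(x$data$dose), max(x$data$dose), length.out = 100)
    graphics::lines(xs, .hill(xs, x$logec50, x$hillslope))
    graphics::abline(v = x$logec50, lty = 2)
  }
  invisible(x)
}

#' Drug sensitivity from a dose-response fit
#'
#' Sensitivity is the negative log EC50 (-logEC50, in -log10 molar):
#' higher values mean the drug acts at lower concentration. Non-convergent
#' or out-of-range fits propagate as NA.
#'
#' @param fit A `dose_response_fit`.
#' @return Numeric sensitivity, or NA.
#' @export
sensitivity_from_fit <- function(fit) {
  if (!fit$converged || fit$flag != "ok") return(NA_real_)
  -fit$logec50
}

#' Fit a whole dose-response panel
#'
#' Fits every (cell line, drug) series in a long-format table and derives
#' sensitivities.
#'
#' @param panel data.frame with columns cell_line, drug, dose_log10M,
#'   viability (replicate rows allowed).
#' @param ... Passed to [fit_dose_response()].
#' @return data.frame: cell_line, drug, logec50, hillslope, converged,
#'   flag, sensitivity.
#' @export
fit_dose_response_panel <- function(panel, ...) {
  stopifnot(all(c("cell_line", "drug", "dose_log10M", "viability") %in%
                  names(panel)))
  keys <- unique(panel[, c("cell_line", "drug")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- panel[panel$cell_line == keys$cell_line[i] &
                   panel$drug == keys$drug[i], ]
    fit <- fit_dose_response(sub$dose_log10M, sub$viability, ...)
    data.frame(cell_line = keys$cell_line[i], drug = keys$drug[i],
               logec50 = fit$logec50, hillslope = fit$hillslope,
               converged = fit$converged, flag = fit$flag,
               sensitivity = sensitivity_from_fit(fit),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# internal: long sensitivity table -> lines x drugs matrix
.sens_matrix <- function(sens) {
  stopifnot(all(c("cell_line", "drug", "sensitivity") %in% names(sens)))
  lines <- unique(sens$cell_line)
  drugs <- unique(sens$drug)
  m <- matrix(NA_real_, length(lines), length(drugs),
              dimnames = list(lines, drugs))
  m[cbind(match(sens$cell_line, lines), match(sens$drug, drugs))] <-
    sens$sensitivity
  m
}

#' Pathway activity vs drug sensitivity correlations
#'
#' Spearman correlation of each pathway's activity with each drug's
#' sensitivity across cell lines, missing sensitivities dropped pairwise.
#' Drugs with fewer than three complete pairs, or with constant
#' sensitivity, are excluded with a warning. The raw correlation matrix is
#' returned together with a display variant z-scaled within each drug for
#' heatmaps.
#'
#' @param act Pathway x cell-line activity matrix.
#' @param sens Long data.frame (cell_line, drug, sensitivity) or a
#'   cell-line x drug sensitivity matrix.
#' @return List with `rho` and `p` (pathway x drug), `display` (row-scaled
#'   per drug), and `excluded` (drug names dropped).
#' @export
activity_drug_correlation <- function(act, sens) {
  m <- if (is.matrix(sens)) sens else .sens_matrix(sens)
  shared <- intersect(colnames(act), rownames(m))
  act <- act[, shared, drop = FALSE]
  m <- m[shared, , drop = FALSE]
  excluded <- character(0)
  keep <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ok <- sum(is.finite(v)) >= 3 &&
      stats::sd(v[is.finite(v)]) > 0
    keep[j] <- ok
    if (!ok) excluded <- c(excluded, colnames(m)[j])
  }
  if (length(excluded)) {
    warning("excluded drug(s) with <3 complete pairs or constant ",
            "sensitivity: ", paste(excluded, collapse = ", "),
            call. = FALSE)
  }
  m <- m[, keep, drop = FALSE]
  rho <- p <- matrix(NA_real_, nrow(act), ncol(m),
                     dimnames = list(rownames(act), colnames(m)))
  for (i in seq_len(nrow(act))) {
    for (j in seq_len(ncol(m))) {
      fin <- is.finite(m[, j]) & is.finite(act[i, ])
      ct <- suppressWarnings(
        stats::cor.test(act[i, fin], m[fin, j], method = "spearman"))
      rho[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  display <- rho
  for (j in seq_len(ncol(rho))) {
    v <- rho[, j]
    s <- stats::sd(v)
    display[, j] <- if (is.na(s) || s == 0) 0 else (v - mean(v)) / s
  }
  list(rho = rho, p = p, display = display, excluded = excluded)
}

#' Subgroup drug-response tests with FDR control
#'
#' For each requested subgroup comparison, runs a Welch t-test of drug
#' sensitivity per drug and adjusts p values across drugs within that
#' comparison family by Benjamini-Hochberg. Drugs with fewer than two
#' finite sensitivities in either subgroup are skipped.
#'
#' @param sens Long sensitivity data.frame (cell_line, drug, sensitivity).
#' @param subgroups Named vector sample -> subgroup label.
#' @param comparisons List of length-2 character vectors (subgroup A vs B).
#' @param q_threshold FDR threshold for the `significant` flag
#'   (default 0.05).
#' @return data.frame: comparison, drug, t, p, q, significant.
#' @export
subgroup_drug_tests <- function(sens, subgroups, comparisons,
                                q_threshold = 0.05) {
  out <- list()
  for (cmp in comparisons) {
    stopifnot(length(cmp) == 2)
    rows <- list()
    for (dr in unique(sens$drug)) {
      sd_ <- sens[sens$drug == dr & is.finite(sens$sensitivity), ]
      g <- subgroups[sd_$cell_line]
      va <- sd_$sensitivity[g == cmp[1] & !is.na(g)]
      vb <- sd_$sensitivity[g == cmp[2] & !is.na(g)]
      if (length(va) < 2 || length(vb) < 2) next
      tt <- group_difference_test(
        c(va, vb), rep(cmp, c(length(va), length(vb))), cmp[1], cmp[2])
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste(cmp, collapse = " vs "), drug = dr,
        t = tt$t, p = tt$p, stringsAsFactors = FALSE)
    }
    if (!length(rows)) next
    fam <- do.call(rbind, rows)
    fam$q <- stats::p.adjust(fam$p, method = "BH")
    fam$significant <- fam$q < q_threshold
    out[[length(out) + 1L]] <- fam
  }
  if (!length(out)) {
    return(data.frame(comparison = character(0), drug = character(0),
                      t = numeric(0), p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  }
  do.call(rbind, out)
}

#' Binarize drug sensitivity around the per-drug mean
#'
#' The cutoff for each drug is the mean sensitivity over all cell lines
#' with a finite value; lines strictly above the cutoff are "sensitive",
#' all others "resistant". Drugs with every sensitivity missing are
#' excluded.
#'
#' @param sens Long sensitivity data.frame (cell_line, drug, sensitivity).
#' @return data.frame: cell_line, drug, call ("sensitive"/"resistant").
#' @export
binarize_sensitivity <- function(sens) {
  out <- list()
  for (dr in unique(sens$drug)) {
    sd_ <- sens[sens$drug == dr, ]
    fin <- is.finite(sd_$sensitivity)
    if (sum(fin) < 2) next
    cutoff <- mean(sd_$sensitivity[fin])
    sd_ <- sd_[fin, ]
    out[[length(out) + 1L]] <- data.frame(
      cell_line = sd_$cell_line, drug = dr,
      call = ifelse(sd_$sensitivity > cutoff, "sensitive", "resistant"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Count drugs responding differently between two label classes
#'
#' Per labelling scheme (e.g. receptor status or GFRN phenotype): Welch
#' t-test of sensitivity between the two classes for every drug with
#' enough coverage, then the count of drugs below the significance
#' threshold (optionally after multiple-testing correction).
#'
#' @param sens Long sensitivity data.frame (cell_line, drug, sensitivity).
#' @param labels Named binary label vector (cell line -> class).
#' @param alpha Significance threshold (default 0.05).
#' @param adjust p-value correction method (default "none"; any
#'   [stats::p.adjust()] method).
#' @return List: `count`, `n_tested`, `fraction`, and the per-drug table.
#' @export
phenotype_drug_significance_count <- function(sens, labels, alpha = 0.05,
                                              adjust = "none") {
  classes <- sort(unique(stats::na.omit(as.character(labels))))
  if (length(classes) != 2) {
    stop("labels must have exactly 2 classes", call. = FALSE)
  }
  rows <- list()
  for (dr in unique(sens$drug)) {
    sd_ <- sens[sens$drug == dr & is.finite(sens$sensitivity), ]
    g <- as.character(labels[sd_$cell_line])
    if (sum(g == classes[1], na.rm = TRUE) < 2 ||
        sum(g == classes[2], na.rm = TRUE) < 2) next
    keep <- !is.na(g)
    tt <- group_difference_test(sd_$sensitivity[keep], g[keep],
                                classes[1], classes[2])
    rows[[length(rows) + 1L]] <- data.frame(drug = dr, t = tt$t, p = tt$p,
                                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    return(list(count = 0L, n_tested = 0L, fraction = NA_real_,
                table = NULL))
  }
  tab$p_adj <- stats::p.adjust(tab$p, method = adjust)
  list(count = sum(tab$p_adj < alpha), n_tested = nrow(tab),
       fraction = mean(tab$p_adj < alpha), table = tab)
}
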