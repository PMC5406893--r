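# Signature length optimization against protein data, and the orthogonal
# validation utilities (percentile-defined expression groups, two-group
# t-tests on mutation-like annotations).

#' Gene-list length grid for the signature scan
#'
#' The default scan covers 25 to 500 genes in steps of 25 (20 lengths).
#' HER2 and AKT signatures perform better when short, so their grids are
#' extended with 5, 10, 15 and 20.
#'
#' @param pathway Pathway name.
#' @return Integer vector of candidate signature lengths.
#' @export
#' @examples
#' length(scan_grid("EGFR"))  # 20
#' scan_grid("HER2")[1:4]     # 5 10 15 20
scan_grid <- function(pathway) {
  grid <- seq(25L, 500L, by = 25L)
  if (pathway %in% c("HER2", "AKT")) grid <- c(5L, 10L, 15L, 20L, grid)
  grid
}

#' Scan signature lengths against protein correlations
#'
#' For every pathway, candidate length K and test cohort: builds the
#' K-gene signature, estimates cohort activity, and computes the Spearman
#' correlation (and p value) between activity and each mapped validation
#' protein. Proteins absent from a cohort's protein matrix are skipped with
#' a warning.
#'
#' @param train Training gene x sample matrix (batch-adjusted).
#' @param groups Group label per training column.
#' @param cohorts Named list of test expression matrices.
#' @param proteins Named list (same names as `cohorts`) of protein x sample
#'   matrices.
#' @param map Protein map data.frame with columns pathway, protein, sign
#'   (see [default_protein_map()]).
#' @param grid Integer vector of lengths, or NULL for the per-pathway
#'   default [scan_grid()].
#' @param control,anchors Passed to [gfrn_signatures()].
#' @param pathways Pathways to scan (default: all in `map`).
#' @param adaptive_background,adaptive_signature Passed to
#'   [estimate_activity()].
#' @return data.frame of class `length_scan`: pathway, K, cohort, protein,
#'   expected_sign, rho, p.
#' @export
scan_lengths <- function(train, groups, cohorts, proteins, map,
                         grid = NULL, control = "GFP", anchors = NULL,
                         pathways = NULL, adaptive_background = TRUE,
                         adaptive_signature = FALSE) {
  stopifnot(is.list(cohorts), is.list(proteins),
            all(names(cohorts) %in% names(proteins)))
  if (is.null(pathways)) pathways <- unique(map$pathway)
  groups <- as.character(groups)
  ctrl_cols <- colnames(train)[groups == control]
  out <- list()
  for (p in pathways) {
    cols <- colnames(train)[groups == p]
    d <- differential_weights(train, cols, ctrl_cols)
    anc <- if (!is.null(anchors) && p %in% names(anchors)) anchors[[p]]
           else if (p %in% names(d)) p else names(which.max(abs(d)))
    ks <- if (is.null(grid)) scan_grid(p) else grid
    pmap <- map[map$pathway == p, , drop = FALSE]
    for (K in ks) {
      sig <- build_signature(d, K, anc, pathway = p)
      for (co in names(cohorts)) {
        a <- estimate_activity(sig, cohorts[[co]],
                               adaptive_background = adaptive_background,
                               adaptive_signature = adaptive_signature)
        for (i in seq_len(nrow(pmap))) {
          prot <- pmap$protein[i]
          if (!prot %in% rownames(proteins[[co]])) {
            warning("protein '", prot, "' absent from cohort '", co,
                    "'; skipped", call. = FALSE)
            next
          }
          pv <- proteins[[co]][prot, colnames(cohorts[[co]])]
          ct <- suppressWarnings(
            stats::cor.test(a, pv, method = "spearman"))
          out[[length(out) + 1L]] <- data.frame(
            pathway = p, K = K, cohort = co, protein = prot,
            expected_sign = pmap$sign[i],
            rho = unname(ct$estimate), p = ct$p.value,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("length_scan", class(res))
  res
}

#' Choose the optimal signature length from a scan
#'
#' Candidate lengths must have every mapped protein correlation significant
#' in both cohorts, with the sign matching the expected direction, an
#' absolute correlation of at least `rho_min` in the secondary (cell-line)
#' cohort, and K at most `max_K`. Among candidates the length with the best
#' average expected-direction correlation (rho times expected sign) in the
#' primary cohort wins. With no candidate, the failure is flagged and
#' diagnostics retained.
#'
#' @param scan A `length_scan` from [scan_lengths()].
#' @param primary,secondary Cohort names (primary drives the argmax;
#'   secondary carries the `rho_min` filter).
#' @param rho_min Minimum |rho| in the secondary cohort (default 0.3).
#' @param max_K Maximum admissible length (default 300).
#' @param alpha Significance level for the correlation p values (raw,
#'   default 0.05).
#' @return data.frame with one row per pathway: chosen_K, score (primary
#'   expected-direction mean rho), n_candidates, ok.
#' @export
select_optimal_length <- function(scan, primary, secondary,
                                  rho_min = 0.3, max_K = 300, alpha = 0.05) {
  if (is.null(scan) || nrow(scan) == 0) stop("empty scan", call. = FALSE)
  stopifnot(all(c(primary, secondary) %in% scan$cohort))
  res <- lapply(unique(scan$pathway), function(p) {
    sp <- scan[scan$pathway == p, , drop = FALSE]
    cand <- vapply(unique(sp$K), function(K) {
      sk <- sp[sp$K == K, , drop = FALSE]
      if (K > max_K) return(NA_real_)
      for (co in c(primary, secondary)) {
        sc <- sk[sk$cohort == co, , drop = FALSE]
        if (nrow(sc) == 0) return(NA_real_)
        ok <- all(sc$p < alpha) &&
          all(sign(sc$rho) == sign(sc$expected_sign))
        if (!ok) return(NA_real_)
        if (co == secondary && any(abs(sc$rho) < rho_min)) {
          return(NA_real_)
        }
      }
      sc <- sk[sk$cohort == primary, , drop = FALSE]
      mean(sc$rho * sc$expected_sign)
    }, numeric(1))
    ks <- unique(sp$K)
    valid <- !is.na(cand)
    if (!any(valid)) {
      data.frame(pathway = p, chosen_K = NA_integer_, score = NA_real_,
                 n_candidates = 0L, ok = FALSE, stringsAsFactors = FALSE)
    } else {
      best <- which(valid)[which.max(cand[valid])]
      data.frame(pathway = p, chosen_K = as.integer(ks[best]),
                 score = cand[best], n_candidates = sum(valid), ok = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}

#' Percentile-defined expression groups
#'
#' Labels samples "high" when at or above the `hi_pct` percentile of the
#' values, "low" when at or below the `lo_pct` percentile, and
#' "intermediate" otherwise. Percentiles use the linear-interpolation
#' convention (R quantile type 7); thresholds are inclusive on both sides.
#' Defaults follow the 90/10 split used for most oncogenes (80/20 is used
#' for IGF1R).
#'
#' @param values Named numeric vector (one value per sample).
#' @param hi_pct,lo_pct Percentiles in [0, 100], `lo_pct < hi_pct`.
#' @return Named factor with levels low, intermediate, high.
#' @export
#' @examples
#' table(percentile_group_labels(setNames(1:100, paste0("s", 1:100))))
percentile_group_labels <- function(values, hi_pct = 90, lo_pct = 10) {
  if (!(lo_pct >= 0 && hi_pct <= 100 && lo_pct < hi_pct)) {
    stop("need 0 <= lo_pct < hi_pct <= 100", call. = FALSE)
  }
  thr_hi <- stats::quantile(values, hi_pct / 100, names = FALSE, type = 7)
  thr_lo <- stats::quantile(values, lo_pct / 100, names = FALSE, type = 7)
  lab <- rep("intermediate", length(values))
  if (thr_hi <= thr_lo) {
    warning("degenerate value distribution; all samples intermediate",
            call. = FALSE)
  } else {
    lab[values >= thr_hi] <- "high"
    lab[values <= thr_lo] <- "low"
  }
  factor(stats::setNames(lab, names(values)),
         levels = c("low", "intermediate", "high"))
}

#' Two-group difference test on activity (or any per-sample score)
#'
#' Welch's unequal-variance t-test by default (pooled-variance available via
#' `var_equal = TRUE`), two-sided. Used e.g. to compare pathway activity
#' between mutation-status groups.
#'
#' @param values Named numeric vector.
#' @param groups Group label per sample (same order/names as `values`).
#' @param a,b The two labels to compare (a minus b).
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return List with `t`, `p`, `df` and group means.
#' @export
group_difference_test <- function(values, groups, a, b, var_equal = FALSE) {
  groups <- as.character(groups)
  va <- values[groups == a]
  vb <- values[groups == b]
  if (length(va) < 2 || length(vb) < 2) {
    stop("need >= 2 samples in each of '", a, "' and '", b, "'",
         call. = FALSE)
  }
  if (stats::sd(va) == 0 && stats::sd(vb) == 0) {
    eq <- isTRUE(all.equal(mean(va), mean(vb)))
    return(list(t = if (eq) 0 else sign(mean(va) - mean(vb)) * Inf,
                p = if (eq) 1 else 0, df = NA_real_,
                mean_a = mean(va), mean_b = mean(vb)))
  }
  tt <- stats::t.test(va, vb, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(va), mean_b = mean(vb))
}
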