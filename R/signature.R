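# Signature construction and pathway-activity estimation.
#
# Signatures are built from overexpression-vs-control contrasts by a
# deterministic standardized-effect ranking, and projected onto test cohorts
# as signed mean z-scores rescaled to [0, 1]. This is a fully specified,
# reproducible scoring scheme: given the same training matrix and settings it
# always returns the same gene lists and activities.

.SD_FLOOR <- 1e-6

#' Standardized differential-expression weights
#'
#' Compares an overexpression group against controls gene by gene and returns
#' the standardized mean difference d = (mean_pathway - mean_control) /
#' pooled SD for every gene. The pooled SD is floored at 1e-6 so genes that
#' are constant in both groups still yield a finite effect.
#'
#' @param train Numeric gene x sample matrix (log2(TPM+1)).
#' @param pathway_group Character vector of column names in the
#'   overexpression group.
#' @param control_group Character vector of column names in the control
#'   group. Must be disjoint from `pathway_group`.
#' @return Named numeric vector of effects, one per gene (all genes kept).
#' @export
#' @examples
#' m <- rbind(g1 = c(2, 2, 0, 0), g2 = c(0, 0, 0, 0))
#' colnames(m) <- c("p1", "p2", "c1", "c2")
#' differential_weights(m, c("p1", "p2"), c("c1", "c2"))
differential_weights <- function(train, pathway_group, control_group) {
  if (length(intersect(pathway_group, control_group)) > 0) {
    stop("pathway and control groups overlap", call. = FALSE)
  }
  if (length(pathway_group) < 2 || length(control_group) < 2) {
    stop("need at least 2 replicates per group", call. = FALSE)
  }
  xp <- train[, pathway_group, drop = FALSE]
  xc <- train[, control_group, drop = FALSE]
  n1 <- ncol(xp); n2 <- ncol(xc)
  m1 <- rowMeans(xp); m2 <- rowMeans(xc)
  v1 <- apply(xp, 1, stats::var)
  v2 <- apply(xc, 1, stats::var)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  sp <- pmax(sp, .SD_FLOOR)
  d <- (m1 - m2) / sp
  names(d) <- rownames(train)
  d
}

#' Build a pathway signature of a given length
#'
#' Selects the top ceiling(K/2) genes by descending effect as up-regulated
#' and the top floor(K/2) by ascending effect as down-regulated, so the two
#' directions differ in size by at most one gene. The anchor gene (the
#' overexpressed oncogene itself) is always included: if not selected on
#' merit it replaces the weakest member (smallest |effect|) of the side
#' matching the sign of its own effect. Ties in ranking are broken by
#' lexicographic gene id.
#'
#' @param effects Named numeric vector of per-gene standardized effects, as
#'   returned by [differential_weights()].
#' @param K Total signature size (>= 2).
#' @param anchor Gene id to force into the signature.
#' @param pathway Optional pathway name stored on the object.
#' @param control_baseline Optional two-column matrix/data.frame (mean, sd)
#'   with gene rownames; required later for baseline-relative scoring.
#' @return An object of class `gfrn_signature`: a list with elements
#'   `pathway`, `genes` (data.frame: gene, direction, weight), `anchor`,
#'   `K`, `effects`, `control_baseline`.
#' @export
build_signature <- function(effects, K, anchor, pathway = NULL,
                            control_baseline = NULL) {
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  if (!anchor %in% names(effects)) {
    stop("anchor gene '", anchor, "' absent from effects", call. = FALSE)
  }
  n_up <- ceiling(K / 2)
  n_dn <- floor(K / 2)
  if (max(n_up, n_dn) > length(effects)) {
    stop("K exceeds available genes per side", call. = FALSE)
  }
  g <- names(effects)
  # deterministic ranking: effect first, lexicographic gene id to break ties
  ord_up <- order(-effects, g)
  ord_dn <- order(effects, g)
  up <- g[ord_up[seq_len(n_up)]]
  dn <- g[ord_dn[seq_len(n_dn)]]
  if (!(anchor %in% up || anchor %in% dn)) {
    side <- if (effects[anchor] >= 0) "up" else "down"
    if (side == "up") {
      drop_idx <- which.min(abs(effects[up]))
      up[drop_idx] <- anchor
    } else {
      drop_idx <- which.min(abs(effects[dn]))
      dn[drop_idx] <- anchor
    }
  }
  genes <- data.frame(
    gene = c(up, dn),
    direction = rep(c("up", "down"), c(length(up), length(dn))),
    weight = unname(effects[c(up, dn)]),
    stringsAsFactors = FALSE
  )
  structure(
    list(pathway = pathway, genes = genes, anchor = anchor, K = K,
         effects = effects, control_baseline = control_baseline),
    class = "gfrn_signature"
  )
}

#' @export
print.gfrn_signature <- function(x, ...) {
  cat("GFRN signature", if (!is.null(x$pathway)) paste0("(", x$pathway, ")"),
      "\n")
  cat("  genes:", nrow(x$genes),
      sprintf("(%d up / %d down)", sum(x$genes$direction == "up"),
              sum(x$genes$direction == "down")), "\n")
  cat("  anchor:", x$anchor, "\n")
  invisible(x)
}

# internal: cohort-relative or baseline-relative z-scores for the genes of a
# signature that are present in the test matrix
.signature_z <- function(sig, test, adaptive_background) {
  present <- intersect(sig$genes$gene, rownames(test))
  if (length(present) == 0) {
    stop("no signature genes present in test matrix", call. = FALSE)
  }
  missing <- setdiff(sig$genes$gene, present)
  if (length(missing)) {
    warning(length(missing), " signature gene(s) absent from test matrix; ",
            "dropped", call. = FALSE)
  }
  x <- test[present, , drop = FALSE]
  if (adaptive_background) {
    mu <- rowMeans(x)
    sdv <- pmax(apply(x, 1, stats::sd), .SD_FLOOR)
  } else {
    bl <- sig$control_baseline
    if (is.null(bl)) {
      stop("signature lacks a control baseline; use adaptive_background = TRUE",
           call. = FALSE)
    }
    mu <- bl[present, "mean"]
    sdv <- pmax(bl[present, "sd"], .SD_FLOOR)
  }
  z <- (x - mu) / sdv
  dirs <- sig$genes$direction[match(present, sig$genes$gene)]
  list(z = z, sign = ifelse(dirs == "up", 1, -1), genes = present)
}

#' Estimate one pathway's activity across a test cohort
#'
#' Scores each sample as the mean of signed gene-wise z-scores over the
#' signature genes, then rescales scores to [0, 1] across the cohort by
#' min-max so 0 marks the least-active and 1 the most-active sample. With
#' `adaptive_background = TRUE` (the default) z-scores are computed within
#' the test cohort, absorbing baseline expression differences between
#' training and test; otherwise they are relative to the training control
#' baseline. With `adaptive_signature = TRUE` the per-gene direction signs
#' are re-estimated in the test cohort as the sign of the Spearman
#' correlation between each gene's z-profile and the current score, iterated
#' to a fixed point; a gene may flip at most once, which bounds the
#' iteration.
#'
#' @param sig A `gfrn_signature`.
#' @param test Numeric gene x sample matrix with >= 2 samples.
#' @param adaptive_background Logical; cohort-relative z-scoring.
#' @param adaptive_signature Logical; re-estimate gene directions in test.
#' @return Numeric vector of activities in [0, 1], one per test sample, with
#'   attributes `raw` (unscaled scores) and `flipped` (genes whose direction
#'   was flipped, if any).
#' @export
estimate_activity <- function(sig, test, adaptive_background = TRUE,
                              adaptive_signature = FALSE) {
  if (ncol(test) < 2) {
    stop("activity estimation is cohort-relative; need >= 2 test samples",
         call. = FALSE)
  }
  zs <- .signature_z(sig, test, adaptive_background)
  s <- zs$sign
  r <- colMeans(zs$z * s)
  flipped <- character(0)
  if (adaptive_signature && length(zs$genes) > 1) {
    done <- rep(FALSE, length(s))
    for (iter in seq_len(20)) {
      changed <- FALSE
      for (i in seq_along(s)) {
        if (done[i]) next
        rho <- suppressWarnings(
          stats::cor(zs$z[i, ], r, method = "spearman"))
        if (!is.na(rho) && rho != 0 && sign(rho) != s[i]) {
          s[i] <- sign(rho)
          done[i] <- TRUE  # a gene flips at most once
          flipped <- c(flipped, zs$genes[i])
          changed <- TRUE
        }
      }
      r <- colMeans(zs$z * s)
      if (!changed) break
    }
  }
  rng <- range(r)
  if (diff(rng) <= 0) {
    warning("constant raw score across cohort; activities set to 0.5",
            call. = FALSE)
    a <- rep(0.5, length(r))
  } else {
    a <- (r - rng[1]) / diff(rng)
  }
  names(a) <- colnames(test)
  attr(a, "raw") <- r
  attr(a, "flipped") <- flipped
  a
}

#' Z-scale pathway activities across samples
#'
#' Standardizes each pathway row to mean 0, sample (n-1) standard deviation
#' 1 across the cohort. Phenotype calls operate on this scaled matrix. A
#' zero-variance pathway is set to all zeros with a warning.
#'
#' @param act Pathway x sample numeric matrix of activities.
#' @return Matrix of the same shape, row-standardized.
#' @export
scale_activities <- function(act) {
  act <- as.matrix(act)
  if (ncol(act) < 2) stop("need >= 2 samples to scale", call. = FALSE)
  sc <- t(apply(act, 1, function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) {
      rep(0, length(v))
    } else {
      (v - mean(v)) / s
    }
  }))
  if (any(apply(act, 1, stats::sd) == 0)) {
    warning("zero-variance pathway(s) scaled to zeros", call. = FALSE)
  }
  dimnames(sc) <- dimnames(act)
  sc
}

# internal: AUC of scores (positives vs negatives) by rank statistic;
# equals the fraction of correctly ordered pairs with ties counted half
.auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos); n2 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Leave-one-out cross-validation of a signature
#'
#' For each training sample in turn, rebuilds the signature without it and
#' scores the held-out sample against the baseline of the remaining
#' controls. Separation of held-out overexpression scores from held-out
#' control scores is summarized as the AUC (probability a pathway sample
#' outscores a control sample); the signature passes when AUC meets the
#' threshold.
#'
#' @inheritParams differential_weights
#' @param K Signature size.
#' @param anchor Anchor gene id.
#' @param auc_threshold Pass threshold on the held-out AUC (default 0.9).
#' @return List with elements `pass` (logical), `auc`, and `scores`
#'   (held-out raw score per training sample).
#' @export
loocv_validate <- function(train, pathway_group, control_group, K, anchor,
                           auc_threshold = 0.9) {
  if (length(pathway_group) < 3 || length(control_group) < 3) {
    stop("LOOCV needs >= 3 replicates per group", call. = FALSE)
  }
  all_samples <- c(pathway_group, control_group)
  scores <- vapply(all_samples, function(s) {
    pg <- setdiff(pathway_group, s)
    cg <- setdiff(control_group, s)
    d <- differential_weights(train, pg, cg)
    anc <- if (anchor %in% names(d)) anchor else names(which.max(abs(d)))
    bl <- cbind(mean = rowMeans(train[, cg, drop = FALSE]),
                sd = apply(train[, cg, drop = FALSE], 1, stats::sd))
    sig <- build_signature(d, K, anc, control_baseline = bl)
    zs <- .signature_z(sig, train[, s, drop = FALSE],
                       adaptive_background = FALSE)
    mean(zs$z[, 1] * zs$sign)
  }, numeric(1))
  auc <- .auc(scores[pathway_group], scores[control_group])
  list(pass = auc >= auc_threshold, auc = auc, scores = scores)
}

#' Fit GFRN pathway signatures from a training matrix
#'
#' Fits one signature per overexpression group against the shared control
#' group, using standardized effects and equal up/down gene selection with
#' the overexpressed oncogene anchored. This is the model-fitting entry
#' point; use [predict.gfrn_model()] to estimate pathway activity in a test
#' cohort.
#'
#' @param train Numeric gene x sample matrix (log2(TPM+1)), typically
#'   batch-adjusted first (see [reference_batch_adjust()]).
#' @param groups Character/factor vector of group labels, one per column of
#'   `train` (overexpressed oncogene per sample, controls labelled
#'   `control`).
#' @param control Label of the control group (default "GFP").
#' @param K Signature size: a single number, or a named vector giving a
#'   per-pathway size.
#' @param anchors Named character vector mapping pathway to anchor gene. By
#'   default a gene whose id equals the pathway name is used when present,
#'   otherwise the gene with the largest absolute effect.
#' @return Object of class `gfrn_model`: list of `gfrn_signature`s plus
#'   fit metadata.
#' @seealso [estimate_activity()], [loocv_validate()], [scan_lengths()]
#' @export
#' @examples
#' syn <- simulate_training(synth_config(n_genes = 300,
#'                                       signature_size_per_pathway = 20,
#'                                       seed = 1))
#' fit <- gfrn_signatures(syn$expr, syn$annotation$group, K = 20)
#' fit
gfrn_signatures <- function(train, groups, control = "GFP", K = 100,
                            anchors = NULL) {
  groups <- as.character(groups)
  if (length(groups) != ncol(train)) {
    stop("groups must have one label per training column", call. = FALSE)
  }
  pathways <- setdiff(unique(groups), control)
  if (!control %in% groups) stop("control group '", control, "' not found",
                                 call. = FALSE)
  ctrl_cols <- colnames(train)[groups == control]
  bl <- cbind(mean = rowMeans(train[, ctrl_cols, drop = FALSE]),
              sd = apply(train[, ctrl_cols, drop = FALSE], 1, stats::sd))
  sigs <- lapply(pathways, function(p) {
    cols <- colnames(train)[groups == p]
    d <- differential_weights(train, cols, ctrl_cols)
    anc <- if (!is.null(anchors) && p %in% names(anchors)) {
      anchors[[p]]
    } else if (p %in% names(d)) {
      p
    } else {
      names(which.max(abs(d)))
    }
    k <- if (length(K) > 1) K[[p]] else K
    build_signature(d, k, anc, pathway = p, control_baseline = bl)
  })
  names(sigs) <- pathways
  structure(
    list(signatures = sigs, pathways = pathways, control = control,
         K = K, n_train = ncol(train), call = match.call()),
    class = "gfrn_model"
  )
}

#' @export
print.gfrn_model <- function(x, ...) {
  cat("GFRN signature model:", length(x$signatures), "pathway(s) fit on",
      x$n_train, "training samples\n")
  for (p in x$pathways) {
    s <- x$signatures[[p]]
    cat(sprintf("  %-6s K=%-4d anchor=%s\n", p, nrow(s$genes), s$anchor))
  }
  invisible(x)
}

#' @export
summary.gfrn_model <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$pathways, function(p) {
    s <- object$signatures[[p]]
    data.frame(pathway = p, K = nrow(s$genes), anchor = s$anchor,
               n_up = sum(s$genes$direction == "up"),
               n_down = sum(s$genes$direction == "down"),
               max_effect = max(abs(s$genes$weight)),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(table = tab), class = "summary.gfrn_model")
}

#' @export
print.summary.gfrn_model <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' @export
coef.gfrn_model <- function(object, ...) {
  lapply(object$signatures, function(s) {
    stats::setNames(s$genes$weight, s$genes$gene)
  })
}

#' Estimate pathway activity in a test cohort
#'
#' Applies every fitted signature to a test expression matrix and returns a
#' pathway x sample activity matrix in [0, 1] (class `gfrn_activity`), with
#' the unscaled raw scores kept as an attribute.
#'
#' @param object A `gfrn_model`.
#' @param newdata Numeric gene x sample matrix (>= 2 samples).
#' @param adaptive_background,adaptive_signature Passed to
#'   [estimate_activity()].
#' @param ... Unused.
#' @return `gfrn_activity` matrix (pathways x samples).
#' @export
predict.gfrn_model <- function(object, newdata, adaptive_background = TRUE,
                               adaptive_signature = FALSE, ...) {
  rows <- lapply(object$pathways, function(p) {
    estimate_activity(object$signatures[[p]], newdata,
                      adaptive_background = adaptive_background,
                      adaptive_signature = adaptive_signature)
  })
  act <- do.call(rbind, lapply(rows, as.vector))
  raw <- do.call(rbind, lapply(rows, attr, "raw"))
  dimnames(act) <- dimnames(raw) <- list(object$pathways, colnames(newdata))
  structure(act, raw = raw, class = c("gfrn_activity", "matrix", "array"))
}

#' @export
print.gfrn_activity <- function(x, ...) {
  cat("GFRN pathway activity:", nrow(x), "pathway(s) x", ncol(x),
      "sample(s), range [0, 1]\n")
  print(utils::head(t(unclass(x)), 6L))
  if (ncol(x) > 6) cat("  ... (", ncol(x) - 6, " more samples)\n", sep = "")
  invisible(x)
}
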