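# Reference-batch harmonization. Non-reference batches are
# location/scale-transformed per gene so their residual moments match the
# designated reference batch, with biological group structure protected by a
# covariate design; the reference batch itself is returned untouched. An
# empirical-Bayes mode (sva::ComBat with a reference batch) is available for
# users who prefer shrunken batch parameters.

#' Adjust batches toward a designated reference batch
#'
#' Per gene, every non-reference batch is location/scale transformed onto
#' the reference batch: a shared batch location offset (the mean
#' difference of group means between the batch and the reference, over
#' groups present in both) is subtracted, and residuals about the
#' within-batch group means are rescaled so the within-batch residual
#' standard deviation matches the reference batch. Group (covariate)
#' structure is thereby protected: each group keeps its own mean, shifted
#' only by the batch offset. Reference-batch values are returned
#' bit-identical to the input, and the operation is exactly idempotent.
#' Genes with zero residual variance in some batch get the location
#' adjustment only (with a warning).
#'
#' @param expr Numeric gene x sample matrix.
#' @param batch Vector of batch ids, one per column of `expr`.
#' @param reference_batch Batch id to adjust toward.
#' @param covariates Optional vector of group labels (one per sample) whose
#'   effects are protected during adjustment.
#' @param method `"exact"` (moment matching, default) or `"eb"`
#'   (empirical-Bayes shrinkage via \pkg{sva}'s ComBat, if installed).
#' @return Adjusted matrix with the same dimnames as `expr`.
#' @export
#' @examples
#' m <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' b <- rep(c("A", "B"), each = 5)
#' adj <- reference_batch_adjust(m, b, "A")
#' stopifnot(identical(adj[, 1:5], m[, 1:5]))
reference_batch_adjust <- function(expr, batch, reference_batch,
                                   covariates = NULL,
                                   method = c("exact", "eb")) {
  method <- match.arg(method)
  expr <- as.matrix(expr)
  batch <- as.character(batch)
  if (length(batch) != ncol(expr)) {
    stop("batch must have one id per sample", call. = FALSE)
  }
  if (!reference_batch %in% batch) {
    stop("reference batch '", reference_batch, "' has no samples",
         call. = FALSE)
  }
  tab <- table(batch)
  if (any(tab < 2)) {
    stop("every batch needs >= 2 samples; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  if (length(unique(batch)) == 1) return(expr)
  if (method == "eb") {
    if (!requireNamespace("sva", quietly = TRUE)) {
      stop("method = 'eb' requires the sva package", call. = FALSE)
    }
    mod <- if (is.null(covariates)) NULL else
      stats::model.matrix(~ factor(covariates))
    out <- sva::ComBat(expr, batch = batch, mod = mod,
                       ref.batch = reference_batch)
    return(out)
  }
  ref <- as.character(reference_batch)
  grp <- if (is.null(covariates)) rep("all", ncol(expr))
         else as.character(covariates)
  batches <- unique(batch)
  # per-gene mean of every (batch, group) cell; residuals are taken about
  # the own cell mean, so covariate structure is removed before moment
  # matching and restored on the reference batch's scale afterwards
  cell_mean <- function(b, g) {
    cols <- which(batch == b & grp == g)
    if (!length(cols)) return(NULL)
    rowMeans(expr[, cols, drop = FALSE])
  }
  resid <- expr
  for (b in batches) for (g in unique(grp[batch == b])) {
    cols <- which(batch == b & grp == g)
    resid[, cols] <- expr[, cols, drop = FALSE] - cell_mean(b, g)
  }
  sd_batch <- function(b) {
    apply(resid[, batch == b, drop = FALSE], 1, stats::sd)
  }
  sd_ref <- sd_batch(ref)
  out <- expr
  skipped_scale <- FALSE
  for (b in setdiff(batches, ref)) {
    ratio <- sd_ref / sd_batch(b)
    bad <- !is.finite(ratio) | ratio == 0
    if (any(bad)) {
      skipped_scale <- TRUE
      ratio[bad] <- 1
    }
    groups_b <- unique(grp[batch == b])
    shared <- intersect(groups_b, unique(grp[batch == ref]))
    if (!length(shared)) {
      stop("batch '", b, "' shares no covariate group with the reference ",
           "batch", call. = FALSE)
    }
    # per-gene batch location offset, shared across groups (estimated from
    # the groups seen in both batches); subtracting it preserves each
    # group's own replicate information across batches
    offset <- rowMeans(as.matrix(
      sapply(shared, function(g) cell_mean(b, g) - cell_mean(ref, g))))
    for (g in groups_b) {
      cols <- which(batch == b & grp == g)
      out[, cols] <- (cell_mean(b, g) - offset) +
        resid[, cols, drop = FALSE] * ratio
    }
  }
  if (skipped_scale) {
    warning("zero residual variance for some gene/batch; ",
            "location-only adjustment used there", call. = FALSE)
  }
  out
}

#' Two-round harmonization of training and test data
#'
#' Round 1 adjusts the training batches toward the designated reference
#' training batch (protecting the overexpression group structure when
#' `covariates` is given). Round 2 treats the whole adjusted training set as
#' the reference batch and the test cohort as a second batch, pulling the
#' test cohort onto the training scale. Only genes present in both matrices
#' are retained (inner join on gene ids, order preserved from the training
#' matrix); training values are unchanged by round 2.
#'
#' @param train,test Gene x sample matrices.
#' @param batch Training batch ids (one per training column).
#' @param reference_batch Reference training batch id for round 1.
#' @param covariates Optional training group labels for round 1.
#' @return List with adjusted `train` and `test` matrices on the shared gene
#'   set.
#' @export
harmonize_train_test <- function(train, test, batch, reference_batch,
                                 covariates = NULL) {
  shared <- intersect(rownames(train), rownames(test))
  if (length(shared) == 0) {
    stop("train and test share no gene ids", call. = FALSE)
  }
  train <- train[shared, , drop = FALSE]
  test <- test[shared, , drop = FALSE]
  train_adj <- reference_batch_adjust(train, batch, reference_batch,
                                      covariates = covariates)
  combined <- cbind(train_adj, test)
  b2 <- rep(c("train", "test"), c(ncol(train_adj), ncol(test)))
  adj <- reference_batch_adjust(combined, b2, "train")
  list(train = adj[, seq_len(ncol(train_adj)), drop = FALSE],
       test = adj[, ncol(train_adj) + seq_len(ncol(test)), drop = FALSE])
}

#' PCA-based batch-effect diagnostic
#'
#' Computes sample principal components of the centered expression matrix
#' and, per component, the one-way ANOVA F statistic of PC value against
#' batch. Large F on leading PCs before adjustment, dropping toward 1
#' afterwards, indicates a batch effect that the adjustment removed.
#'
#' @param expr Gene x sample matrix (>= 3 samples).
#' @param batch Batch ids, one per sample.
#' @param n_pcs Number of components to report (default 5, capped by the
#'   data rank).
#' @return List with `scores` (sample x PC), `variance_fraction`,
#'   `f_statistic` and `p_value` per PC.
#' @export
batch_pca_diagnostic <- function(expr, batch, n_pcs = 5) {
  if (ncol(expr) < 3) stop("need >= 3 samples", call. = FALSE)
  n_pcs <- min(n_pcs, ncol(expr) - 1)
  pc <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  vf <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  bfac <- factor(batch)
  stats_pc <- apply(scores, 2, function(v) {
    if (nlevels(bfac) < 2) return(c(NA_real_, NA_real_))
    a <- stats::anova(stats::lm(v ~ bfac))
    c(a[["F value"]][1], a[["Pr(>F)"]][1])
  })
  list(scores = scores, variance_fraction = vf,
       f_statistic = stats_pc[1, ], p_value = stats_pc[2, ])
}
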