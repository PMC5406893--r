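# Phenotype and subgroup calling. A sample's phenotype is decided by which
# arm of the network has the larger mean z-scaled activity: survival
# (HER2/IGF1R/AKT) or growth (BAD/EGFR/KRAS/RAF1). Four k-means clusters on
# the AKT/HER2/BAD/EGFR activities then split each phenotype by HER2 (resp.
# BAD) activity.

#' Call survival/growth phenotypes from scaled activities
#'
#' For each sample computes the mean z-scaled activity of the survival arm
#' (HER2, IGF1R, AKT) and of the growth arm (BAD, EGFR, KRAS, RAF1); the
#' phenotype is the arm with the larger mean. Exact ties resolve to
#' survival, deterministically.
#'
#' @param scaled Pathway x sample matrix of z-scaled activities containing
#'   all seven pathways (see [scale_activities()]).
#' @return data.frame of class `gfrn_phenotypes` with columns sample,
#'   survival_mean, growth_mean, phenotype.
#' @export
#' @examples
#' sc <- matrix(c(1, 1, 1, -1, -1, -1, -1), 7, 2,
#'              dimnames = list(c("HER2", "IGF1R", "AKT", "BAD", "EGFR",
#'                                "KRAS", "RAF1"), c("a", "b")))
#' call_phenotype(sc)
call_phenotype <- function(scaled) {
  arms <- gfrn_arms()
  .check_pathways(rownames(scaled), unlist(arms))
  sm <- colMeans(scaled[arms$survival, , drop = FALSE])
  gm <- colMeans(scaled[arms$growth, , drop = FALSE])
  out <- data.frame(
    sample = colnames(scaled),
    survival_mean = unname(sm),
    growth_mean = unname(gm),
    phenotype = ifelse(sm >= gm, "survival", "growth"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("gfrn_phenotypes", class(out))
  out
}

#' @export
print.gfrn_phenotypes <- function(x, ...) {
  cat("GFRN phenotype calls for", nrow(x), "samples:\n")
  print(table(x$phenotype))
  if (!is.null(x$subgroup)) print(table(x$subgroup))
  invisible(x)
}

#' K-means subgrouping on four discriminating pathways
#'
#' Clusters samples on their z-scaled AKT, HER2, BAD and EGFR activities
#' with k-means (squared Euclidean distance), four centers and 100 random
#' starts, keeping the start with the lowest total within-cluster sum of
#' squares. Deterministic given `seed`.
#'
#' @param scaled Pathway x sample z-scaled activity matrix.
#' @param pathways Pathways used for clustering.
#' @param k Number of clusters (default 4).
#' @param n_starts Random starts (default 100).
#' @param seed Optional integer seed set before clustering.
#' @return The `stats::kmeans` fit, with `cluster` named by sample.
#' @export
kmeans_subgroups <- function(scaled,
                             pathways = c("AKT", "HER2", "BAD", "EGFR"),
                             k = 4, n_starts = 100, seed = NULL) {
  .check_pathways(rownames(scaled), pathways)
  x <- t(scaled[pathways, , drop = FALSE])
  if (nrow(x) < k) stop("fewer samples than clusters", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = n_starts, iter.max = 100)
  names(km$cluster) <- colnames(scaled)
  km
}

# archetype directions per subgroup on the (AKT, HER2, BAD, EGFR) axes,
# used only when the clusters do not split 2/2 across phenotypes
.subgroup_archetypes <- function(pathways) {
  a <- rbind(
    survival_HER2_high = c(AKT = 1, HER2 = 1, BAD = -1, EGFR = -1),
    survival_HER2_low  = c(AKT = 1, HER2 = -1, BAD = -1, EGFR = -1),
    growth_BAD_high    = c(AKT = -1, HER2 = -1, BAD = 1, EGFR = 1),
    growth_BAD_low     = c(AKT = -1, HER2 = -1, BAD = -1, EGFR = 1)
  )
  a <- a[, pathways, drop = FALSE]
  a / sqrt(rowSums(a^2))
}

#' Label the four k-means clusters as phenotype subgroups
#'
#' Each cluster takes the majority phenotype of its members; the expected
#' outcome is two survival and two growth clusters. Within the survival
#' pair, the cluster with the higher mean scaled HER2 activity becomes
#' `survival_HER2_high`; within the growth pair, higher mean BAD activity
#' becomes `growth_BAD_high`. If the clusters do not split two and two, a
#' structured warning is raised and each cluster is instead labelled by the
#' nearest subgroup archetype (signed unit direction vectors on the
#' clustering pathways).
#'
#' @param clusters Named cluster assignment (sample -> 1..4), e.g.
#'   `kmeans_subgroups(...)$cluster`.
#' @param calls `gfrn_phenotypes` data.frame from [call_phenotype()].
#' @param scaled The scaled activity matrix used for clustering.
#' @param pathways Pathways the archetypes are defined on.
#' @return `calls` with `cluster` and `subgroup` columns filled.
#' @export
label_subgroups <- function(clusters, calls, scaled,
                            pathways = c("AKT", "HER2", "BAD", "EGFR")) {
  ids <- sort(unique(clusters))
  if (length(ids) < 4) stop("need exactly 4 clusters", call. = FALSE)
  pheno <- stats::setNames(calls$phenotype, calls$sample)
  maj <- vapply(ids, function(k) {
    tb <- table(pheno[names(clusters)[clusters == k]])
    names(tb)[which.max(tb)]
  }, character(1))
  centroid <- function(k, p) {
    mean(scaled[p, names(clusters)[clusters == k]])
  }
  lab <- character(length(ids))
  if (sum(maj == "survival") == 2 && sum(maj == "growth") == 2) {
    sv <- ids[maj == "survival"]
    gr <- ids[maj == "growth"]
    her2 <- vapply(sv, centroid, numeric(1), p = "HER2")
    bad <- vapply(gr, centroid, numeric(1), p = "BAD")
    lab[match(sv[order(-her2)], ids)] <- c("survival_HER2_high",
                                           "survival_HER2_low")
    lab[match(gr[order(-bad)], ids)] <- c("growth_BAD_high",
                                          "growth_BAD_low")
  } else {
    warning("clusters do not split 2/2 across phenotypes (",
            paste(maj, collapse = "/"),
            "); falling back to nearest-archetype labels", call. = FALSE)
    arch <- .subgroup_archetypes(pathways)
    for (i in seq_along(ids)) {
      cen <- vapply(pathways, function(p) centroid(ids[i], p), numeric(1))
      d2 <- apply(arch, 1, function(a) sum((cen / max(sqrt(sum(cen^2)),
                                                      1e-12) - a)^2))
      lab[i] <- rownames(arch)[which.min(d2)]
    }
  }
  calls$cluster <- unname(clusters[calls$sample])
  calls$subgroup <- lab[match(calls$cluster, ids)]
  calls
}
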