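# Synthetic study data: overexpression training replicates with batch
# structure, tumor cohorts with a planted two-arm phenotype dichotomy and
# four subgroups, matched protein (RPPA-like) measurements, and dose-response
# viability panels. Each generator is deterministic given the config seed, so
# the whole pipeline is testable without external data.

#' Configuration for the synthetic study generators
#'
#' Defaults mirror the emulated study design: seven pathways (AKT, BAD,
#' EGFR, HER2, IGF1R, KRAS, RAF1), six overexpression replicates per pathway
#' against twelve shared controls spread over three sequencing batches, and
#' a 200-sample test cohort split evenly between the survival and growth
#' phenotypes. Expression is on the log2(TPM+1) scale with additive Gaussian
#' noise.
#'
#' @param n_train_replicates_per_group Overexpression replicates per pathway.
#' @param n_control_replicates Control (GFP) replicates.
#' @param n_genes Total genes in the expression matrix.
#' @param signature_size_per_pathway Planted signature genes per pathway
#'   (half up-, half down-regulated; disjoint across pathways).
#' @param effect_size Planted shift of signature genes, log2 units.
#' @param noise_sd Replicate noise SD in the training matrix, log2 units.
#' @param n_batches Number of training sequencing batches (batch 1 is the
#'   reference).
#' @param batch_shift_sd SD of the per-gene additive batch shift, log2 units.
#' @param batch_scale_range Range of the multiplicative batch noise scale.
#' @param n_test_samples Test-cohort size.
#' @param phenotype_fraction_survival Intended fraction of survival-arm
#'   samples in the cohort.
#' @param subgroup_split Intended fraction of the high-activity subgroup
#'   within each phenotype (HER2-high within survival, BAD-high within
#'   growth).
#' @param activity_noise_sd Residual expression noise SD in the cohort,
#'   log2 units.
#' @param beta_high,beta_low Beta shape parameters for high- and low-arm
#'   planted activities.
#' @param rppa_noise_sd Noise SD of synthetic protein measurements.
#' @param n_proteins_per_pathway Validation proteins measured per pathway
#'   (default 3, emulating receptor/kinase plus downstream and
#'   phospho-forms; BAD is always validated through the AKT protein alone).
#' @param viability_noise_sd Replicate noise SD of dose-response points.
#' @param ec50_range Range (min, max) of planted logEC50, log10 molar.
#' @param seed Integer seed; derived generators use fixed offsets of it.
#' @return A validated list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_genes = 500, signature_size_per_pathway = 30,
#'                     seed = 42)
synth_config <- function(n_train_replicates_per_group = 6,
                         n_control_replicates = 12,
                         n_genes = 5000,
                         signature_size_per_pathway = 100,
                         effect_size = 2,
                         noise_sd = 1,
                         n_batches = 3,
                         batch_shift_sd = 0.5,
                         batch_scale_range = c(0.8, 1.25),
                         n_test_samples = 200,
                         phenotype_fraction_survival = 0.5,
                         subgroup_split = 0.5,
                         activity_noise_sd = 1,
                         beta_high = c(8, 2),
                         beta_low = c(2, 8),
                         rppa_noise_sd = 0.3,
                         n_proteins_per_pathway = 3,
                         viability_noise_sd = 0.05,
                         ec50_range = c(-8, -5),
                         seed = 1) {
  cfg <- list(
    pathways = gfrn_pathways(),
    n_train_replicates_per_group = n_train_replicates_per_group,
    n_control_replicates = n_control_replicates,
    n_genes = n_genes,
    signature_size_per_pathway = signature_size_per_pathway,
    effect_size = effect_size,
    noise_sd = noise_sd,
    n_batches = n_batches,
    batch_shift_sd = batch_shift_sd,
    batch_scale_range = batch_scale_range,
    n_test_samples = n_test_samples,
    phenotype_fraction_survival = phenotype_fraction_survival,
    subgroup_split = subgroup_split,
    activity_noise_sd = activity_noise_sd,
    beta_high = beta_high,
    beta_low = beta_low,
    rppa_noise_sd = rppa_noise_sd,
    n_proteins_per_pathway = n_proteins_per_pathway,
    viability_noise_sd = viability_noise_sd,
    ec50_range = ec50_range,
    seed = as.integer(seed)
  )
  .validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

.validate_synth_config <- function(cfg) {
  fail <- function(msg) stop("invalid synth_config: ", msg, call. = FALSE)
  if (cfg$signature_size_per_pathway * length(cfg$pathways) > cfg$n_genes) {
    fail("signature_size_per_pathway x n_pathways exceeds n_genes")
  }
  counts <- c(cfg$n_train_replicates_per_group, cfg$n_control_replicates,
              cfg$n_genes, cfg$signature_size_per_pathway, cfg$n_batches,
              cfg$n_test_samples)
  if (any(counts < 2)) fail("all counts must be >= 2")
  props <- c(cfg$phenotype_fraction_survival, cfg$subgroup_split)
  if (any(props < 0 | props > 1)) {
    fail("proportions must lie in [0, 1]")
  }
  if (cfg$ec50_range[1] >= cfg$ec50_range[2]) {
    fail("ec50_range must be (min, max) with min < max")
  }
  invisible(TRUE)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic GFRN study config:\n")
  cat("  training:", x$n_train_replicates_per_group, "reps x",
      length(x$pathways), "pathways +", x$n_control_replicates,
      "controls in", x$n_batches, "batches\n")
  cat("  genes:", x$n_genes, "(", x$signature_size_per_pathway,
      "planted per pathway, effect", x$effect_size, ")\n")
  cat("  cohort:", x$n_test_samples, "samples, survival fraction",
      x$phenotype_fraction_survival, "\n")
  invisible(x)
}

# internal: gene universe with pathway-named anchors; planted gene sets are
# disjoint blocks, first gene of each block renamed to the pathway id so the
# anchor gene is the overexpressed oncogene itself
.synth_genes <- function(cfg) {
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  planted <- list()
  s <- cfg$signature_size_per_pathway
  for (i in seq_along(cfg$pathways)) {
    p <- cfg$pathways[i]
    idx <- ((i - 1) * s + 1):(i * s)
    genes[idx[1]] <- p
    n_up <- ceiling(s / 2)
    planted[[p]] <- data.frame(
      gene = genes[idx],
      sign = rep(c(1, -1), c(n_up, s - n_up)),
      stringsAsFactors = FALSE
    )
  }
  list(genes = genes, planted = planted)
}

#' Simulate an overexpression training set
#'
#' One overexpression group per pathway versus shared controls, with each
#' pathway's planted signature genes shifted by +/- `effect_size` relative
#' to the control baseline. Samples are spread cyclically over the training
#' batches; non-reference batches receive an additive per-gene shift and a
#' multiplicative noise-scale distortion, leaving batch 1 as the clean
#' reference.
#'
#' @param cfg A [synth_config()].
#' @return List with `expr` (gene x sample matrix), `annotation`
#'   (data.frame: sample, group, batch) and `truth` (planted signature gene
#'   tables with signs, anchor genes, batch assignment).
#' @export
simulate_training <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  gu <- .synth_genes(cfg)
  groups <- c(rep(cfg$pathways, each = cfg$n_train_replicates_per_group),
              rep("GFP", cfg$n_control_replicates))
  samples <- paste0(groups, "_", stats::ave(seq_along(groups), groups,
                                            FUN = seq_along))
  batch <- ((seq_along(samples) - 1) %% cfg$n_batches) + 1
  baseline <- stats::rnorm(cfg$n_genes, mean = 6, sd = 1)
  shift <- matrix(stats::rnorm(cfg$n_genes * cfg$n_batches, 0,
                               cfg$batch_shift_sd),
                  nrow = cfg$n_genes)
  shift[, 1] <- 0
  scale_b <- stats::runif(cfg$n_batches, cfg$batch_scale_range[1],
                          cfg$batch_scale_range[2])
  scale_b[1] <- 1
  expr <- matrix(0, cfg$n_genes, length(samples),
                 dimnames = list(gu$genes, samples))
  for (j in seq_along(samples)) {
    mu <- baseline
    if (groups[j] != "GFP") {
      pl <- gu$planted[[groups[j]]]
      idx <- match(pl$gene, gu$genes)
      mu[idx] <- mu[idx] + pl$sign * cfg$effect_size
    }
    noise <- stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)
    expr[, j] <- mu + scale_b[batch[j]] * noise + shift[, batch[j]]
  }
  annotation <- data.frame(sample = samples, group = groups, batch = batch,
                           stringsAsFactors = FALSE)
  truth <- list(
    planted_signatures = gu$planted,
    anchors = stats::setNames(cfg$pathways, cfg$pathways),
    batch_assignment = stats::setNames(batch, samples),
    baseline = stats::setNames(baseline, gu$genes)
  )
  list(expr = expr, annotation = annotation, truth = truth)
}

#' Simulate a test cohort with planted phenotype structure
#'
#' Each sample receives planted per-pathway activities in [0, 1]: one
#' phenotype arm (HER2/IGF1R/AKT or BAD/EGFR/KRAS/RAF1) drawn high
#' (Beta(8, 2) by default) and the other low (Beta(2, 8)), with subgroup
#' structure from HER2 activity within the survival arm and BAD activity
#' within the growth arm. Planted signature-gene expression is
#' `baseline + sign * activity * effect_size + noise`, plus a cohort-wide
#' per-gene batch offset distinct from the training batches. The planted
#' phenotype label is derived from the planted activities by the max-mean
#' arm rule, so label and activity are consistent by construction.
#'
#' @param cfg A [synth_config()].
#' @param truth Training truth as returned by [simulate_training()]
#'   (planted signature genes are reused).
#' @return List with `expr`, `annotation`, and `truth` containing
#'   `planted_activity` (pathway x sample), `planted_phenotype`,
#'   `planted_subgroup`.
#' @export
simulate_cohort <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(truth$planted_signatures)) {
    stop("training truth with planted signature genes is required",
         call. = FALSE)
  }
  set.seed(cfg$seed + 1L)
  n <- cfg$n_test_samples
  samples <- sprintf("s%04d", seq_len(n))
  arms <- gfrn_arms()
  n_surv <- round(cfg$phenotype_fraction_survival * n)
  intent <- sample(rep(c("survival", "growth"), c(n_surv, n - n_surv)))
  sub_high <- stats::runif(n) < cfg$subgroup_split
  rbeta2 <- function(k, shape) stats::rbeta(k, shape[1], shape[2])
  act <- matrix(NA_real_, length(cfg$pathways), n,
                dimnames = list(cfg$pathways, samples))
  for (j in seq_len(n)) {
    hi <- if (intent[j] == "survival") arms$survival else arms$growth
    lo <- setdiff(cfg$pathways, hi)
    # subgroup pathway (HER2 within survival, BAD within growth) follows the
    # subgroup draw rather than the arm
    subp <- if (intent[j] == "survival") "HER2" else "BAD"
    for (p in cfg$pathways) {
      high <- if (p == subp) sub_high[j] else p %in% hi
      act[p, j] <- rbeta2(1, if (high) cfg$beta_high else cfg$beta_low)
    }
  }
  surv_mean <- colMeans(act[arms$survival, , drop = FALSE])
  grow_mean <- colMeans(act[arms$growth, , drop = FALSE])
  phenotype <- ifelse(surv_mean >= grow_mean, "survival", "growth")
  subp_act <- ifelse(phenotype == "survival", act["HER2", ], act["BAD", ])
  subgroup <- ifelse(
    phenotype == "survival",
    ifelse(subp_act >= 0.5, "survival_HER2_high", "survival_HER2_low"),
    ifelse(subp_act >= 0.5, "growth_BAD_high", "growth_BAD_low"))
  genes <- names(truth$baseline)
  baseline <- truth$baseline
  cohort_shift <- stats::rnorm(length(genes), 0, cfg$batch_shift_sd)
  expr <- matrix(stats::rnorm(length(genes) * n, 0, cfg$activity_noise_sd),
                 length(genes), n, dimnames = list(genes, samples))
  expr <- expr + baseline + cohort_shift
  for (p in cfg$pathways) {
    pl <- truth$planted_signatures[[p]]
    idx <- match(pl$gene, genes)
    expr[idx, ] <- expr[idx, ] +
      outer(pl$sign, act[p, ]) * cfg$effect_size
  }
  annotation <- data.frame(sample = samples, group = "tumor",
                           batch = "cohort", stringsAsFactors = FALSE)
  truth_out <- list(
    planted_signatures = truth$planted_signatures,
    anchors = truth$anchors,
    planted_activity = act,
    planted_phenotype = stats::setNames(phenotype, samples),
    planted_subgroup = stats::setNames(subgroup, samples)
  )
  list(expr = expr, annotation = annotation, truth = truth_out)
}

# protein ids for one pathway: p_AKT, p_AKT_2, ...
.protein_ids <- function(pathway, n) {
  paste0("p_", pathway, c("", paste0("_", seq_len(max(n - 1, 0)) + 1))[
    seq_len(n)])
}

#' Default pathway-to-protein validation map for synthetic data
#'
#' Each pathway maps to `n_proteins` synthetic proteins with positive
#' expected sign (emulating a receptor/kinase plus downstream and
#' phosphorylated forms), except BAD, which -- as in the validation design
#' this emulates -- is checked against the AKT protein alone with negative
#' expected sign: AKT activation inhibits BAD, so BAD pathway activity
#' should anti-correlate with AKT protein.
#'
#' @param n_proteins Positive proteins mapped per pathway (default 3).
#' @return data.frame with columns pathway, protein, sign.
#' @export
default_protein_map <- function(n_proteins = 3) {
  rows <- lapply(gfrn_pathways(), function(p) {
    if (p == "BAD") {
      data.frame(pathway = "BAD", protein = "p_AKT", sign = -1,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(pathway = p, protein = .protein_ids(p, n_proteins),
                 sign = 1, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Simulate protein (RPPA-like) and dose-response data for a cohort
#'
#' Proteins: one per pathway, equal to the planted activity plus Gaussian
#' noise (BAD is validated via the AKT protein, see
#' [default_protein_map()]). Drugs: a panel whose planted logEC50 is driven
#' by the survival-arm mean, the growth-arm mean, HER2 alone, BAD alone, or
#' nothing (null drugs); higher driver activity means lower logEC50 (more
#' sensitive). Viability points follow
#' `Y = 1 / (1 + 10^((logEC50 - X) * HillSlope))` at six log10 doses with
#' four replicates and additive noise.
#'
#' @param cfg A [synth_config()].
#' @param truth Cohort truth from [simulate_cohort()] (needs
#'   `planted_activity`).
#' @return List with `protein` (protein x sample matrix), `protein_map`,
#'   `dose_response` (long data.frame: cell_line, drug, dose_log10M,
#'   viability, replicate), and `truth` (planted logEC50/HillSlope table
#'   with each drug's driver).
#' @export
simulate_protein_drug <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(truth$planted_activity)) {
    stop("cohort truth with planted_activity is required", call. = FALSE)
  }
  set.seed(cfg$seed + 2L)
  act <- truth$planted_activity
  samples <- colnames(act)
  p <- gfrn_pathways()
  npp <- cfg$n_proteins_per_pathway
  protein <- do.call(rbind, lapply(p, function(pw) {
    matrix(rep(act[pw, ], each = npp), npp) +
      matrix(stats::rnorm(npp * length(samples), 0, cfg$rppa_noise_sd),
             npp)
  }))
  dimnames(protein) <- list(
    unlist(lapply(p, .protein_ids, n = npp)), samples)
  arms <- gfrn_arms()
  drivers <- c(drug_surv1 = "survival_arm", drug_surv2 = "survival_arm",
               drug_surv3 = "survival_arm",
               drug_grow1 = "growth_arm", drug_grow2 = "growth_arm",
               drug_grow3 = "growth_arm",
               drug_her2 = "HER2", drug_bad = "BAD",
               drug_null1 = "none", drug_null2 = "none")
  driver_value <- function(dr) {
    switch(dr,
           survival_arm = colMeans(act[arms$survival, , drop = FALSE]),
           growth_arm = colMeans(act[arms$growth, , drop = FALSE]),
           none = stats::runif(ncol(act)),
           act[dr, ])
  }
  lo <- cfg$ec50_range[1]; hi <- cfg$ec50_range[2]
  doses <- seq(lo - 1, hi + 1, length.out = 6)
  rows <- vector("list", length(drivers))
  planted <- vector("list", length(drivers))
  for (k in seq_along(drivers)) {
    drug <- names(drivers)[k]
    v <- driver_value(drivers[[k]])
    logec50 <- hi - (hi - lo) * v
    hill <- stats::runif(length(samples), 0.8, 1.5)
    planted[[k]] <- data.frame(cell_line = samples, drug = drug,
                               logec50 = logec50, hillslope = hill,
                               driver = drivers[[k]],
                               stringsAsFactors = FALSE)
    grid <- expand.grid(replicate = 1:4, dose_log10M = doses,
                        cell_line = samples, stringsAsFactors = FALSE)
    mu <- 1 / (1 + 10^((logec50[match(grid$cell_line, samples)] -
                          grid$dose_log10M) *
                         hill[match(grid$cell_line, samples)]))
    grid$viability <- mu + stats::rnorm(nrow(grid), 0,
                                        cfg$viability_noise_sd)
    grid$drug <- drug
    rows[[k]] <- grid[, c("cell_line", "drug", "dose_log10M", "viability",
                          "replicate")]
  }
  list(
    protein = protein,
    protein_map = default_protein_map(npp),
    dose_response = do.call(rbind, rows),
    truth = do.call(rbind, planted)
  )
}
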