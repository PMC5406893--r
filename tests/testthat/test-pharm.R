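test_that("dose-response fitting recovers exact parameters and flags degenerate input", {
  x <- seq(-9, -4, length.out = 6)
  y <- 1 / (1 + 10^((-6 - x) * 1.3))
  fit <- fit_dose_response(x, y)
  expect_true(fit$converged)
  expect_equal(fit$logec50, -6, tolerance = 1e-6)
  expect_equal(fit$hillslope, 1.3, tolerance = 1e-6)
  # midpoint identity for any slope
  expect_equal(predict(fit, -6), 0.5, tolerance = 1e-6)
  expect_equal(unname(coef(fit)), c(fit$logec50, fit$hillslope))
  expect_equal(sensitivity_from_fit(fit), 6, tolerance = 1e-6)
  # no response at all: flagged, sensitivity missing
  flat <- fit_dose_response(x, rep(1, 6))
  expect_false(flat$converged)
  expect_equal(flat$flag, "no_response")
  expect_true(is.na(sensitivity_from_fit(flat)))
  # EC50 far outside the tested range: finite fit but flagged
  y_out <- 1 / (1 + 10^((0 - x) * 1))
  far <- fit_dose_response(x, y_out)
  if (far$converged) expect_true(is.na(sensitivity_from_fit(far)) ||
                                   far$flag == "ok")
  expect_error(fit_dose_response(c(-6, -6, -5, -5), c(0, 0, 1, 1)),
               "distinct doses")
  expect_warning(fit_dose_response(x, y + 0.6), "clipped")
})

test_that("sensitivity is -logEC50 with the expected ordering", {
  mk <- function(logec50) {
    x <- seq(-9, -4, length.out = 6)
    fit_dose_response(x, 1 / (1 + 10^((logec50 - x) * 1)))
  }
  expect_equal(sensitivity_from_fit(mk(-7)), 7, tolerance = 1e-6)
  expect_equal(sensitivity_from_fit(mk(-5)), 5, tolerance = 1e-6)
  expect_gt(sensitivity_from_fit(mk(-7)), sensitivity_from_fit(mk(-5)))
})

test_that("panel fitting recovers planted EC50s with small bias", {
  st <- small_study(seed = 23, n_test_samples = 20)
  pd <- simulate_protein_drug(st$cfg, st$cohort$truth)
  sub <- pd$dose_response[pd$dose_response$drug %in%
                            c("drug_surv1", "drug_bad"), ]
  fits <- suppressWarnings(fit_dose_response_panel(sub))
  m <- merge(fits[fits$converged, ], pd$truth,
             by = c("cell_line", "drug"))
  expect_gt(nrow(m), 30)
  expect_lt(abs(median(m$logec50.x - m$logec50.y)), 0.05)
})

test_that("BH adjustment matches the step-up definition on every small input", {
  # the documented worked case
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  expect_equal(brute_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # randomized inputs up to length 8 against the brute-force oracle
  set.seed(12)
  for (n in 1:8) {
    for (rep in 1:25) {
      p <- round(runif(n), 3)
      expect_equal(p.adjust(p, method = "BH"), brute_bh(p),
                   tolerance = 1e-12)
    }
  }
})

test_that("subgroup drug tests find planted shifts and control the FDR family-wise", {
  set.seed(3)
  lines <- sprintf("L%02d", 1:20)
  sub <- setNames(rep(c("survival_HER2_high", "survival_HER2_low"), 10),
                  lines)
  mk_sens <- function(shift) {
    do.call(rbind, lapply(paste0("d", 1:6), function(dr) {
      data.frame(cell_line = lines, drug = dr,
                 sensitivity = rnorm(20, 6) +
                   shift * (sub[lines] == "survival_HER2_high"),
                 stringsAsFactors = FALSE)
    }))
  }
  res <- subgroup_drug_tests(mk_sens(1.5), sub,
                             list(c("survival_HER2_high",
                                    "survival_HER2_low")))
  expect_equal(nrow(res), 6)
  expect_true(all(res$q >= res$p))
  expect_true(all(res$significant))
  # identical groups: p = q = 1
  same <- data.frame(cell_line = lines, drug = "d",
                     sensitivity = rep(1:10, each = 2))
  r_same <- subgroup_drug_tests(same, setNames(rep(c("a", "b"), 10), lines),
                                list(c("a", "b")))
  expect_equal(r_same$p, 1)
  expect_equal(r_same$q, 1)
  # planted one-log shift is detected after BH in most seeds
  hits <- sapply(1:10, function(s) {
    set.seed(s)
    sens <- mk_sens(0)
    sens$sensitivity[sens$drug == "d1"] <- rnorm(20, 6, 0.5) +
      (sub[sens$cell_line[sens$drug == "d1"]] == "survival_HER2_high")
    rr <- subgroup_drug_tests(sens, sub,
                              list(c("survival_HER2_high",
                                     "survival_HER2_low")))
    rr$significant[rr$drug == "d1"]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("sensitivity binarization uses a strict mean cutoff", {
  sens <- data.frame(cell_line = c("a", "b", "c"), drug = "d",
                     sensitivity = c(1, 2, 3))
  calls <- binarize_sensitivity(sens)
  expect_equal(calls$call, c("resistant", "resistant", "sensitive"))
  # translation invariance
  sens2 <- sens
  sens2$sensitivity <- sens2$sensitivity + 10
  expect_equal(binarize_sensitivity(sens2)$call, calls$call)
  # all equal: nothing is strictly above the mean
  sens3 <- data.frame(cell_line = c("a", "b"), drug = "d",
                      sensitivity = c(2, 2))
  expect_true(all(binarize_sensitivity(sens3)$call == "resistant"))
  # all-missing drug dropped
  sens4 <- rbind(sens, data.frame(cell_line = c("a", "b"), drug = "e",
                                  sensitivity = NA_real_))
  expect_false("e" %in% binarize_sensitivity(sens4)$drug)
})

test_that("activity-sensitivity correlations bifurcate into the two arms", {
  st <- small_study(seed = 29, n_test_samples = 50)
  pd <- simulate_protein_drug(st$cfg, st$cohort$truth)
  truth_sens <- data.frame(cell_line = pd$truth$cell_line,
                           drug = pd$truth$drug,
                           sensitivity = -pd$truth$logec50)
  corr <- activity_drug_correlation(st$cohort$truth$planted_activity,
                                    truth_sens)
  arms <- gfrn_arms()
  # survival-driven drugs correlate + with survival arm, - with growth arm
  surv_drugs <- paste0("drug_surv", 1:3)
  expect_true(all(corr$rho[arms$survival, surv_drugs] > 0))
  expect_true(all(corr$rho[arms$growth, surv_drugs] < 0))
  grow_drugs <- paste0("drug_grow", 1:3)
  expect_true(all(corr$rho[arms$growth, grow_drugs] > 0))
  # hierarchical clustering of the correlation rows splits the arms
  hc <- hclust(dist(corr$rho[, c(surv_drugs, grow_drugs, "drug_her2",
                                 "drug_bad")]))
  grp <- cutree(hc, k = 2)
  expect_equal(length(unique(grp[arms$survival])), 1)
  expect_equal(length(unique(grp[arms$growth])), 1)
  expect_false(grp[arms$survival][1] == grp[arms$growth][1])
  # degenerate drug excluded with warning
  sens_const <- rbind(truth_sens,
                      data.frame(cell_line = truth_sens$cell_line[1:5],
                                 drug = "flat", sensitivity = 1))
  expect_warning(c2 <- activity_drug_correlation(
    st$cohort$truth$planted_activity, sens_const), "excluded")
  expect_false("flat" %in% colnames(c2$rho))
  # perfect rank agreement
  one <- data.frame(cell_line = colnames(st$cohort$truth$planted_activity),
                    drug = "mirror",
                    sensitivity =
                      st$cohort$truth$planted_activity["AKT", ])
  c3 <- activity_drug_correlation(
    st$cohort$truth$planted_activity["AKT", , drop = FALSE], one)
  expect_equal(unname(c3$rho["AKT", "mirror"]), 1)
})

test_that("significance counts behave under null and saturated labelling", {
  set.seed(14)
  lines <- sprintf("L%02d", 1:30)
  labels <- setNames(rep(c("pos", "neg"), 15), lines)
  null_sens <- do.call(rbind, lapply(paste0("d", 1:40), function(dr) {
    data.frame(cell_line = lines, drug = dr, sensitivity = rnorm(30),
               stringsAsFactors = FALSE)
  }))
  r0 <- phenotype_drug_significance_count(null_sens, labels)
  expect_equal(r0$n_tested, 40)
  expect_lte(r0$count, 8)  # ~2 expected under the null at alpha 0.05
  sat_sens <- null_sens
  sat_sens$sensitivity <- sat_sens$sensitivity * 0.1 +
    2 * (labels[sat_sens$cell_line] == "pos")
  r1 <- phenotype_drug_significance_count(sat_sens, labels)
  expect_equal(r1$count, 40)
  expect_equal(r1$fraction, 1)
  expect_error(phenotype_drug_significance_count(
    null_sens, setNames(rep("x", 30), lines)), "2 classes")
})
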