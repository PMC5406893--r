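test_that("differential weights follow the pooled-sd formula", {
  m <- rbind(g1 = c(2, 2, 0, 0), g2 = c(5, 5, 5, 5))
  colnames(m) <- c("p1", "p2", "c1", "c2")
  # zero variance in both groups: pooled sd floored, not NaN
  d <- differential_weights(m, c("p1", "p2"), c("c1", "c2"))
  expect_equal(unname(d["g1"]), 2 / 1e-6)
  expect_equal(unname(d["g2"]), 0)

  # identical groups give zero effect everywhere
  set.seed(1)
  x <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  x[, 6:10] <- x[, 1:5]
  expect_true(all(differential_weights(x, paste0("s", 1:5),
                                       paste0("s", 6:10)) == 0))

  # matches an independently coded brute-force statistic up to the
  # pooled-sd vs t-statistic scale factor
  st <- small_study(seed = 2)
  egfr <- st$train$annotation$sample[st$train$annotation$group == "EGFR"]
  gfp <- st$train$annotation$sample[st$train$annotation$group == "GFP"]
  d <- differential_weights(st$train$expr, egfr, gfp)
  ts <- brute_t_stats(st$train$expr, egfr, gfp)
  scale <- sqrt(1 / length(egfr) + 1 / length(gfp))
  expect_equal(unname(d), unname(ts * scale), tolerance = 1e-9)

  expect_error(differential_weights(x, "s1", paste0("s", 6:10)),
               "2 replicates")
  expect_error(differential_weights(x, paste0("s", 1:5), paste0("s", 5:10)),
               "overlap")
})

test_that("signature selection is balanced, anchored and tie-stable", {
  eff <- c(A = 3, B = 2, C = -1, D = -2)
  sig <- build_signature(eff, K = 4, anchor = "A")
  expect_setequal(sig$genes$gene[sig$genes$direction == "up"], c("A", "B"))
  expect_setequal(sig$genes$gene[sig$genes$direction == "down"],
                  c("C", "D"))

  # anchor outside the top genes displaces the weakest same-direction gene
  eff2 <- c(A = 3, B = 2, X = 0.1, C = -1, D = -2)
  sig2 <- build_signature(eff2, K = 2, anchor = "X")
  expect_true("X" %in% sig2$genes$gene)
  expect_equal(nrow(sig2$genes), 2)
  expect_equal(sum(sig2$genes$direction == "up"), 1)

  # all-equal effects: deterministic lexicographic tie-break
  eff3 <- setNames(rep(1, 6), c("f", "b", "d", "a", "c", "e"))
  sig3 <- build_signature(eff3, K = 4, anchor = "a")
  expect_identical(sig3$genes$gene[sig3$genes$direction == "up"],
                   c("a", "b"))

  # odd K: up side gets the extra gene
  sig5 <- build_signature(eff2, K = 5, anchor = "A")
  expect_equal(sum(sig5$genes$direction == "up"), 3)
  expect_equal(sum(sig5$genes$direction == "down"), 2)

  expect_error(build_signature(eff, K = 4, anchor = "Z"), "anchor")
  expect_error(build_signature(eff, K = 10, anchor = "A"), "exceeds")
})

test_that("raw scores match a brute-force oracle and behave symmetrically", {
  set.seed(42)
  test <- matrix(rnorm(30), 5, 6,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  eff <- setNames(c(2, 1.5, 1, -1.5, -2), paste0("g", 1:5))
  sig <- build_signature(eff, K = 4, anchor = "g1")
  a <- estimate_activity(sig, test)
  oracle <- brute_raw_score(sig$genes$gene,
                            ifelse(sig$genes$direction == "up", 1, -1),
                            test)
  expect_equal(unname(attr(a, "raw")), unname(oracle), tolerance = 1e-9)

  # min-max endpoints
  expect_equal(unname(a[which.max(attr(a, "raw"))]), 1)
  expect_equal(unname(a[which.min(attr(a, "raw"))]), 0)

  # negating every direction negates raw scores exactly
  flip <- sig
  flip$genes$direction <- ifelse(sig$genes$direction == "up", "down", "up")
  b <- estimate_activity(flip, test)
  expect_equal(unname(attr(b, "raw")), -unname(attr(a, "raw")),
               tolerance = 1e-12)
})

test_that("baseline-relative scoring is zero at the control baseline", {
  set.seed(7)
  ctrl <- matrix(rnorm(40, 5), 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
  bl <- cbind(mean = rowMeans(ctrl), sd = apply(ctrl, 1, sd))
  eff <- setNames(c(2, 1, -1, -2), paste0("g", 1:4))
  sig <- build_signature(eff, K = 4, anchor = "g1", control_baseline = bl)
  test <- cbind(s1 = bl[, "mean"], s2 = bl[, "mean"] + 1)
  a <- estimate_activity(sig, test, adaptive_background = FALSE)
  expect_equal(unname(attr(a, "raw")["s1"]), 0, tolerance = 1e-12)
})

test_that("cohort-relative activities are insensitive to a per-sample offset", {
  st <- small_study(seed = 11, n_test_samples = 100)
  model <- gfrn_signatures(st$train$expr, st$train$annotation$group,
                           K = 20, anchors = st$train$truth$anchors)
  sig <- model$signatures$AKT
  a1 <- estimate_activity(sig, st$cohort$expr)
  shifted <- st$cohort$expr
  shifted[, 3] <- shifted[, 3] + 5
  a2 <- estimate_activity(sig, shifted)
  expect_lt(max(abs(a1 - a2)), 0.05)
})

test_that("missing and degenerate test genes are handled", {
  eff <- setNames(c(2, 1, -1, -2), paste0("g", 1:4))
  sig <- build_signature(eff, K = 4, anchor = "g1")
  set.seed(3)
  test <- matrix(rnorm(12), 3, 4,
                 dimnames = list(paste0("g", c(1, 2, 4)), paste0("s", 1:4)))
  expect_warning(a <- estimate_activity(sig, test), "dropped")
  expect_length(a, 4)
  no_genes <- matrix(rnorm(8), 2, 4,
                     dimnames = list(c("x1", "x2"), paste0("s", 1:4)))
  expect_error(estimate_activity(sig, no_genes), "no signature genes")
  const <- matrix(1, 4, 3, dimnames = list(paste0("g", 1:4),
                                           paste0("s", 1:3)))
  expect_warning(ac <- estimate_activity(sig, const), "constant")
  expect_true(all(ac == 0.5))
  expect_error(estimate_activity(sig, test[, 1, drop = FALSE]),
               ">= 2 test samples")
})

test_that("adaptive signature re-estimation repairs inverted directions", {
  st <- small_study(seed = 13, n_test_samples = 80, activity_noise_sd = 0.5)
  model <- gfrn_signatures(st$train$expr, st$train$annotation$group,
                           K = 20, anchors = st$train$truth$anchors)
  sig <- model$signatures$HER2
  # corrupt half the directions; adaptive mode should recover the ranking
  bad <- sig
  flip_idx <- seq(1, nrow(bad$genes), by = 2)
  bad$genes$direction[flip_idx] <-
    ifelse(bad$genes$direction[flip_idx] == "up", "down", "up")
  a_bad <- estimate_activity(bad, st$cohort$expr)
  a_fix <- estimate_activity(bad, st$cohort$expr,
                             adaptive_signature = TRUE)
  truth <- st$cohort$truth$planted_activity["HER2", ]
  expect_gt(abs(cor(a_fix, truth, method = "spearman")),
            abs(cor(a_bad, truth, method = "spearman")))
  expect_gt(length(attr(a_fix, "flipped")), 0)
})

test_that("z-scaling of activities matches hand computation", {
  m <- rbind(P1 = c(0, 1), P2 = c(3, 3))
  colnames(m) <- c("a", "b")
  expect_warning(sc <- scale_activities(m), "zero-variance")
  expect_equal(unname(sc["P1", ]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(sc["P2", ]), c(0, 0))
  set.seed(1)
  x <- matrix(runif(30), 3, 10,
              dimnames = list(paste0("P", 1:3), paste0("s", 1:10)))
  sc2 <- scale_activities(x)
  expect_equal(unname(rowMeans(sc2)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(sc2, 1, sd)), rep(1, 3), tolerance = 1e-9)
  expect_error(scale_activities(x[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("LOOCV separates real signal, matches pair counting, and is null at chance", {
  st <- small_study(seed = 8, effect_size = 3, noise_sd = 0.5,
                    batch_shift_sd = 0)
  an <- st$train$annotation
  akt <- an$sample[an$group == "AKT"]
  gfp <- an$sample[an$group == "GFP"]
  cv <- loocv_validate(st$train$expr, akt, gfp, K = 20, anchor = "AKT")
  expect_true(cv$pass)
  expect_equal(cv$auc, 1.0)
  # AUC equals exhaustive pair enumeration (and the pROC computation)
  expect_equal(cv$auc, brute_auc(cv$scores[akt], cv$scores[gfp]))
  if (requireNamespace("pROC", quietly = TRUE)) {
    roc <- pROC::roc(rep(c(1, 0), c(length(akt), length(gfp))),
                     c(cv$scores[akt], cv$scores[gfp]), quiet = TRUE,
                     direction = "<")
    expect_equal(cv$auc, as.numeric(pROC::auc(roc)))
  }
  # permuted labels: chance-level AUC over an ensemble
  aucs <- sapply(1:8, function(s) {
    set.seed(s)
    pool <- sample(c(akt, gfp))
    loocv_validate(st$train$expr, pool[1:6], pool[7:12], K = 20,
                   anchor = "AKT")$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("the fitted model recovers planted activity and prints sanely", {
  st <- small_study(seed = 21, n_test_samples = 100)
  model <- gfrn_signatures(st$train$expr, st$train$annotation$group,
                           K = 20, anchors = st$train$truth$anchors)
  expect_s3_class(model, "gfrn_model")
  expect_output(print(model), "7 pathway")
  expect_equal(nrow(summary(model)$table), 7)
  act <- predict(model, st$cohort$expr)
  expect_true(all(act >= 0 & act <= 1))
  rec <- sapply(gfrn_pathways(), function(p) {
    cor(act[p, ], st$cohort$truth$planted_activity[p, ],
        method = "spearman")
  })
  expect_true(all(rec > 0.7))
  expect_output(print(act), "pathway")
  cf <- coef(model)
  expect_length(cf, 7)
  expect_equal(length(cf$AKT), 20)
})
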