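# Shared fixtures and independent oracles for the suite. Everything is
# generated in code; sizes are kept small so individual tests run in
# seconds.

# compact synthetic study config for unit tests
small_cfg <- function(seed = 1, ...) {
  defaults <- list(
    n_genes = 400, signature_size_per_pathway = 20,
    n_train_replicates_per_group = 4, n_control_replicates = 8,
    n_test_samples = 60, seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_config, args)
}

# simulate training + cohort once per config
small_study <- function(seed = 1, ...) {
  cfg <- small_cfg(seed = seed, ...)
  tr <- simulate_training(cfg)
  co <- simulate_cohort(cfg, tr$truth)
  list(cfg = cfg, train = tr, cohort = co)
}

# independent oracle: two-sample pooled-sd t statistic per gene, written
# from the textbook formula (not via differential_weights)
brute_t_stats <- function(m, g1, g2) {
  apply(m, 1, function(v) {
    a <- v[g1]; b <- v[g2]
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  })
}

# independent oracle: AUC by exhaustive pair enumeration
brute_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg) {
    s <- s + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

# independent oracle: Benjamini-Hochberg step-up from its definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  if (m > 1) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# independent oracle: raw signature score by direct loops (no vectorization
# shared with the implementation)
brute_raw_score <- function(genes, signs, test) {
  sapply(seq_len(ncol(test)), function(j) {
    acc <- 0
    for (i in seq_along(genes)) {
      v <- test[genes[i], ]
      z <- (v[j] - mean(v)) / sd(v)
      acc <- acc + signs[i] * z
    }
    acc / length(genes)
  })
}
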