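# Programmatic fixtures: small cohorts built in code at test time.

# Unstructured random cohort: independent SNPs, optional group shifts.
random_cohort <- function(n = 120, m = 5, n_groups = NULL, seed = 1,
                          alpha = 0, causal = 1) {
  set.seed(seed)
  p <- runif(m, 0.2, 0.8)
  geno <- sapply(p, function(pp) rbinom(n, 2, pp))
  y <- rnorm(n)
  if (alpha != 0) y <- y + geno[, causal] * alpha
  groups <- NULL
  if (!is.null(n_groups)) {
    groups <- rep_len(paste0("g", seq_len(n_groups)), n)
    y <- y + rnorm(n_groups)[match(groups, paste0("g", seq_len(n_groups)))]
  }
  snp_cohort(geno, y, groups = groups)
}

# Cohort with exactly equal-sized groups (for exact pool-nesting tests).
balanced_group_cohort <- function(n_groups = 10, group_size = 32, m = 400,
                                  seed = 1) {
  set.seed(seed)
  n <- n_groups * group_size
  p <- runif(m, 0.1, 0.9)
  geno <- sapply(p, function(pp) rbinom(n, 2, pp))
  groups <- rep(paste0("g", formatC(seq_len(n_groups), width = 2, flag = "0")),
                each = group_size)
  y <- rnorm(n) + rnorm(n_groups, 0, 0.5)[as.integer(factor(groups))]
  snp_cohort(geno, y, groups = groups)
}
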