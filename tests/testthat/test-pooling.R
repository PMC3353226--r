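# Pool construction, frequencies, perturbation and MAF filters.

test_that("whole-cohort rank pooling cuts ranks into equal blocks", {
  set.seed(1)
  y <- rnorm(3000)
  asg <- assign_pools_by_rank(y, n_pools = 4, within_group = FALSE)
  expect_identical(asg$sizes, rep(750L, 4))
  # pool 1 holds the 750 lowest phenotypes
  expect_setequal(which(asg$assignment == 1), order(y)[1:750])
})

test_that("singleton target makes the assignment a permutation", {
  y <- c(3, 1, 2, 5, 4)
  asg <- assign_pools_by_rank(y, n_pools = 5, within_group = FALSE)
  expect_setequal(asg$assignment, 1:5)
  expect_identical(asg$sizes, rep(1L, 5))
  # rank order: lowest phenotype -> pool 1
  expect_identical(asg$assignment[order(y)], 1:5)
})

test_that("940 individuals in 29 groups at 134 pools give sizes 6 to 8", {
  set.seed(2)
  gsz <- c(rep(33L, 12), rep(32L, 17))        # sums to 940
  groups <- rep(paste0("g", seq_len(29)), gsz)
  y <- rnorm(940)
  asg <- assign_pools_by_rank(y, groups, n_pools = 134)
  expect_identical(sum(asg$sizes), 940L)
  expect_length(asg$sizes, 134L)
  expect_true(all(asg$sizes %in% 6:8))
  # within-group pooling: all members of a pool share a group
  for (pl in seq_along(asg$sizes)) {
    members <- which(asg$assignment == pl)
    expect_length(unique(groups[members]), 1L)
    expect_identical(unique(groups[members]), as.character(asg$pool_group[pl]))
  }
})

test_that("pooling is deterministic and errors when a group would get no pool", {
  y <- rnorm(40)
  g <- rep(c("a", "b", "c", "d"), each = 10)
  a1 <- assign_pools_by_rank(y, g, n_pools = 8)
  a2 <- assign_pools_by_rank(y, g, n_pools = 8)
  expect_identical(a1, a2)
  expect_error(assign_pools_by_rank(y, g, n_pools = 3), "zero pools")
})

test_that("pool allele frequencies match direct allele counting", {
  # singleton pools: frequency is dosage / 2
  expect_equal(as.numeric(pool_allele_frequencies(
    matrix(c(0, 1, 2), ncol = 1), 1:3)), c(0, 0.5, 1))
  # one pool of {0,1,2} -> 0.5; one all-2 pool -> 1
  f <- pool_allele_frequencies(matrix(c(0, 1, 2, 2, 2, 2), ncol = 1),
                               c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(as.numeric(f), c(0.5, 1))
  # random 8-individual pools vs brute-force enumeration
  set.seed(4)
  geno <- matrix(rbinom(80, 2, 0.4), nrow = 16)
  asg <- rep(1:2, each = 8)
  f <- pool_allele_frequencies(geno, asg)
  for (pl in 1:2) for (j in 1:5)
    expect_equal(unname(f[pl, j]), sum(geno[asg == pl, j]) / 16)
  expect_error(pool_allele_frequencies(matrix(c(0, NA), ncol = 1), c(1L, 1L)),
               "missing")
})

test_that("frequency perturbation clamps and has the requested spread", {
  f <- matrix(runif(20), 4, 5)
  expect_identical(perturb_frequencies(f, 0), f)
  set.seed(5)
  hi <- perturb_frequencies(matrix(0.99, 1, 1e4), sd = 0.5)
  expect_true(all(hi >= 0 & hi <= 1))
  expect_true(any(hi == 1))                  # clamping active
  set.seed(6)
  mid <- perturb_frequencies(matrix(0.5, 1, 1e5), sd = 0.05)
  expect_equal(sd(mid), 0.05, tolerance = 0.02)   # no clamping at 0.5
  expect_error(perturb_frequencies(f, -1), "non-negative")
})

test_that("pool mean phenotypes are exact means and preserve the grand mean", {
  y <- c(1, 3, 2, 8)
  expect_equal(pool_mean_phenotypes(y, c(1, 1, 2, 2)), c(2, 5))
  expect_equal(pool_mean_phenotypes(y, 1:4), y)
  set.seed(7)
  yy <- rnorm(100)
  asg <- assign_pools_by_rank(yy, n_pools = 7, within_group = FALSE)
  mp <- pool_mean_phenotypes(yy, asg$assignment)
  expect_equal(weighted.mean(mp, asg$sizes), mean(yy), tolerance = 1e-12)
})

test_that("size-weighted pool frequencies recover the cohort frequency exactly", {
  ch <- random_cohort(n = 90, m = 4, seed = 8)
  ps <- make_pools(ch, 7, within_group = FALSE)
  for (j in 1:4)
    expect_equal(weighted.mean(ps$freq[, j], ps$sizes),
                 mean(ch$genotypes[, j]) / 2, tolerance = 1e-12)
})

test_that("weighted group MAF follows the size-weighted mean frequency", {
  ps <- pool_set(sizes = c(5, 5), mean_phenotype = c(0, 1),
                 freq = matrix(c(0.2, 0.4), 2, 1), group = c("a", "a"))
  expect_equal(weighted_group_maf(ps, 1, "a"), 0.3)
  ps2 <- pool_set(sizes = c(6, 8), mean_phenotype = c(0, 1),
                  freq = matrix(c(0, 0.07), 2, 1), group = c("a", "a"))
  expect_equal(weighted_group_maf(ps2, 1, "a"), (6 * 0 + 8 * 0.07) / 14)
  fixed <- pool_set(sizes = c(4, 4), mean_phenotype = c(0, 1),
                    freq = matrix(1, 2, 1), group = c("a", "a"))
  expect_equal(weighted_group_maf(fixed, 1, "a"), 0)
})

test_that("group MAF filter brackets its threshold", {
  # group a at weighted MAF 0.005, group b comfortably polymorphic
  ps <- pool_set(sizes = c(10, 10, 10, 10), mean_phenotype = c(0, 1, 0, 1),
                 freq = matrix(c(0.005, 0.005, 0.3, 0.4), 4, 1),
                 group = c("a", "a", "b", "b"))
  expect_identical(excluded_groups(filter_groups_by_maf(ps, 0.01), 1), "a")
  expect_identical(excluded_groups(filter_groups_by_maf(ps, 0.001), 1),
                   character(0))
  # all polymorphic -> empty; monomorphic group -> listed
  mono <- pool_set(sizes = c(10, 10), mean_phenotype = c(0, 1),
                   freq = matrix(c(1, 0.5), 2, 1), group = c("a", "b"))
  expect_identical(excluded_groups(filter_groups_by_maf(mono, 0.01), 1), "a")
})

test_that("pre-adjustment removes group means and preserves within-group order", {
  y <- c(1, 2, 3, 11, 12, 13)
  g <- rep(c("a", "b"), each = 3)
  r <- preadjust_phenotypes(y, g)
  expect_equal(r, c(-1, 0, 1, -1, 0, 1), tolerance = 1e-12)
  expect_equal(preadjust_phenotypes(y, rep("a", 6)), y - mean(y),
               tolerance = 1e-12)
  # matches per-group demeaning when no covariates are fitted
  set.seed(9)
  yy <- rnorm(50); gg <- sample(letters[1:4], 50, TRUE)
  expect_equal(preadjust_phenotypes(yy, gg), yy - ave(yy, gg),
               tolerance = 1e-10)
})

test_that("one-representative sampling picks one member per pool", {
  set.seed(10)
  asg <- rep(1:5, times = c(3, 4, 2, 1, 5))
  reps <- sample_pool_representatives(asg)
  expect_length(reps, 5)
  expect_identical(asg[reps], 1:5)
})

test_that("a pool set round-trips through its two-file TSV format", {
  ch <- random_cohort(n = 60, m = 3, n_groups = 3, seed = 11)
  ps <- make_pools(ch, 9)
  pf <- tempfile(fileext = ".tsv"); ff <- tempfile(fileext = ".tsv")
  write_pool_set(ps, pf, ff)
  back <- read_pool_set(pf, ff)
  expect_identical(back$sizes, ps$sizes)
  expect_equal(back$mean_phenotype, ps$mean_phenotype, tolerance = 1e-10)
  expect_equal(unname(back$freq), unname(ps$freq), tolerance = 1e-10)
  expect_identical(as.character(back$group), as.character(ps$group))
})
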