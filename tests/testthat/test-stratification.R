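# Genomic correlation matrix from pool frequencies and its eigenvectors.

test_that("pools with identical frequency vectors correlate at 1", {
  set.seed(1)
  f <- matrix(runif(200, 0.1, 0.9), 4, 50)
  f[2, ] <- f[1, ]                # an identical pair among four pools
  gcm <- genomic_correlation_from_pools(f, rep(10, 4))
  expect_equal(unname(gcm$matrix[1, 2]), 1, tolerance = 1e-10)
  expect_equal(unname(diag(gcm$matrix)), rep(1, 4), tolerance = 1e-10)
})

test_that("singleton pools reduce to the individual-genotype construction", {
  set.seed(2)
  geno <- sapply(runif(200, 0.1, 0.9), function(p) rbinom(30, 2, p))
  gcm <- genomic_correlation_from_pools(geno / 2, rep(1L, 30))
  expect_equal(unname(gcm$relationship), unname(vanraden_oracle(geno)),
               tolerance = 1e-10)
  # symmetry and unit diagonal of the correlation form
  expect_lt(max(abs(gcm$matrix - t(gcm$matrix))), 1e-12)
  expect_equal(unname(diag(gcm$matrix)), rep(1, 30), tolerance = 1e-10)
})

test_that("monomorphic SNPs are dropped and an all-monomorphic input raises", {
  f <- cbind(c(0.3, 0.3), c(0.2, 0.6))     # first SNP constant across pools
  gcm <- genomic_correlation_from_pools(f, c(5, 5))
  expect_identical(gcm$n_snps_used, 1L)
  expect_error(genomic_correlation_from_pools(cbind(c(1, 1), c(0, 0)), c(5, 5)),
               "monomorphic")
})

test_that("correlations are invariant to which allele is counted", {
  set.seed(3)
  f <- matrix(runif(200, 0.05, 0.95), 8, 25)
  flip <- sample(25, 10)
  f2 <- f; f2[, flip] <- 1 - f2[, flip]
  g1 <- genomic_correlation_from_pools(f, rep(4, 8))
  g2 <- genomic_correlation_from_pools(f2, rep(4, 8))
  expect_equal(g1$matrix, g2$matrix, tolerance = 1e-10)
})

test_that("two diverged populations separate in the pool correlations", {
  set.seed(4)
  m <- 1000; fst <- 0.1
  p0 <- runif(m, 0.1, 0.9); shape <- (1 - fst) / fst
  f1 <- rbeta(m, p0 * shape, (1 - p0) * shape)
  f2 <- rbeta(m, p0 * shape, (1 - p0) * shape)
  npool <- 8; size <- 20
  pf <- rbind(
    t(replicate(npool, rbinom(m, 2 * size, f1) / (2 * size))),
    t(replicate(npool, rbinom(m, 2 * size, f2) / (2 * size))))
  gcm <- genomic_correlation_from_pools(pf, rep(size, 2 * npool))
  breed <- rep(1:2, each = npool)
  C <- gcm$matrix; diag(C) <- NA
  within <- mean(C[breed == 1, breed == 1], na.rm = TRUE)
  between <- mean(C[breed == 1, breed == 2], na.rm = TRUE)
  expect_gt(within, between)
  # and the first eigenvector linearly separates the populations
  ev1 <- leading_eigenvectors(gcm, 2)$vectors[, 1]
  expect_true(max(ev1[breed == 1]) < min(ev1[breed == 2]) ||
              max(ev1[breed == 2]) < min(ev1[breed == 1]))
})

test_that("leading eigenpairs match a constructed known spectrum", {
  set.seed(5)
  n <- 20
  Q <- qr.Q(qr(matrix(rnorm(n * n), n)))
  vals <- sort(runif(n, 0.1, 5), decreasing = TRUE)
  A <- Q %*% diag(vals) %*% t(Q)
  basis <- leading_eigenvectors(A, 5)
  expect_equal(basis$values, vals[1:5], tolerance = 1e-8)
  for (j in 1:5) {
    v <- basis$vectors[, j]
    expect_equal(abs(sum(v * Q[, j])), 1, tolerance = 1e-8)  # same axis
    expect_gt(v[which.max(abs(v))], 0)                       # sign rule
  }
  expect_equal(crossprod(basis$vectors), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("rank-one matrices yield their generating vector", {
  v <- c(3, -1, 2, 0.5) / sqrt(sum(c(3, -1, 2, 0.5)^2))
  basis <- leading_eigenvectors(v %*% t(v), 2)
  expect_equal(abs(sum(basis$vectors[, 1] * v)), 1, tolerance = 1e-10)
  expect_equal(basis$values[1], 1, tolerance = 1e-10)
  expect_error(leading_eigenvectors(v %*% t(v), 4), "smaller")
  expect_error(leading_eigenvectors(matrix(c(1, NA, NA, 1), 2), 1),
               "non-finite")
})

test_that("splitting pools preserves the leading structure", {
  ch <- balanced_group_cohort(n_groups = 12, group_size = 32, m = 800,
                              seed = 6)
  # inject two-population structure so there is signal to preserve
  half <- as.integer(factor(ch$groups)) <= 6
  geno <- ch$genotypes
  shift_snps <- sample(ncol(geno), 200)
  geno[half, shift_snps] <- pmin(geno[half, shift_snps] + rbinom(
    sum(half) * length(shift_snps), 1, 0.4), 2)
  ch2 <- snp_cohort(geno, ch$phenotypes, groups = ch$groups)
  coarse <- make_pools(ch2, 12 * 4)   # 4 pools/group of 8
  fine <- make_pools(ch2, 12 * 8)     # 8 pools/group of 4: exact split of coarse
  ev_c <- leading_eigenvectors(
    genomic_correlation_from_pools(coarse$freq, coarse$sizes), 2)$vectors[, 1]
  ev_f <- leading_eigenvectors(
    genomic_correlation_from_pools(fine$freq, fine$sizes), 2)$vectors[, 1]
  parent <- coarse$assignment[match(seq_along(fine$sizes), fine$assignment)]
  child_means <- tapply(ev_f, parent, mean)
  expect_gt(abs(cor(as.numeric(child_means), ev_c)), 0.9)
})
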