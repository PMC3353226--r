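# Synthetic stratified cohort: two genetically diverged breeds (Balding-
# Nichols drift model), contemporary groups nested within breed, and a
# polygenic quantitative trait with configurable heritability.  Stands in
# for stratified livestock data so that within/across-group pooling and
# stratification correction can be exercised end to end.

#' Configuration for the synthetic stratified cohort
#'
#' Defaults emulate a two-breed beef-cattle design: 940 individuals in 29
#' contemporary groups (each group containing one breed only, groups of at
#' least 16), 5000 SNPs with breed divergence Fst = 0.1, 50 causal SNPs,
#' and a high-heritability trait (h^2 = 0.65) with contemporary-group
#' effects of SD 0.5 phenotypic standard deviations.
#'
#' @param n_individuals Total cohort size.
#' @param n_groups Number of contemporary groups (nested in breed; split
#'   as evenly as possible between the two breeds).
#' @param n_snps Number of biallelic SNPs.
#' @param n_causal Number of SNPs carrying additive effects.
#' @param fst Balding-Nichols divergence between the two breeds.
#' @param heritability Proportion of within-group phenotypic variance that
#'   is genetic (effects are rescaled to hit this on the realised
#'   genotypes).
#' @param group_effect_sd SD of the Gaussian contemporary-group effects,
#'   in phenotypic standard deviations.
#' @param ancestral_freq_range Range of the uniform ancestral allele
#'   frequency draw.
#' @param min_group_size Smallest admissible group size.
#' @return A list of class \code{"strat_config"}.
#' @export
strat_config <- function(n_individuals = 940, n_groups = 29, n_snps = 5000,
                         n_causal = 50, fst = 0.1, heritability = 0.65,
                         group_effect_sd = 0.5,
                         ancestral_freq_range = c(0.05, 0.95),
                         min_group_size = 16) {
  stopifnot(n_groups >= 2, n_snps >= 1, n_causal >= 1, n_causal <= n_snps,
            fst >= 0, fst < 1, heritability > 0, heritability < 1,
            group_effect_sd >= 0)
  if (n_individuals / n_groups < min_group_size)
    stop("groups would be smaller than the minimum group size")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_groups = as.integer(n_groups),
                 n_snps = as.integer(n_snps), n_causal = as.integer(n_causal),
                 fst = fst, heritability = heritability,
                 group_effect_sd = group_effect_sd,
                 ancestral_freq_range = ancestral_freq_range,
                 min_group_size = as.integer(min_group_size)),
            class = "strat_config")
}

#' Simulate a two-breed stratified cohort
#'
#' Ancestral allele frequencies are drawn uniformly, breed frequencies from
#' a Balding-Nichols Beta draw around them at the configured Fst (Fst = 0
#' keeps the ancestral frequency), genotypes Binomial(2, breed frequency).
#' A random subset of SNPs carries additive effects, rescaled so that the
#' realised within-group genetic variance is exactly \code{heritability};
#' the Gaussian noise is orthogonalised against the genetic values within
#' groups and rescaled to \code{1 - heritability}, so the realised
#' within-group heritability equals the target by construction.
#' Phenotype = group effect + genetic value + noise.  Groups are near-equal-sized and nested within
#' breed.  Uses the current R random stream.
#'
#' @param config A [strat_config()].
#' @return A [snp_cohort()] with \code{groups} and \code{breed} labels and
#'   attributes \code{true_effects} (per-SNP per-allele effects, zero for
#'   non-causal SNPs), \code{causal} (indices), \code{breed_freq}
#'   (2 x SNPs matrix) and \code{group_effects}.
#' @export
simulate_stratified_cohort <- function(config) {
  stopifnot(inherits(config, "strat_config"))
  n <- config$n_individuals
  m <- config$n_snps
  ng <- config$n_groups

  # near-equal group sizes summing to n, nested in two equal-ish breeds
  gsz <- rep(n %/% ng, ng)
  r <- n %% ng
  if (r > 0) gsz[seq_len(r)] <- gsz[seq_len(r)] + 1L
  if (any(gsz < config$min_group_size))
    stop("group sizes fell below the minimum")
  gb <- rep(c(1L, 2L), c(ceiling(ng / 2), floor(ng / 2)))  # group -> breed
  groups <- rep(seq_len(ng), gsz)
  breed <- gb[groups]

  p0 <- stats::runif(m, config$ancestral_freq_range[1],
                     config$ancestral_freq_range[2])
  if (config$fst > 0) {
    shape <- (1 - config$fst) / config$fst
    bf <- rbind(stats::rbeta(m, p0 * shape, (1 - p0) * shape),
                stats::rbeta(m, p0 * shape, (1 - p0) * shape))
  } else {
    bf <- rbind(p0, p0)
  }
  geno <- matrix(stats::rbinom(n * m, 2L, rep(bf[breed, ], 1)), nrow = n)
  colnames(geno) <- paste0("snp", seq_len(m))

  causal <- sort(sample.int(m, config$n_causal))
  a_raw <- stats::rnorm(config$n_causal)
  gval <- as.numeric(geno[, causal, drop = FALSE] %*% a_raw)
  h2 <- config$heritability
  # scale effects so the realised within-group genetic variance is h2, and
  # draw noise orthogonal to the genetic values within groups scaled to
  # 1 - h2, pinning the realised heritability at the target exactly
  gc <- gval - stats::ave(gval, groups)
  vg <- stats::var(gc)
  scale <- if (vg > 0) sqrt(h2 / vg) else 0
  a <- a_raw * scale
  gval <- gval * scale
  gc <- gc * scale
  ge <- stats::rnorm(ng, 0, config$group_effect_sd)
  nz <- stats::rnorm(n)
  nzc <- nz - stats::ave(nz, groups)
  if (sum(gc^2) > 0) nz <- nz - gc * sum(nzc * gc) / sum(gc^2)
  nzc <- nz - stats::ave(nz, groups)
  nz <- nz * sqrt((1 - h2) / stats::var(nzc))
  y <- ge[groups] + gval + nz

  ch <- snp_cohort(geno, y, groups = paste0("g", formatC(groups, width = 2, flag = "0")),
                   breed = paste0("breed", breed))
  effects <- numeric(m)
  effects[causal] <- a
  attr(ch, "true_effects") <- effects
  attr(ch, "causal") <- causal
  attr(ch, "breed_freq") <- bf
  attr(ch, "group_effects") <- ge
  ch
}

# Internal: scan every SNP of a cohort with one analysis strategy,
# returning per-SNP alpha / mlp / converged vectors.
.scan_strategy <- function(cohort, strategy, n_pools, n_eigenvectors,
                           maf_exclude) {
  m <- ncol(cohort$genotypes)
  alpha <- mlp <- rep(NA_real_, m)
  conv <- rep(FALSE, m)

  fit_all <- function(pools, sigma2, fit_groups, ev, report) {
    for (j in seq_len(m)) {
      excl <- if (is.null(report)) NULL else excluded_groups(report, j)
      est <- tryCatch(
        estimate_pooled_snp_effect(pools, j, sigma2 = sigma2,
                                   fit_groups = fit_groups,
                                   eigenvectors = ev,
                                   exclude_groups = excl),
        error = function(e) NULL)
      if (!is.null(est) && isTRUE(est$converged)) {
        alpha[j] <<- est$alpha; mlp[j] <<- est$mlp; conv[j] <<- TRUE
      }
    }
  }

  # sigma2 for the back-transformation: variance of phenotypes after
  # removing the group effects the model accounts for
  sigma2_adj <- stats::var(preadjust_phenotypes(cohort$phenotypes,
                                                cohort$groups))

  if (strategy == "within_concurrent") {
    pools <- make_pools(cohort, n_pools, within_group = TRUE)
    gcm <- genomic_correlation_from_pools(pools$freq, pools$sizes)
    ev <- leading_eigenvectors(gcm, n_eigenvectors)$vectors
    report <- filter_groups_by_maf(pools, maf_exclude)
    fit_all(pools, sigma2_adj, TRUE, ev, report)
  } else if (strategy == "preadjust_within") {
    yadj <- preadjust_phenotypes(cohort$phenotypes, cohort$groups)
    pools <- make_pools(cohort, n_pools, within_group = TRUE,
                        phenotypes = yadj)
    gcm <- genomic_correlation_from_pools(pools$freq, pools$sizes)
    ev <- leading_eigenvectors(gcm, n_eigenvectors)$vectors
    fit_all(pools, stats::var(yadj), FALSE, ev, NULL)
  } else if (strategy == "preadjust_across") {
    yadj <- preadjust_phenotypes(cohort$phenotypes, cohort$groups)
    pools <- make_pools(cohort, n_pools, within_group = FALSE,
                        phenotypes = yadj)
    gcm <- genomic_correlation_from_pools(pools$freq, pools$sizes)
    ev <- leading_eigenvectors(gcm, n_eigenvectors)$vectors
    fit_all(pools, stats::var(yadj), FALSE, ev, NULL)
  } else if (strategy == "one_per_pool") {
    asg <- assign_pools_by_rank(cohort$phenotypes, cohort$groups, n_pools)
    reps <- sample_pool_representatives(asg$assignment)
    sub <- snp_cohort(cohort$genotypes[reps, , drop = FALSE],
                      cohort$phenotypes[reps],
                      groups = droplevels(cohort$groups[reps]))
    pools <- singleton_pools(sub)
    gcm <- genomic_correlation_from_pools(pools$freq, pools$sizes)
    ev <- leading_eigenvectors(gcm, n_eigenvectors)$vectors
    report <- filter_groups_by_maf(pools, maf_exclude)
    s2 <- stats::var(preadjust_phenotypes(sub$phenotypes, sub$groups))
    fit_all(pools, s2, TRUE, ev, report)
  } else stop("unknown strategy: ", strategy)

  data.frame(snp = seq_len(m), alpha = alpha, mlp = mlp, converged = conv)
}

# Internal: individual-genotype LS reference scan with concurrent group +
# eigenvector fitting and per-SNP group-MAF exclusions.
.scan_ls_reference <- function(cohort, n_eigenvectors, maf_exclude) {
  pools <- singleton_pools(cohort)
  gcm <- genomic_correlation_from_pools(pools$freq, pools$sizes)
  ev <- leading_eigenvectors(gcm, n_eigenvectors)$vectors
  report <- filter_groups_by_maf(pools, maf_exclude)
  m <- ncol(cohort$genotypes)
  alpha <- mlp <- rep(NA_real_, m)
  conv <- rep(FALSE, m)
  for (j in seq_len(m)) {
    est <- tryCatch(
      fit_individual_ls(cohort, j, fit_groups = TRUE, covariates = ev,
                        exclude_groups = excluded_groups(report, j)),
      error = function(e) NULL)
    if (!is.null(est) && isTRUE(est$converged)) {
      alpha[j] <- est$alpha; mlp[j] <- est$mlp; conv[j] <- TRUE
    }
  }
  data.frame(snp = seq_len(m), alpha = alpha, mlp = mlp, converged = conv)
}

#' Compare pooling strategies against the least-squares reference
#'
#' Runs up to four analysis strategies on a stratified cohort --
#' within-group pooling with concurrent group + eigenvector fitting,
#' pre-adjusted phenotypes with within-group pooling, pre-adjusted
#' phenotypes with pooling across groups, and one random individual
#' assayed per pool -- and reports, per minor-allele-frequency stratum,
#' the R-squared of each strategy's per-SNP alpha and MLP against the
#' individual-genotype least-squares reference (concurrent groups,
#' eigenvectors, group-MAF exclusions).
#'
#' @param cohort A stratified [snp_cohort()] (e.g. from
#'   [simulate_stratified_cohort()]).
#' @param n_pools Number of pools for the pooling strategies.
#' @param strategies Subset of the four strategy names.
#' @param n_eigenvectors Leading eigenvectors fitted (default 5).
#' @param maf_strata Population-MAF lower bounds defining the reporting
#'   strata.
#' @param maf_exclude Within-group MAF threshold for excluding groups.
#' @return A data frame: \code{strategy}, \code{maf_gt}, \code{parameter},
#'   \code{r2}, \code{slope}, \code{n_snps}.
#' @export
compare_pooling_strategies <- function(cohort, n_pools,
                                       strategies = c("within_concurrent",
                                                      "preadjust_within",
                                                      "preadjust_across",
                                                      "one_per_pool"),
                                       n_eigenvectors = 5,
                                       maf_strata = c(0.20, 0.05, 0.01),
                                       maf_exclude = 0.01) {
  stopifnot(inherits(cohort, "snp_cohort"))
  strategies <- match.arg(strategies, several.ok = TRUE)
  pop_maf <- pmin(cohort_allele_freq(cohort), 1 - cohort_allele_freq(cohort))
  ref <- .scan_ls_reference(cohort, n_eigenvectors, maf_exclude)

  out <- list()
  for (s in strategies) {
    res <- .scan_strategy(cohort, s, n_pools, n_eigenvectors, maf_exclude)
    for (th in maf_strata) {
      for (param in c("alpha", "mlp")) {
        yv <- res[[param]]; xv <- ref[[param]]
        use <- pop_maf > th & res$converged & ref$converged &
          is.finite(yv) & is.finite(xv)
        r2 <- slope <- NA_real_
        if (sum(use) >= 3 && stats::var(xv[use]) > 0) {
          slope <- stats::cov(xv[use], yv[use]) / stats::var(xv[use])
          r2 <- stats::cor(xv[use], yv[use])^2
        }
        out[[length(out) + 1L]] <- data.frame(
          strategy = s, maf_gt = th, parameter = param,
          r2 = r2, slope = slope, n_snps = sum(use))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
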