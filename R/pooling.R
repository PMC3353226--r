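# Pool construction and bookkeeping: rank-based assignment within (or
# across) contemporary groups, pool allele frequencies and mean phenotypes,
# Gaussian frequency perturbation with clamping, and MAF-based group
# filters.

#' Construct a pool set
#'
#' Container for pool-level data: per-pool sizes, optional contemporary
#' group, mean phenotypes and the pools-by-SNPs allele-frequency matrix.
#'
#' @param sizes Integer vector: number of individuals per pool.
#' @param mean_phenotype Numeric vector: arithmetic mean phenotype per pool.
#' @param freq Numeric matrix (pools x SNPs) of allele frequencies in
#'   \code{[0, 1]}.
#' @param group Optional factor mapping pools to contemporary groups.
#' @param assignment Optional integer vector mapping individuals to pool
#'   indices (kept when the pool set was built from individual data).
#' @param perturbed Logical: have the frequencies been error-perturbed?
#' @return An object of class \code{"pool_set"}.
#' @export
pool_set <- function(sizes, mean_phenotype, freq, group = NULL,
                     assignment = NULL, perturbed = FALSE) {
  freq <- as.matrix(freq)
  k <- length(sizes)
  if (nrow(freq) != k || length(mean_phenotype) != k)
    stop("'sizes', 'mean_phenotype' and rows of 'freq' must agree")
  if (any(sizes <= 0)) stop("pool sizes must be positive")
  if (any(!is.finite(freq)) || any(freq < 0) || any(freq > 1))
    stop("pool allele frequencies must lie in [0, 1]")
  if (!is.null(group)) {
    if (length(group) != k) stop("'group' must have one entry per pool")
    group <- factor(group)
  }
  if (!is.null(assignment)) {
    if (sum(sizes) != length(assignment))
      stop("pool sizes must sum to the number of assigned individuals")
    tab <- tabulate(assignment, nbins = k)
    if (!all(tab == sizes))
      stop("'assignment' is inconsistent with 'sizes'")
  }
  if (is.null(colnames(freq)))
    colnames(freq) <- paste0("snp", seq_len(ncol(freq)))
  structure(list(sizes = as.integer(sizes),
                 mean_phenotype = as.numeric(mean_phenotype),
                 freq = freq, group = group, assignment = assignment,
                 perturbed = isTRUE(perturbed)),
            class = "pool_set")
}

#' @export
print.pool_set <- function(x, ...) {
  cat(sprintf("pool_set: %d pools (sizes %d..%d) x %d SNPs%s%s\n",
              length(x$sizes), min(x$sizes), max(x$sizes), ncol(x$freq),
              if (!is.null(x$group)) sprintf(", %d groups", nlevels(x$group)) else "",
              if (x$perturbed) ", frequencies perturbed" else ""))
  invisible(x)
}

# Split k pools over strata by largest-remainder apportionment,
# guaranteeing every stratum at least one pool.  Ties broken by stratum
# order.  Raises if k < number of strata.
.apportion_pools <- function(stratum_sizes, n_pools) {
  g <- length(stratum_sizes)
  if (n_pools < g)
    stop("target pool count smaller than the number of groups: ",
         "some group would receive zero pools")
  quota <- n_pools * stratum_sizes / sum(stratum_sizes)
  k <- pmax(1L, floor(quota))
  k <- pmin(k, stratum_sizes)          # never more pools than individuals
  rem <- n_pools - sum(k)
  if (rem > 0) {
    frac <- quota - floor(quota)
    frac[k >= stratum_sizes] <- -Inf   # cannot grow past singleton pools
    ord <- order(frac, decreasing = TRUE)
    i <- 1L
    while (rem > 0 && i <= g) {
      j <- ord[i]
      if (k[j] < stratum_sizes[j]) { k[j] <- k[j] + 1L; rem <- rem - 1L }
      i <- i + 1L
    }
  } else if (rem < 0) {
    frac <- quota - floor(quota)
    frac[k <= 1L] <- Inf
    ord <- order(frac)
    i <- 1L
    while (rem < 0 && i <= g) {
      j <- ord[i]
      if (k[j] > 1L) { k[j] <- k[j] - 1L; rem <- rem + 1L }
      i <- i + 1L
    }
  }
  if (sum(k) != n_pools)
    stop("could not apportion ", n_pools, " pools over ", g, " groups")
  k
}

# Cut s ranked individuals into k contiguous blocks whose sizes differ by
# at most one; lowest-rank blocks take the extra individual.
.block_sizes <- function(s, k) {
  sz <- rep(s %/% k, k)
  r <- s %% k
  if (r > 0) sz[seq_len(r)] <- sz[seq_len(r)] + 1L
  sz
}

#' Assign individuals to pools by phenotype rank
#'
#' Within each stratum (contemporary group, or the whole cohort when
#' \code{within_group = FALSE}), individuals are sorted by phenotype (ties
#' broken stably by input order) and cut into contiguous rank blocks whose
#' sizes differ by at most one.  For within-group pooling, per-group pool
#' counts are allocated proportionally to group size by largest-remainder
#' apportionment so the total matches \code{n_pools} exactly.
#'
#' @param phenotypes Numeric vector of individual phenotypes.
#' @param groups Optional contemporary-group labels.
#' @param n_pools Target total number of pools.
#' @param within_group Pool within groups (default when groups are given)
#'   or across the whole cohort.
#' @return A list with \code{assignment} (individual -> pool index),
#'   \code{pool_group} (factor, or NULL) and \code{sizes}.
#' @export
assign_pools_by_rank <- function(phenotypes, groups = NULL,
                                 n_pools, within_group = !is.null(groups)) {
  n <- length(phenotypes)
  if (n_pools < 1L || n_pools > n)
    stop("'n_pools' must lie between 1 and the number of individuals")
  if (within_group && is.null(groups))
    stop("'within_group = TRUE' requires group labels")
  assignment <- integer(n)
  if (!within_group) {
    ord <- order(phenotypes)           # stable for ties
    sizes <- .block_sizes(n, n_pools)
    assignment[ord] <- rep(seq_len(n_pools), times = sizes)
    pool_group <- NULL
  } else {
    groups <- factor(groups)
    gsizes <- as.integer(table(groups))
    kg <- .apportion_pools(gsizes, n_pools)
    sizes <- integer(0)
    pool_group <- character(0)
    offset <- 0L
    for (gi in seq_along(levels(groups))) {
      idx <- which(groups == levels(groups)[gi])
      ord <- idx[order(phenotypes[idx])]
      bs <- .block_sizes(length(idx), kg[gi])
      assignment[ord] <- offset + rep(seq_len(kg[gi]), times = bs)
      sizes <- c(sizes, bs)
      pool_group <- c(pool_group, rep(levels(groups)[gi], kg[gi]))
      offset <- offset + kg[gi]
    }
    pool_group <- factor(pool_group, levels = levels(groups))
  }
  list(assignment = assignment, pool_group = pool_group,
       sizes = as.integer(sizes))
}

#' Pool allele frequencies from individual dosages
#'
#' @param genotypes Dosage matrix (individuals x SNPs), values 0/1/2.
#' @param assignment Integer vector mapping individuals to pool indices.
#' @return Pools-by-SNPs matrix: sum of dosages in the pool divided by
#'   twice the pool size.
#' @export
pool_allele_frequencies <- function(genotypes, assignment) {
  genotypes <- as.matrix(genotypes)
  if (any(is.na(genotypes)))
    stop("missing genotype dosages are not supported")
  sizes <- tabulate(assignment)
  sums <- rowsum(genotypes, assignment, reorder = TRUE)
  sums / (2 * sizes)
}

#' Mean phenotype per pool
#'
#' @param phenotypes Numeric vector of individual phenotypes.
#' @param assignment Integer vector mapping individuals to pool indices.
#' @return Numeric vector of per-pool arithmetic means.
#' @export
pool_mean_phenotypes <- function(phenotypes, assignment) {
  sizes <- tabulate(assignment)
  as.numeric(rowsum(phenotypes, assignment, reorder = TRUE)) / sizes
}

#' Perturb pool allele frequencies with Gaussian measurement error
#'
#' Adds i.i.d. N(0, sd^2) noise to every pool-by-SNP frequency and clamps
#' the result to \code{[0, 1]} (frequencies below 0 are set to 0, above 1
#' to 1).  \code{sd = 0} returns the input unchanged.  Uses the current R
#' random-number stream; seed upstream for reproducibility.
#'
#' @param freq Pools-by-SNPs frequency matrix.
#' @param sd Standard deviation of the measurement error.
#' @return Perturbed frequency matrix.
#' @export
perturb_frequencies <- function(freq, sd = 0.05) {
  if (sd < 0) stop("'sd' must be non-negative")
  if (sd == 0) return(freq)
  noisy <- freq + stats::rnorm(length(freq), mean = 0, sd = sd)
  noisy[noisy < 0] <- 0
  noisy[noisy > 1] <- 1
  noisy
}

#' Build a complete pool set from a cohort
#'
#' Convenience wrapper: rank-based assignment, pool frequencies, pool mean
#' phenotypes and (optionally) frequency perturbation in one call.
#'
#' @param cohort A [snp_cohort()].
#' @param n_pools Target number of pools.
#' @param within_group Pool within contemporary groups (default when the
#'   cohort has groups).
#' @param freq_error_sd SD of Gaussian frequency measurement error
#'   (0 = none).
#' @param phenotypes Optional replacement phenotypes used for ranking and
#'   pool means (e.g. pre-adjusted residuals); defaults to the cohort's.
#' @return A [pool_set()].
#' @export
make_pools <- function(cohort, n_pools,
                       within_group = !is.null(cohort$groups),
                       freq_error_sd = 0, phenotypes = NULL) {
  stopifnot(inherits(cohort, "snp_cohort"))
  y <- if (is.null(phenotypes)) cohort$phenotypes else phenotypes
  asg <- assign_pools_by_rank(y, cohort$groups, n_pools,
                              within_group = within_group)
  freq <- pool_allele_frequencies(cohort$genotypes, asg$assignment)
  mph <- pool_mean_phenotypes(y, asg$assignment)
  if (freq_error_sd > 0) freq <- perturb_frequencies(freq, freq_error_sd)
  pool_set(sizes = asg$sizes, mean_phenotype = mph, freq = freq,
           group = asg$pool_group, assignment = asg$assignment,
           perturbed = freq_error_sd > 0)
}

#' Singleton pools: every individual its own pool
#'
#' @param cohort A [snp_cohort()].
#' @return A [pool_set()] with one pool of size one per individual
#'   (frequency = dosage / 2, mean phenotype = phenotype).
#' @export
singleton_pools <- function(cohort) {
  stopifnot(inherits(cohort, "snp_cohort"))
  n <- nrow(cohort$genotypes)
  pool_set(sizes = rep(1L, n), mean_phenotype = cohort$phenotypes,
           freq = cohort$genotypes / 2, group = cohort$groups,
           assignment = seq_len(n))
}

#' Size-weighted within-group minor allele frequency
#'
#' The group frequency is the mean of the group's pool frequencies weighted
#' by pool size; the MAF is \code{min(f, 1 - f)}.
#'
#' @param pools A [pool_set()] with group labels.
#' @param snp SNP index or name.
#' @param group Group label.
#' @return Minor allele frequency in \code{[0, 0.5]}.
#' @export
weighted_group_maf <- function(pools, snp, group) {
  stopifnot(inherits(pools, "pool_set"))
  if (is.null(pools$group)) stop("pools carry no group labels")
  sel <- pools$group == group
  if (!any(sel)) stop("no pools in group '", group, "'")
  f <- stats::weighted.mean(pools$freq[sel, snp], pools$sizes[sel])
  min(f, 1 - f)
}

#' Flag contemporary groups with low within-group MAF, per SNP
#'
#' For each SNP, lists the groups whose size-weighted minor allele
#' frequency falls below \code{threshold}; downstream fits drop those
#' groups' pools for that SNP.  In effect this removes groups in which one
#' SNP allele is (nearly) fixed.
#'
#' @param pools A [pool_set()] with group labels.
#' @param threshold MAF threshold (default 0.01).
#' @return An object of class \code{"group_filter_report"}: list with
#'   \code{excluded} (logical groups x SNPs matrix), \code{group_maf}
#'   (groups x SNPs weighted MAF matrix) and \code{threshold}.
#' @export
filter_groups_by_maf <- function(pools, threshold = 0.01) {
  stopifnot(inherits(pools, "pool_set"))
  if (is.null(pools$group)) stop("pools carry no group labels")
  w <- pools$sizes
  num <- rowsum(pools$freq * w, pools$group, reorder = TRUE)
  den <- as.numeric(rowsum(w, pools$group, reorder = TRUE))
  f <- num / den
  maf <- pmin(f, 1 - f)
  structure(list(excluded = maf < threshold, group_maf = maf,
                 threshold = threshold),
            class = "group_filter_report")
}

#' Groups excluded for one SNP
#'
#' @param report A [filter_groups_by_maf()] report.
#' @param snp SNP index or name.
#' @return Character vector of excluded group labels (possibly empty).
#' @export
excluded_groups <- function(report, snp) {
  stopifnot(inherits(report, "group_filter_report"))
  rownames(report$excluded)[report$excluded[, snp]]
}

#' Pre-adjust phenotypes for contemporary group (and optional covariates)
#'
#' Returns the residuals of an ordinary least-squares fit of phenotype on
#' group indicators and any extra covariates; with groups only this equals
#' per-group mean-centering.
#'
#' @param phenotypes Numeric vector.
#' @param groups Group labels.
#' @param covariates Optional numeric covariate matrix (e.g. eigenvector
#'   loadings per individual).
#' @return Numeric vector of residual phenotypes.
#' @export
preadjust_phenotypes <- function(phenotypes, groups, covariates = NULL) {
  g <- factor(groups)
  X <- if (nlevels(g) > 1L) stats::model.matrix(~g)
       else matrix(1, length(phenotypes), 1)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  stats::lm.fit(X, phenotypes)$residuals
}

#' Sample one random individual from each pool
#'
#' Utility for the fixed-assay comparison: instead of assaying the pool,
#' assay one randomly chosen member.  Uses the current R random stream.
#'
#' @param assignment Integer vector mapping individuals to pool indices.
#' @return Integer vector (one individual index per pool, in pool order).
#' @export
sample_pool_representatives <- function(assignment) {
  pools <- sort(unique(assignment))
  vapply(pools, function(p) {
    members <- which(assignment == p)
    if (length(members) == 1L) members else sample(members, 1L)
  }, integer(1))
}

#' Write / read a pool set as two TSV files
#'
#' The pool table holds \code{pool_id}, \code{group}, \code{size},
#' \code{mean_phenotype}; the frequency table holds the pools-by-SNPs
#' matrix with a header row of SNP ids.  Individual-level assignment is not
#' serialised.
#'
#' @param pools A [pool_set()].
#' @param pool_file,freq_file Paths for the two TSV files.
#' @return \code{write_pool_set}: invisibly, the two paths.
#'   \code{read_pool_set}: a [pool_set()].
#' @export
write_pool_set <- function(pools, pool_file, freq_file) {
  stopifnot(inherits(pools, "pool_set"))
  tab <- data.frame(pool_id = seq_along(pools$sizes),
                    group = if (is.null(pools$group)) NA
                            else as.character(pools$group),
                    size = pools$sizes,
                    mean_phenotype = pools$mean_phenotype)
  utils::write.table(tab, pool_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(pools$freq), freq_file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(pool_file, freq_file))
}

#' @rdname write_pool_set
#' @export
read_pool_set <- function(pool_file, freq_file) {
  tab <- utils::read.table(pool_file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  freq <- as.matrix(utils::read.table(freq_file, header = TRUE, sep = "\t",
                                      check.names = FALSE))
  grp <- if (all(is.na(tab$group))) NULL else tab$group
  pool_set(sizes = tab$size, mean_phenotype = tab$mean_phenotype,
           freq = freq, group = grp)
}
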