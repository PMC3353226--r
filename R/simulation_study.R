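# Single-SNP simulation study: replicate cohorts with one biallelic SNP and
# a Gaussian residual, analysed at a ladder of pool counts by pooled
# logistic regression, by logistic regression on un-pooled data, and by the
# least-squares reference.  Replicate-level estimates are then compared by
# regressing pooled results on the least-squares results.

#' Configuration for the single-SNP simulation study
#'
#' Defaults reproduce the study design: 3000 unrelated individuals, 1000
#' replicates, allele frequency p ~ U(0.01, 0.99), per-allele effect
#' alpha ~ U(0, 0.5) trait units, residual variance 1, pool-count ladder
#' 2^1..2^11 (the largest power of two below the population size), and
#' optional Gaussian allele-frequency measurement error.
#'
#' @param n_individuals Cohort size per replicate.
#' @param n_reps Number of simulation replicates.
#' @param p_range Range of the uniform allele-frequency draw.
#' @param alpha_range Range of the uniform per-allele-effect draw (trait
#'   units).
#' @param sigma_e2 Residual (non-SNP) phenotypic variance.
#' @param pool_counts Integer vector of pool counts to analyse.
#' @param freq_error_sd SD of Gaussian pool-frequency measurement error
#'   (0 = none; frequencies clamped to [0, 1] after perturbation).
#' @param include_individual Also analyse each replicate with un-pooled
#'   logistic regression (every individual a pool of size one)?
#' @param seed Master seed; per-replicate substream seeds are derived from
#'   it so replicates are independently reproducible.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_individuals = 3000, n_reps = 1000,
                       p_range = c(0.01, 0.99), alpha_range = c(0, 0.5),
                       sigma_e2 = 1, pool_counts = 2^(1:11),
                       freq_error_sd = 0, include_individual = TRUE,
                       seed = 1) {
  stopifnot(n_individuals >= 2, n_reps >= 1, sigma_e2 > 0,
            all(pool_counts >= 2), freq_error_sd >= 0)
  if (max(pool_counts) > n_individuals)
    stop("pool counts cannot exceed the number of individuals")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_reps = as.integer(n_reps), p_range = p_range,
                 alpha_range = alpha_range, sigma_e2 = sigma_e2,
                 pool_counts = as.integer(sort(unique(pool_counts))),
                 freq_error_sd = freq_error_sd,
                 include_individual = isTRUE(include_individual),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate one single-SNP replicate cohort
#'
#' Draws p and alpha, samples genotypes Binomial(2, p) independently (no
#' family structure), and sets phenotype = dosage * alpha + N(0, sigma_e2);
#' genotype effects are 0, alpha, 2*alpha for 0, 1, 2 copies of the counted
#' allele.  Uses the current R random stream.
#'
#' @param config A [sim_config()].
#' @return A [snp_cohort()] with a single SNP and attributes
#'   \code{true_p} and \code{true_alpha}.
#' @export
simulate_replicate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- stats::runif(1, config$p_range[1], config$p_range[2])
  alpha <- stats::runif(1, config$alpha_range[1], config$alpha_range[2])
  n <- config$n_individuals
  dosage <- stats::rbinom(n, 2L, p)
  y <- dosage * alpha + stats::rnorm(n, 0, sqrt(config$sigma_e2))
  ch <- snp_cohort(matrix(dosage, ncol = 1, dimnames = list(NULL, "snp1")), y)
  attr(ch, "true_p") <- p
  attr(ch, "true_alpha") <- alpha
  ch
}

#' Analyse one replicate at a ladder of pool counts
#'
#' Fits the least-squares reference, optionally un-pooled logistic
#' regression, and pooled logistic regression at each requested pool count
#' (rank-based pooling over the whole cohort; frequencies optionally
#' perturbed).  All back-transformations use the replicate's sample
#' phenotypic variance and the size-weighted mean pool frequency.
#'
#' @param cohort A single-SNP [snp_cohort()] (e.g. from
#'   [simulate_replicate()]).
#' @param config A [sim_config()]; only \code{pool_counts},
#'   \code{freq_error_sd} and \code{include_individual} are used.
#' @return A data frame with one row per analysis: \code{method},
#'   \code{pool_count}, \code{alpha}, \code{mlp}, \code{converged}.
#' @export
analyze_replicate <- function(cohort, config) {
  stopifnot(inherits(cohort, "snp_cohort"), inherits(config, "sim_config"))
  sigma2 <- stats::var(cohort$phenotypes)
  n <- nrow(cohort$genotypes)

  rows <- vector("list", length(config$pool_counts) + 2L)
  ls <- fit_individual_ls(cohort, 1L)
  rows[[1L]] <- data.frame(method = "individual_ls", pool_count = n,
                           alpha = ls$alpha, mlp = ls$mlp,
                           converged = ls$converged)
  j <- 2L
  if (config$include_individual) {
    lr <- tryCatch(estimate_individual_lr(cohort, 1L, sigma2 = sigma2),
                   error = function(e) NULL)
    rows[[j]] <- data.frame(method = "individual_lr", pool_count = n,
                            alpha = if (is.null(lr)) NA_real_ else lr$alpha,
                            mlp = if (is.null(lr)) NA_real_ else lr$mlp,
                            converged = !is.null(lr) && lr$converged)
    j <- j + 1L
  }
  for (k in config$pool_counts) {
    ps <- make_pools(cohort, k, within_group = FALSE,
                     freq_error_sd = config$freq_error_sd)
    est <- tryCatch(
      estimate_pooled_snp_effect(ps, 1L, sigma2 = sigma2),
      error = function(e) NULL)
    rows[[j]] <- data.frame(method = "pooled_lr", pool_count = k,
                            alpha = if (is.null(est)) NA_real_ else est$alpha,
                            mlp = if (is.null(est)) NA_real_ else est$mlp,
                            converged = !is.null(est) && est$converged)
    j <- j + 1L
  }
  do.call(rbind, rows[seq_len(j - 1L)])
}

#' Run the full simulation study
#'
#' Simulates and analyses \code{config$n_reps} replicates.  Each replicate
#' runs on its own RNG substream seeded from the master seed, so results
#' are reproducible replicate-by-replicate.
#'
#' @param config A [sim_config()].
#' @return A data frame of replicate-level estimates: \code{rep},
#'   \code{true_p}, \code{true_alpha}, \code{method}, \code{pool_count},
#'   \code{alpha}, \code{mlp}, \code{converged}.
#' @export
run_simulation_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$n_reps)
  out <- vector("list", config$n_reps)
  for (r in seq_len(config$n_reps)) {
    set.seed(rep_seeds[r])
    ch <- simulate_replicate(config)
    res <- analyze_replicate(ch, config)
    res$rep <- r
    res$true_p <- attr(ch, "true_p")
    res$true_alpha <- attr(ch, "true_alpha")
    out[[r]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("rep", "true_p", "true_alpha", "method", "pool_count",
          "alpha", "mlp", "converged")]
}

#' Comparison statistics: pooled results regressed on the LS reference
#'
#' For each pool count (and for un-pooled logistic regression, labelled
#' with pool count = cohort size), each parameter (alpha, MLP) and each
#' replicate subset (all replicates, or only those whose least-squares MLP
#' is below 5), fits an ordinary regression (with intercept) of the
#' logistic-regression value on the least-squares value across replicates
#' and reports its R-squared and slope.  Replicates with non-converged
#' fits on either side are dropped and counted.
#'
#' @param results Data frame from [run_simulation_study()].
#' @param mlp_subset_threshold MLP cut defining the low-significance
#'   subset (default 5, i.e. p > 1e-5), applied to the least-squares MLP.
#' @return A data frame: \code{method}, \code{pool_count},
#'   \code{parameter}, \code{subset}, \code{r2}, \code{slope},
#'   \code{n_used}, \code{n_dropped}.
#' @export
comparison_stats <- function(results, mlp_subset_threshold = 5) {
  ref <- results[results$method == "individual_ls", ]
  ref <- ref[ref$converged, c("rep", "alpha", "mlp")]
  names(ref) <- c("rep", "ls_alpha", "ls_mlp")

  lr <- results[results$method != "individual_ls", ]
  combos <- unique(lr[, c("method", "pool_count")])
  out <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- lr[lr$method == combos$method[i] &
              lr$pool_count == combos$pool_count[i], ]
    m <- merge(sub, ref, by = "rep")
    ok <- m$converged & is.finite(m$alpha) & is.finite(m$mlp)
    for (param in c("alpha", "mlp")) {
      yv <- if (param == "alpha") m$alpha else m$mlp
      xv <- if (param == "alpha") m$ls_alpha else m$ls_mlp
      for (subset in c("all", "mlp_lt_5")) {
        use <- ok & (subset == "all" | m$ls_mlp < mlp_subset_threshold)
        r2 <- slope <- NA_real_
        if (sum(use) >= 3 && stats::var(xv[use]) > 0) {
          slope <- stats::cov(xv[use], yv[use]) / stats::var(xv[use])
          r2 <- stats::cor(xv[use], yv[use])^2
        }
        out[[length(out) + 1L]] <- data.frame(
          method = combos$method[i], pool_count = combos$pool_count[i],
          parameter = param, subset = subset, r2 = r2, slope = slope,
          n_used = sum(use),
          n_dropped = if (subset == "all") sum(!ok) else NA_integer_)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$method, -res$pool_count, res$parameter, res$subset), ]
}

#' Pivot comparison statistics to a wide table
#'
#' One row per (parameter, statistic, subset), one column per pool count --
#' the layout of the published summary table.
#'
#' @param stats Data frame from [comparison_stats()].
#' @return A data frame in wide layout.
#' @export
comparison_table <- function(stats) {
  counts <- sort(unique(stats$pool_count), decreasing = TRUE)
  rows <- expand.grid(statistic = c("r2", "slope"),
                      subset = c("all", "mlp_lt_5"),
                      parameter = c("alpha", "mlp"),
                      stringsAsFactors = FALSE)[, 3:1]
  out <- rows
  for (k in counts) {
    col <- vapply(seq_len(nrow(rows)), function(i) {
      sel <- stats$pool_count == k & stats$parameter == rows$parameter[i] &
        stats$subset == rows$subset[i]
      if (!any(sel)) return(NA_real_)
      stats[[rows$statistic[i]]][sel][1L]
    }, numeric(1))
    out[[as.character(k)]] <- round(col, 3)
  }
  out
}
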