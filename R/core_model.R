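# Core estimator: binomial logistic regression of pool allele counts on the
# (half) pool mean phenotype, and the closed-form conversion of the fitted
# slope to a per-allele effect in trait units.
#
# For a biallelic SNP with additive genotype effects (-alpha, 0, +alpha) and
# diploid residual variance sigma_e^2, the probability that a haploid DNA
# copy carries the increasing allele follows a logistic curve in the haploid
# phenotype, with slope b = 2*alpha/sigma_e^2.  Regressing pool allele
# counts on half the pool mean phenotype therefore estimates b, and alpha is
# recovered from b, the allele frequency p and the diploid phenotypic
# variance sigma^2 = sigma_e^2 + 2p(1-p)alpha^2.

#' Fit a binomial logistic regression of allele counts on phenotype
#'
#' Maximum-likelihood (IRLS) fit of
#' \code{log-odds(successes/total) = g + b x + covariates \%*\% beta},
#' where \code{x} is typically one half of a pool mean phenotype.
#'
#' Successes may be real-valued: pool allele counts are derived as
#' frequency times pool size and are rarely integral.  The fractional-count
#' fit proceeds silently (the usual non-integer-count warning is muffled);
#' estimates and standard errors are those of the binomial quasi-likelihood.
#'
#' Quasi-separation (fitted probabilities numerically 0 or 1) or failure of
#' IRLS to converge within \code{max_iter} iterations sets
#' \code{converged = FALSE} rather than raising, so genome scans do not
#' abort on degenerate SNPs.
#'
#' @param successes Numeric vector of counts of the counted allele, one per
#'   binomial observation (pool).  Real values allowed, in \code{[0, total]}.
#' @param total Numeric vector of binomial totals (pool sizes), > 0.
#' @param x Numeric regressor: one half of the pool mean phenotype.
#' @param covariates Optional numeric matrix of additional covariates
#'   (group indicators, eigenvector loadings), one row per observation.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Relative deviance convergence tolerance.
#' @param test Significance test for the slope: \code{"wald"} (z test on
#'   \code{b}, the default, matching \code{summary.glm}) or \code{"lrt"}
#'   (likelihood-ratio chi-square against the model without \code{x}).
#' @return An object of class \code{"logistic_fit"}: list with elements
#'   \code{intercept_g}, \code{slope_b}, \code{se_b}, \code{zvalue},
#'   \code{pvalue}, \code{log_pvalue} (natural log, for precision),
#'   \code{converged}, \code{n_obs}, \code{coefficients}.
#' @examples
#' fit <- fit_binomial_logit(c(1, 1), c(2, 2), c(-1, 1))
#' fit$slope_b   # 0: symmetric frequencies force zero slope
#' @export
fit_binomial_logit <- function(successes, total, x, covariates = NULL,
                               max_iter = 100L, tol = 1e-8,
                               test = c("wald", "lrt")) {
  test <- match.arg(test)
  n <- length(successes)
  if (length(total) != n || length(x) != n)
    stop("'successes', 'total' and 'x' must have equal length")
  if (n < 2L)
    stop("at least two binomial observations are required")
  if (any(!is.finite(successes)) || any(!is.finite(total)) || any(!is.finite(x)))
    stop("non-finite values in observations")
  if (any(total <= 0))
    stop("binomial totals must be positive")
  if (any(successes < 0 | successes > total))
    stop("successes must lie in [0, total]")
  if (diff(range(x)) == 0)
    stop("regressor 'x' is constant across observations")
  if (all(successes == 0) || all(successes == total))
    stop("slope unidentifiable: every observation fixed for the same allele")

  X <- cbind("(Intercept)" = 1, x = x)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop("covariates must have one row per observation")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("c", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  if (qr(X)$rank < ncol(X))
    stop("covariate matrix is rank deficient")

  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, successes / total, weights = total,
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = tol,
                                                maxit = max_iter)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w), fixed = TRUE))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })

  p <- fit$rank
  converged <- isTRUE(fit$converged) && !separated && p == ncol(X)
  cf <- fit$coefficients
  Rm <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  Rm[lower.tri(Rm)] <- 0
  covmat <- tryCatch(chol2inv(Rm), error = function(e) NULL)
  se <- if (is.null(covmat)) rep(NA_real_, p) else sqrt(diag(covmat))
  se_b <- if (p >= 2L) se[2L] else NA_real_
  b <- cf[["x"]]
  if (!is.finite(se_b) || se_b <= 0) converged <- FALSE

  if (test == "wald") {
    z <- b / se_b
    logp <- log(2) + stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE)
  } else {
    X0 <- X[, -2L, drop = FALSE]
    fit0 <- suppressWarnings(
      stats::glm.fit(X0, successes / total, weights = total,
                     family = stats::binomial(),
                     control = stats::glm.control(epsilon = tol,
                                                  maxit = max_iter)))
    dev_diff <- max(fit0$deviance - fit$deviance, 0)
    z <- sign(b) * sqrt(dev_diff)
    logp <- stats::pchisq(dev_diff, df = 1, lower.tail = FALSE, log.p = TRUE)
  }

  structure(list(
    intercept_g = unname(cf[1L]),
    slope_b     = unname(b),
    se_b        = unname(se_b),
    zvalue      = unname(z),
    pvalue      = exp(logp),
    log_pvalue  = unname(logp),
    converged   = converged,
    n_obs       = n,
    coefficients = cf,
    deviance    = fit$deviance,
    test        = test
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Binomial logistic fit (", x$n_obs, " observations)\n", sep = "")
  cat(sprintf("  g = %.6g, b = %.6g (SE %.3g), p = %.3g [%s]%s\n",
              x$intercept_g, x$slope_b, x$se_b, x$pvalue, x$test,
              if (x$converged) "" else "  ** not converged **"))
  invisible(x)
}

#' Convert a logistic slope to a per-allele effect in trait units
#'
#' Inverts the identity \code{b = 2 alpha / sigma_e^2} with
#' \code{sigma^2 = sigma_e^2 + 2 p (1-p) alpha^2}, giving
#' \deqn{\alpha = \frac{-1 + \sqrt{1 + 2p(1-p) b^2 \sigma^2}}{2p(1-p)\, b}.}
#' The implementation uses the equivalent cancellation-free form
#' \code{b * sigma2 / (1 + sqrt(1 + 2p(1-p) b^2 sigma2))}, whose value at
#' \code{b = 0} is the series limit \code{b * sigma2 / 2}, so the map is
#' continuous through zero.  The sign of the result always matches the
#' sign of \code{b}.
#'
#' @param b Logistic slope: log-odds per (haploid) trait unit.
#' @param p Allele frequency in (0, 1); enters only through \code{p(1-p)},
#'   so which allele is counted does not matter.
#' @param sigma2 Diploid phenotypic variance, in trait units squared.
#' @return Per-allele effect alpha, in trait units.  Vectorised over
#'   \code{b}, \code{p} and \code{sigma2}.
#' @examples
#' alpha_from_b(1, 0.5, 1.125)   # 0.5
#' alpha_from_b(0, 0.5, 1)       # 0
#' @export
alpha_from_b <- function(b, p, sigma2) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("allele frequency 'p' must lie strictly inside (0, 1)")
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0))
    stop("'sigma2' must be positive")
  k <- 2 * p * (1 - p)
  # (-1 + sqrt(1 + u)) / (k b) with u = k b^2 sigma2, rewritten as
  # b sigma2 / (1 + sqrt(1 + u)): algebraically identical but free of the
  # small-b cancellation, and equal to the series limit b sigma2 / 2 at 0.
  b * sigma2 / (1 + sqrt(1 + k * b^2 * sigma2))
}

#' Minus log10 of a p-value
#'
#' @param pvalue Numeric p-value(s) in (0, 1].
#' @return \code{-log10(pvalue)}; \code{mlp_from_pvalue(1e-5)} is exactly 5.
#' @export
mlp_from_pvalue <- function(pvalue) {
  if (any(!is.finite(pvalue)) || any(pvalue <= 0) || any(pvalue > 1))
    stop("p-values must lie in (0, 1]")
  -log10(pvalue)
}

# MLP from a natural-log p-value, capped so that numerically-zero p-values
# (possible for very large effects) report a finite score.
.mlp_from_logp <- function(logp, cap = 300) {
  mlp <- -logp / log(10)
  pmin(pmax(mlp, 0), cap)
}

#' Estimate a SNP effect from pooled data by logistic regression
#'
#' Builds one binomial observation per pool -- successes = pool allele
#' frequency times pool size, total = pool size, regressor = half the pool
#' mean phenotype -- fits [fit_binomial_logit()], and converts the fitted
#' slope to a per-allele effect with [alpha_from_b()] using the
#' pool-size-weighted mean allele frequency and the diploid phenotypic
#' variance.
#'
#' Counts use pool frequency times the number of \emph{haploid} DNA copies
#' in the pool (2n for a pool of n individuals) by default, the scale on
#' which the haploid-copy model is formulated.  \code{count_scale =
#' "individuals"} multiplies by pool size n instead; this leaves the
#' fitted slope and alpha unchanged but halves the effective binomial
#' information, deflating significance roughly twofold.
#'
#' @param pools A [pool_set()] object.
#' @param snp SNP index or column name into \code{pools$freq}.
#' @param sigma2 Diploid phenotypic variance for the back-transformation.
#'   If \code{NULL}, it is computed as the sample variance of
#'   \code{phenotypes}; one of the two must be given.
#' @param phenotypes Optional vector of individual (possibly pre-adjusted)
#'   phenotypes used only to estimate \code{sigma2}.
#' @param fit_groups If \code{TRUE}, contemporary-group indicators
#'   (treatment coding, first level as reference) are included as
#'   covariates; requires \code{pools$group}.
#' @param eigenvectors Optional pools-by-k matrix of stratification
#'   covariates (e.g. from [leading_eigenvectors()]), fitted as raw real
#'   covariates, never nested within group.
#' @param exclude_groups Optional character vector of group labels whose
#'   pools are dropped before fitting (per-SNP MAF exclusions).
#' @param count_scale \code{"haploid"} (default: 2n copies per pool) or
#'   \code{"individuals"} (n per pool).
#' @param test Passed to [fit_binomial_logit()].
#' @param mlp_cap Upper bound for the reported MLP.
#' @return An object of class \code{"snp_effect_estimate"}: list with
#'   \code{alpha} (trait units per allele copy), \code{mlp}, \code{pvalue},
#'   \code{slope_b}, \code{se_b}, \code{p_hat}, \code{sigma2},
#'   \code{method}, \code{n_obs}, \code{converged},
#'   \code{excluded_groups}.  When every retained pool is fixed for one
#'   allele the estimate is flagged (\code{alpha = NA},
#'   \code{converged = FALSE}) instead of raising.
#' @export
estimate_pooled_snp_effect <- function(pools, snp, sigma2 = NULL,
                                       phenotypes = NULL,
                                       fit_groups = FALSE,
                                       eigenvectors = NULL,
                                       exclude_groups = NULL,
                                       count_scale = c("haploid", "individuals"),
                                       test = c("wald", "lrt"),
                                       mlp_cap = 300) {
  count_scale <- match.arg(count_scale)
  test <- match.arg(test)
  stopifnot(inherits(pools, "pool_set"))
  if (is.null(sigma2)) {
    if (is.null(phenotypes))
      stop("supply 'sigma2' or individual 'phenotypes' to estimate it from")
    sigma2 <- stats::var(phenotypes)
  }

  keep <- rep(TRUE, nrow(pools$freq))
  if (!is.null(exclude_groups) && length(exclude_groups)) {
    if (is.null(pools$group))
      stop("'exclude_groups' given but pools carry no group labels")
    keep <- !(as.character(pools$group) %in% as.character(exclude_groups))
  }
  freq  <- pools$freq[keep, snp]
  sizes <- pools$sizes[keep]
  x     <- pools$mean_phenotype[keep] / 2

  p_hat <- stats::weighted.mean(freq, sizes)
  method_tag <- if (all(pools$sizes == 1)) "individual_lr" else "pooled_lr"
  flagged <- function() {
    structure(list(snp = snp, method = method_tag, alpha = NA_real_,
                   mlp = NA_real_, pvalue = NA_real_, slope_b = NA_real_,
                   se_b = NA_real_, p_hat = p_hat, sigma2 = sigma2,
                   n_obs = sum(keep), converged = FALSE,
                   excluded_groups = setdiff(unique(as.character(pools$group)),
                                             unique(as.character(pools$group[keep])))),
              class = "snp_effect_estimate")
  }
  if (p_hat <= 0 || p_hat >= 1) return(flagged())

  mult <- if (count_scale == "haploid") 2 else 1
  successes <- freq * sizes * mult
  totals <- sizes * mult

  covars <- NULL
  if (fit_groups) {
    if (is.null(pools$group))
      stop("'fit_groups = TRUE' but pools carry no group labels")
    g <- droplevels(factor(pools$group[keep]))
    if (nlevels(g) > 1L)
      covars <- stats::model.matrix(~g)[, -1L, drop = FALSE]
  }
  if (!is.null(eigenvectors)) {
    ev <- as.matrix(eigenvectors)[keep, , drop = FALSE]
    covars <- if (is.null(covars)) ev else cbind(covars, ev)
  }

  fit <- fit_binomial_logit(successes, totals, x, covariates = covars,
                            test = test)
  alpha <- if (is.finite(fit$slope_b))
    alpha_from_b(fit$slope_b, p_hat, sigma2) else NA_real_
  mlp <- if (is.finite(fit$log_pvalue))
    .mlp_from_logp(fit$log_pvalue, cap = mlp_cap) else NA_real_

  structure(list(snp = snp, method = method_tag, alpha = alpha, mlp = mlp,
                 pvalue = fit$pvalue, slope_b = fit$slope_b,
                 se_b = fit$se_b, p_hat = p_hat, sigma2 = sigma2,
                 n_obs = fit$n_obs, converged = fit$converged,
                 excluded_groups = setdiff(unique(as.character(pools$group)),
                                           unique(as.character(pools$group[keep])))),
            class = "snp_effect_estimate")
}

#' Logistic-regression SNP effect from individual genotypes
#'
#' Treats each individual as a pool of size one (successes = dosage/2,
#' total = 1, regressor = phenotype/2) and delegates to
#' [estimate_pooled_snp_effect()], so the two are identical by
#' construction.
#'
#' @param cohort A [snp_cohort()] object.
#' @param snp SNP index or column name.
#' @param ... Passed on to [estimate_pooled_snp_effect()]
#'   (\code{fit_groups}, \code{eigenvectors}, \code{exclude_groups}, ...).
#' @inheritParams estimate_pooled_snp_effect
#' @return A \code{"snp_effect_estimate"} with method
#'   \code{"individual_lr"}.
#' @export
estimate_individual_lr <- function(cohort, snp, sigma2 = NULL, ...) {
  stopifnot(inherits(cohort, "snp_cohort"))
  ps <- singleton_pools(cohort)
  if (is.null(sigma2)) sigma2 <- stats::var(cohort$phenotypes)
  estimate_pooled_snp_effect(ps, snp, sigma2 = sigma2, ...)
}

#' @export
print.snp_effect_estimate <- function(x, ...) {
  cat(sprintf("SNP effect [%s]: alpha = %.5g, MLP = %.4g (p_hat = %.3f, n = %d)%s\n",
              x$method, x$alpha, x$mlp, x$p_hat, x$n_obs,
              if (isTRUE(x$converged)) "" else "  ** not converged **"))
  invisible(x)
}

#' @export
as.data.frame.snp_effect_estimate <- function(x, ...) {
  data.frame(snp = as.character(x$snp), method = x$method, alpha = x$alpha,
             slope_b = x$slope_b, se_b = x$se_b, pvalue = x$pvalue,
             mlp = x$mlp, p_hat = x$p_hat, sigma2 = x$sigma2,
             n_obs = x$n_obs, converged = x$converged,
             n_excluded_groups = length(x$excluded_groups),
             stringsAsFactors = FALSE)
}
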