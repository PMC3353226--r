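# Reference analysis: ordinary least-squares regression of individual
# phenotype on genotype dosage (0/1/2) with optional group and
# stratification covariates.  This is the benchmark the pooled logistic
# estimates are compared against.

# OLS of y on cbind(target, X); returns coefficient, SE, t, two-sided
# p-value (natural log) and residual variance for the first column.
.ols_target <- function(target, X, y) {
  XX <- cbind(target = target, X)
  qr_ <- qr(XX)
  if (qr_$rank < ncol(XX)) return(NULL)
  cf <- qr.coef(qr_, y)
  res <- y - XX %*% cf
  df <- length(y) - ncol(XX)
  if (df <= 0) return(NULL)
  s2 <- sum(res^2) / df
  covmat <- chol2inv(qr.R(qr_))      # rows/cols follow qr_$pivot order
  pos <- which(qr_$pivot == 1L)
  se <- sqrt(s2 * covmat[pos, pos])
  tval <- cf[1L] / se
  logp <- log(2) + stats::pt(abs(tval), df, lower.tail = FALSE, log.p = TRUE)
  list(coef = unname(cf[1L]), se = unname(se), tvalue = unname(tval),
       log_pvalue = unname(logp), residual_variance = s2, df = df)
}

#' Least-squares SNP effect from individual genotypes
#'
#' Ordinary least-squares fit of phenotype on allele dosage (coded 0/1/2)
#' plus optional contemporary-group indicators and covariates:
#' \code{Y = G alpha + X beta + e}.  The estimate of \code{alpha} is the
#' per-allele (haploid copy) effect in trait units; significance is the
#' two-sided t-test on \code{alpha}.
#'
#' @param cohort A [snp_cohort()].
#' @param snp SNP index or column name.
#' @param fit_groups Include contemporary-group indicators (treatment
#'   coding, first level as reference).
#' @param covariates Optional numeric matrix of per-individual covariates
#'   (e.g. eigenvector loadings).
#' @param exclude_groups Optional group labels whose individuals are
#'   dropped before fitting (per-SNP MAF exclusions).
#' @param mlp_cap Upper bound for the reported MLP (p-values below
#'   10^-cap are floored).
#' @return A \code{"snp_effect_estimate"} with method
#'   \code{"individual_ls"} and an extra \code{residual_variance} field.
#'   Monomorphic SNPs (after exclusions) yield a flagged estimate
#'   (\code{alpha = NA}, \code{converged = FALSE}) rather than an error.
#' @export
fit_individual_ls <- function(cohort, snp, fit_groups = FALSE,
                              covariates = NULL, exclude_groups = NULL,
                              mlp_cap = 300) {
  stopifnot(inherits(cohort, "snp_cohort"))
  keep <- rep(TRUE, nrow(cohort$genotypes))
  if (!is.null(exclude_groups) && length(exclude_groups)) {
    if (is.null(cohort$groups))
      stop("'exclude_groups' given but the cohort carries no group labels")
    keep <- !(as.character(cohort$groups) %in% as.character(exclude_groups))
  }
  g <- cohort$genotypes[keep, snp]
  y <- cohort$phenotypes[keep]
  p_hat <- mean(g) / 2

  flagged <- function() {
    structure(list(snp = snp, method = "individual_ls", alpha = NA_real_,
                   mlp = NA_real_, pvalue = NA_real_, slope_b = NA_real_,
                   se_b = NA_real_, se_alpha = NA_real_,
                   residual_variance = NA_real_, p_hat = p_hat,
                   sigma2 = stats::var(y), n_obs = sum(keep),
                   converged = FALSE,
                   excluded_groups = as.character(exclude_groups %||% character(0))),
              class = "snp_effect_estimate")
  }
  if (stats::var(g) == 0) return(flagged())

  X <- matrix(1, nrow = sum(keep), ncol = 1,
              dimnames = list(NULL, "(Intercept)"))
  if (fit_groups) {
    if (is.null(cohort$groups))
      stop("'fit_groups = TRUE' but the cohort carries no group labels")
    gr <- droplevels(factor(cohort$groups[keep]))
    if (nlevels(gr) > 1L)
      X <- cbind(X, stats::model.matrix(~gr)[, -1L, drop = FALSE])
  }
  if (!is.null(covariates))
    X <- cbind(X, as.matrix(covariates)[keep, , drop = FALSE])

  fit <- .ols_target(g, X, y)
  if (is.null(fit)) return(flagged())
  mlp <- .mlp_from_logp(fit$log_pvalue, cap = mlp_cap)

  structure(list(snp = snp, method = "individual_ls", alpha = fit$coef,
                 mlp = mlp, pvalue = max(exp(fit$log_pvalue), 10^(-mlp_cap)),
                 slope_b = NA_real_, se_b = NA_real_, se_alpha = fit$se,
                 residual_variance = fit$residual_variance, p_hat = p_hat,
                 sigma2 = stats::var(y), n_obs = sum(keep), converged = TRUE,
                 excluded_groups = as.character(exclude_groups %||% character(0))),
            class = "snp_effect_estimate")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
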