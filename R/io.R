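# File formats and the whole-genome scan driver.  Genotypes come in as
# dosage tables (CSV, individuals x SNPs) or PLINK .raw exports; all
# outputs are plain TSV.

#' Read a genotype dosage matrix
#'
#' Two dialects are supported.  \code{"csv"}: comma-separated, header row
#' of SNP ids, one row per individual, values 0/1/2; an optional leading
#' \code{id} (or \code{IID}) column supplies individual ids.
#' \code{"raw"}: the PLINK \code{--recode A} dialect -- whitespace-
#' separated with columns \code{FID IID PAT MAT SEX PHENOTYPE} followed by
#' one dosage column per SNP (conventionally named \code{SNP_A} for
#' counted allele A).  \code{"auto"} picks by file extension.
#'
#' @param path Input file.
#' @param dialect \code{"auto"}, \code{"csv"} or \code{"raw"}.
#' @return Integer dosage matrix with individual ids as rownames and SNP
#'   ids as colnames.  Values outside {0, 1, 2, NA} are rejected.
#' @export
read_genotypes <- function(path, dialect = c("auto", "csv", "raw")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.raw$", path, ignore.case = TRUE)) "raw" else "csv"
  if (dialect == "raw") {
    tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                             check.names = FALSE)
    need <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(need %in% names(tab)[seq_len(6)]))
      stop("malformed .raw header: expected FID IID PAT MAT SEX PHENOTYPE")
    ids <- as.character(tab$IID)
    geno <- as.matrix(tab[, -(1:6), drop = FALSE])
  } else {
    tab <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
    idcol <- which(tolower(names(tab)) %in% c("id", "iid"))[1]
    if (!is.na(idcol)) {
      ids <- as.character(tab[[idcol]])
      geno <- as.matrix(tab[, -idcol, drop = FALSE])
    } else {
      ids <- paste0("ind", seq_len(nrow(tab)))
      geno <- as.matrix(tab)
    }
  }
  if (!is.numeric(geno))
    stop("non-numeric dosage values in ", path)
  bad <- !(geno %in% c(0, 1, 2)) & !is.na(geno)
  if (any(bad))
    stop("dosage values outside {0, 1, 2, NA} in ", path)
  if (anyDuplicated(ids)) stop("duplicated individual ids in ", path)
  if (anyDuplicated(colnames(geno))) stop("duplicated SNP ids in ", path)
  storage.mode(geno) <- "integer"
  rownames(geno) <- ids
  geno
}

#' Write a genotype dosage matrix as CSV
#'
#' Inverse of [read_genotypes()] (CSV dialect, with an \code{id} column).
#'
#' @param genotypes Dosage matrix with rownames / colnames.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_genotypes <- function(genotypes, path) {
  tab <- data.frame(id = rownames(genotypes), genotypes,
                    check.names = FALSE)
  utils::write.csv(tab, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype / contemporary-group table
#'
#' Tab- or comma-separated with a header; must contain columns \code{id}
#' and \code{phenotype}, optionally \code{group} and \code{breed}.
#'
#' @param path Input file.
#' @return A data frame with those columns.
#' @export
read_phenotypes <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("id", "phenotype") %in% names(tab)))
    stop("phenotype table must contain columns 'id' and 'phenotype'")
  tab
}

#' Assemble a cohort from genotype and phenotype files
#'
#' @param genotype_file Passed to [read_genotypes()].
#' @param phenotype_file Passed to [read_phenotypes()]; rows are matched
#'   to genotype rows by id.
#' @param dialect Genotype dialect.
#' @return A [snp_cohort()].
#' @export
read_cohort <- function(genotype_file, phenotype_file,
                        dialect = c("auto", "csv", "raw")) {
  geno <- read_genotypes(genotype_file, dialect)
  ph <- read_phenotypes(phenotype_file)
  idx <- match(rownames(geno), as.character(ph$id))
  if (any(is.na(idx)))
    stop("phenotype records missing for some genotyped individuals")
  snp_cohort(geno, ph$phenotype[idx],
             groups = if ("group" %in% names(ph)) ph$group[idx] else NULL,
             breed = if ("breed" %in% names(ph)) ph$breed[idx] else NULL)
}

#' Write a per-SNP results table as TSV
#'
#' @param results Data frame (e.g. from [run_scan()]).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Whole-genome scan of pooled SNP effects
#'
#' Orchestrates the pipeline on an individual-level cohort: rank-based
#' pooling (within contemporary groups by default), optional frequency
#' perturbation, per-SNP group-MAF filtering, genomic correlation matrix
#' and leading eigenvectors, then a per-SNP pooled logistic fit -- plus,
#' optionally, the individual least-squares reference.  Deterministic
#' given \code{seed}.
#'
#' @param cohort A [snp_cohort()].
#' @param n_pools Number of pools.
#' @param mode \code{"concurrent"}: fit contemporary groups and
#'   eigenvectors alongside the SNP; \code{"preadjust"}: pre-adjust
#'   phenotypes for group before pooling within groups.
#' @param n_eigenvectors Leading eigenvectors fitted as covariates
#'   (0 = none).
#' @param group_maf_exclude Within-group MAF threshold below which a
#'   group's pools are dropped for that SNP (concurrent mode).
#' @param freq_error_sd SD of Gaussian pool-frequency measurement error.
#' @param seed Optional seed applied before any randomness.
#' @param ls_reference Also run the individual least-squares scan?
#' @return A list of class \code{"poolfx_scan"}: \code{results} (per-SNP
#'   data frame with columns \code{snp_id}, \code{method}, \code{alpha},
#'   \code{se}, \code{pvalue}, \code{mlp}, \code{p_hat}, \code{n_used},
#'   \code{n_excluded_groups}, \code{converged}), \code{pools},
#'   \code{gcm}, \code{eigenbasis}, \code{group_filter}.
#' @export
run_scan <- function(cohort, n_pools, mode = c("concurrent", "preadjust"),
                     n_eigenvectors = 5, group_maf_exclude = 0.01,
                     freq_error_sd = 0, seed = NULL, ls_reference = TRUE) {
  stopifnot(inherits(cohort, "snp_cohort"))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  has_groups <- !is.null(cohort$groups)
  if (mode == "preadjust" && !has_groups)
    stop("pre-adjustment requires contemporary-group labels")

  y <- cohort$phenotypes
  if (mode == "preadjust") y <- preadjust_phenotypes(y, cohort$groups)
  pools <- make_pools(cohort, n_pools, within_group = has_groups,
                      freq_error_sd = freq_error_sd, phenotypes = y)
  gcm <- genomic_correlation_from_pools(pools$freq, pools$sizes)
  basis <- if (n_eigenvectors > 0)
    leading_eigenvectors(gcm, n_eigenvectors) else NULL
  ev <- if (is.null(basis)) NULL else basis$vectors
  report <- if (has_groups && mode == "concurrent")
    filter_groups_by_maf(pools, group_maf_exclude) else NULL

  # sigma2 for the back-transformation: variance after removing the group
  # effects the model accounts for (concurrent mode fits them; preadjust
  # mode already removed them from y)
  sigma2 <- if (mode == "concurrent" && has_groups)
    stats::var(preadjust_phenotypes(y, cohort$groups)) else stats::var(y)
  m <- ncol(cohort$genotypes)
  rows <- vector("list", m * (1L + ls_reference))
  for (j in seq_len(m)) {
    excl <- if (is.null(report)) NULL else excluded_groups(report, j)
    est <- tryCatch(
      estimate_pooled_snp_effect(pools, j, sigma2 = sigma2,
                                 fit_groups = has_groups && mode == "concurrent",
                                 eigenvectors = ev, exclude_groups = excl),
      error = function(e) NULL)
    rows[[j]] <- data.frame(
      snp_id = cohort$snp_ids[j], method = "pooled_lr",
      alpha = if (is.null(est)) NA_real_ else est$alpha,
      se = if (is.null(est)) NA_real_ else est$se_b,
      pvalue = if (is.null(est)) NA_real_ else est$pvalue,
      mlp = if (is.null(est)) NA_real_ else est$mlp,
      p_hat = if (is.null(est)) NA_real_ else est$p_hat,
      n_used = if (is.null(est)) 0L else est$n_obs,
      n_excluded_groups = length(excl),
      converged = !is.null(est) && isTRUE(est$converged))
  }
  if (ls_reference) {
    for (j in seq_len(m)) {
      excl <- if (is.null(report)) NULL else excluded_groups(report, j)
      est <- tryCatch(
        fit_individual_ls(cohort, j, fit_groups = has_groups,
                          exclude_groups = excl),
        error = function(e) NULL)
      rows[[m + j]] <- data.frame(
        snp_id = cohort$snp_ids[j], method = "individual_ls",
        alpha = if (is.null(est)) NA_real_ else est$alpha,
        se = if (is.null(est)) NA_real_ else est$se_alpha,
        pvalue = if (is.null(est)) NA_real_ else est$pvalue,
        mlp = if (is.null(est)) NA_real_ else est$mlp,
        p_hat = if (is.null(est)) NA_real_ else est$p_hat,
        n_used = if (is.null(est)) 0L else est$n_obs,
        n_excluded_groups = length(excl),
        converged = !is.null(est) && isTRUE(est$converged))
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results, pools = pools, gcm = gcm,
                 eigenbasis = basis, group_filter = report,
                 mode = mode, n_pools = n_pools),
            class = "poolfx_scan")
}

#' @export
print.poolfx_scan <- function(x, ...) {
  pl <- x$results[x$results$method == "pooled_lr", ]
  cat(sprintf("poolfx_scan [%s]: %d SNPs at %d pools; %d converged; top MLP %.2f\n",
              x$mode, nrow(pl), x$n_pools, sum(pl$converged),
              suppressWarnings(max(pl$mlp, na.rm = TRUE))))
  invisible(x)
}
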