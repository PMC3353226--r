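# Individual-level container: genotype dosages, phenotypes and
# contemporary-group labels -- the un-pooled ground truth.

#' Construct an individual-level cohort
#'
#' @param genotypes Integer matrix of allele dosages (individuals x SNPs),
#'   values in {0, 1, 2}; missing dosages are not allowed (filter or impute
#'   upstream).
#' @param phenotypes Numeric vector, one trait record per individual.
#' @param groups Optional contemporary-group labels (coerced to factor).
#' @param breed Optional breed/population labels (coerced to factor).
#' @param ids Optional individual identifiers; defaults to rownames of
#'   \code{genotypes} or \code{ind1..indN}.
#' @param snp_ids Optional SNP identifiers; defaults to colnames or
#'   \code{snp1..snpM}.
#' @return An object of class \code{"snp_cohort"}.
#' @export
snp_cohort <- function(genotypes, phenotypes, groups = NULL, breed = NULL,
                       ids = NULL, snp_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  n <- nrow(genotypes)
  if (length(phenotypes) != n)
    stop("'phenotypes' must have one entry per row of 'genotypes'")
  if (any(is.na(genotypes)))
    stop("missing genotype dosages are not supported; filter SNPs upstream")
  if (!all(genotypes %in% c(0, 1, 2)))
    stop("genotype dosages must be 0, 1 or 2")
  if (is.null(ids)) ids <- rownames(genotypes)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))
  if (is.null(snp_ids)) snp_ids <- colnames(genotypes)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(genotypes)))
  if (anyDuplicated(ids)) stop("duplicated individual ids")
  if (anyDuplicated(snp_ids)) stop("duplicated SNP ids")
  dimnames(genotypes) <- list(ids, snp_ids)
  if (!is.null(groups)) {
    if (length(groups) != n) stop("'groups' must have one entry per individual")
    groups <- factor(groups)
  }
  if (!is.null(breed)) {
    if (length(breed) != n) stop("'breed' must have one entry per individual")
    breed <- factor(breed)
  }
  structure(list(genotypes = genotypes, phenotypes = as.numeric(phenotypes),
                 groups = groups, breed = breed, ids = ids,
                 snp_ids = snp_ids),
            class = "snp_cohort")
}

#' @export
print.snp_cohort <- function(x, ...) {
  cat(sprintf("snp_cohort: %d individuals x %d SNPs", nrow(x$genotypes),
              ncol(x$genotypes)))
  if (!is.null(x$groups)) cat(sprintf(", %d groups", nlevels(x$groups)))
  if (!is.null(x$breed)) cat(sprintf(", %d breeds", nlevels(x$breed)))
  cat("\n")
  invisible(x)
}

#' Allele frequency of the counted allele, per SNP
#'
#' @param cohort A [snp_cohort()].
#' @return Numeric vector of cohort-wide allele frequencies
#'   (mean dosage / 2).
#' @export
cohort_allele_freq <- function(cohort) {
  stopifnot(inherits(cohort, "snp_cohort"))
  colMeans(cohort$genotypes) / 2
}
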