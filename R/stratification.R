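# Population-stratification correction for pooled data: a genomic
# correlation matrix built from pool allele frequencies (VanRaden's first
# method, with pool frequencies standing in for individual dosages) and its
# leading eigenvectors, used as covariates in the per-SNP fits.

#' Genomic correlation matrix from pool allele frequencies
#'
#' Maps each pool frequency to an expected dosage \code{2f}, centres by
#' twice the size-weighted mean frequency per SNP, and forms
#' \deqn{G = M M' / (2 \sum_j \bar p_j (1 - \bar p_j)),}
#' VanRaden's first relationship-matrix construction with real-valued pool
#' frequencies in place of integer genotypes.  The returned matrix is
#' \code{G} rescaled to a correlation (entry \code{ij} divided by
#' \code{sqrt(G_ii G_jj)}).  SNPs with no variance across pools contribute
#' nothing and are dropped from the numerator and denominator.
#'
#' With singleton pools (\code{f = dosage / 2}) the relationship matrix
#' \code{G} reduces exactly to VanRaden's method on individual genotypes.
#'
#' @param freq Pools-by-SNPs allele-frequency matrix.
#' @param pool_sizes Integer vector of pool sizes (weights for the mean
#'   frequency).
#' @return An object of class \code{"genomic_correlation"}: list with
#'   \code{matrix} (pools x pools correlation), \code{relationship} (the
#'   unscaled \code{G}), \code{pool_ids}, \code{n_snps_used} and
#'   \code{degenerate} (pools with zero diagonal, flagged, their
#'   correlations set to 0).
#' @export
genomic_correlation_from_pools <- function(freq, pool_sizes) {
  freq <- as.matrix(freq)
  k <- nrow(freq)
  if (k < 2L) stop("at least two pools are required")
  if (length(pool_sizes) != k)
    stop("'pool_sizes' must have one entry per pool")
  if (any(!is.finite(freq))) stop("non-finite frequencies")

  w <- pool_sizes / sum(pool_sizes)
  pbar <- as.numeric(crossprod(w, freq))          # size-weighted mean per SNP
  varying <- apply(freq, 2L, function(col) diff(range(col)) > 0)
  poly <- pbar > 0 & pbar < 1
  use <- varying & poly
  if (!any(use))
    stop("all SNPs are monomorphic across pools; cannot build a genomic ",
         "correlation matrix")

  M <- sweep(2 * freq[, use, drop = FALSE], 2L, 2 * pbar[use])
  denom <- 2 * sum(pbar[use] * (1 - pbar[use]))
  G <- tcrossprod(M) / denom

  d <- diag(G)
  degenerate <- which(d <= .Machine$double.eps)
  dd <- d
  dd[degenerate] <- 1                             # avoid 0/0; flagged below
  C <- G / sqrt(outer(dd, dd))
  if (length(degenerate)) {
    C[degenerate, ] <- 0
    C[, degenerate] <- 0
    diag(C)[degenerate] <- 1
  }
  C <- (C + t(C)) / 2                             # enforce exact symmetry
  ids <- rownames(freq)
  if (is.null(ids)) ids <- paste0("pool", seq_len(k))
  dimnames(C) <- dimnames(G) <- list(ids, ids)

  structure(list(matrix = C, relationship = G, pool_ids = ids,
                 n_snps_used = sum(use), degenerate = degenerate),
            class = "genomic_correlation")
}

#' @export
print.genomic_correlation <- function(x, ...) {
  cat(sprintf("genomic_correlation: %d pools, %d SNPs used%s\n",
              nrow(x$matrix), x$n_snps_used,
              if (length(x$degenerate))
                sprintf(" (%d degenerate pools)", length(x$degenerate))
              else ""))
  invisible(x)
}

#' Leading eigenvectors of a genomic correlation matrix
#'
#' Top-k eigenpairs of the symmetric correlation matrix, eigenvalues in
#' descending order.  The sign of each eigenvector is fixed so that its
#' largest-magnitude loading is positive; downstream regressions are
#' sign-invariant but serialised outputs stay reproducible.
#'
#' @param gcm A [genomic_correlation_from_pools()] result, or a plain
#'   symmetric matrix.
#' @param k Number of leading eigenvectors (default 5, always fitted
#'   regardless of significance).
#' @return An object of class \code{"eigen_basis"}: list with
#'   \code{vectors} (pools x k, orthonormal columns), \code{values}
#'   (descending) and \code{pool_ids}.
#' @export
leading_eigenvectors <- function(gcm, k = 5) {
  A <- if (inherits(gcm, "genomic_correlation")) gcm$matrix else as.matrix(gcm)
  if (any(!is.finite(A))) stop("non-finite entries in the matrix")
  if (k >= nrow(A)) stop("'k' must be smaller than the number of pools")
  if (max(abs(A - t(A))) > 1e-8) stop("matrix is not symmetric")
  es <- eigen(A, symmetric = TRUE)
  vec <- es$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  ids <- rownames(A)
  if (is.null(ids)) ids <- paste0("pool", seq_len(nrow(A)))
  rownames(vec) <- ids
  colnames(vec) <- paste0("ev", seq_len(k))
  structure(list(vectors = vec, values = es$values[seq_len(k)],
                 pool_ids = ids),
            class = "eigen_basis")
}

#' @export
print.eigen_basis <- function(x, ...) {
  cat(sprintf("eigen_basis: %d pools x %d eigenvectors; eigenvalues %s\n",
              nrow(x$vectors), ncol(x$vectors),
              paste(signif(x$values, 4), collapse = ", ")))
  invisible(x)
}

#' Serialise a genomic correlation matrix / eigenbasis to TSV
#'
#' @param gcm A [genomic_correlation_from_pools()] result.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_gcm <- function(gcm, path) {
  stopifnot(inherits(gcm, "genomic_correlation"))
  tab <- data.frame(pool_id = gcm$pool_ids, gcm$matrix,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gcm
#' @param basis An [leading_eigenvectors()] result.
#' @export
write_eigenbasis <- function(basis, path) {
  stopifnot(inherits(basis, "eigen_basis"))
  tab <- data.frame(pool_id = basis$pool_ids, basis$vectors,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
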