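#' Genetic relationship matrix from standardised genotypes
#'
#' `GRM = Z Z' / M` over standardised genotype columns
#' `z = (g - 2f) / sqrt(2 f (1 - f))`; monomorphic SNPs are skipped. The
#' leave-one-chromosome-out (LOCO) variant excludes the named chromosome, so
#' that the relatedness correction for a tested SNP does not absorb the SNP's
#' own chromosome (proximal contamination).
#'
#' @param cohort A `cohort`.
#' @param loco_chrom Optional chromosome label to exclude.
#' @return A `grm` object: list with `matrix` (N x N), `n_snps_used`,
#'   `loco_chrom`.
#' @export
compute_grm <- function(cohort, loco_chrom = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  use <- seq_len(ncol(cohort$genotypes))
  if (!is.null(loco_chrom)) {
    use <- use[cohort$map$chrom[use] != as.character(loco_chrom)]
  }
  g <- cohort$genotypes[, use, drop = FALSE]
  f <- colMeans(g) / 2
  poly <- f > 0 & f < 1
  if (sum(poly) < 2) abort("need >= 2 polymorphic SNPs outside the excluded chromosome")
  g <- g[, poly, drop = FALSE]
  f <- f[poly]
  z <- sweep(g, 2L, 2 * f, "-")
  z <- sweep(z, 2L, sqrt(2 * f * (1 - f)), "/")
  structure(list(matrix = tcrossprod(z) / ncol(z), n_snps_used = ncol(z),
                 loco_chrom = loco_chrom),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("<grm> ", nrow(x$matrix), " x ", ncol(x$matrix), " from ",
      x$n_snps_used, " SNPs",
      if (!is.null(x$loco_chrom)) paste0(" (LOCO: chr ", x$loco_chrom, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Principal components of a GRM (or of standardised genotypes)
#'
#' Top-`k` eigenvectors of the genetic relationship matrix; eigenvalues are
#' non-increasing and the principal-component coordinates orthonormal.
#'
#' @param x A `grm` or a `cohort` (a GRM is computed first).
#' @param k Number of components (`k < N`).
#' @return List: `scores` (N x k orthonormal), `eigenvalues` (length k).
#' @export
grm_pca <- function(x, k = 10) {
  if (inherits(x, "cohort")) x <- compute_grm(x)
  stopifnot(inherits(x, "grm"))
  n <- nrow(x$matrix)
  if (k >= n) abort("k must be smaller than the number of individuals")
  e <- eigen(x$matrix, symmetric = TRUE)
  list(scores = e$vectors[, seq_len(k), drop = FALSE],
       eigenvalues = e$values[seq_len(k)])
}
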