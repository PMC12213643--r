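#' Supervised global-ancestry estimation
#'
#' Estimates each individual's ancestry proportion vector `q` on the
#' K-simplex by maximising the binomial log-likelihood
#' `sum_m [g log(q'f_m) + (2 - g) log(1 - q'f_m)]` with the parental
#' allele frequencies `f` held fixed (the supervised analysis mode of
#' model-based ancestry estimation). Optimisation is by EM; convergence is
#' declared when the mean per-individual log-likelihood gain drops below
#' `tol`.
#'
#' If two parental populations have (numerically) identical frequency
#' vectors the likelihood is flat between them; the result is then flagged
#' `unidentifiable` rather than returned as an arbitrary confident estimate.
#'
#' @param genotypes N x M genotype matrix (alt-allele counts 0/1/2), or a
#'   `cohort`.
#' @param panel_freqs K x M matrix of parental alt-allele frequencies
#'   (clipped away from 0/1 internally).
#' @param tol Convergence tolerance on the log-likelihood gain
#'   (default 1e-6).
#' @param max_iter Maximum EM iterations.
#' @return List of class `ancestry_estimate`: `proportions` (N x K, rows sum
#'   to 1), `loglik`, `n_iter`, `converged`, `flag` (`NA` or
#'   `"unidentifiable"`).
#' @export
supervised_global_ancestry <- function(genotypes, panel_freqs, tol = 1e-6,
                                       max_iter = 1000L) {
  if (inherits(genotypes, "cohort")) genotypes <- genotypes$genotypes
  g <- as.matrix(genotypes)
  f <- as.matrix(panel_freqs)
  k <- nrow(f)
  if (k < 2) abort("need K >= 2 parental populations")
  if (ncol(f) != ncol(g)) abort("non-overlapping variant sets: frequency columns must match genotypes")
  f <- pmin(pmax(f, 1e-4), 1 - 1e-4)
  flag <- NA_character_
  for (a in seq_len(k - 1L)) {
    for (b in seq(a + 1L, k)) {
      if (max(abs(f[a, ] - f[b, ])) < 1e-8) flag <- "unidentifiable"
    }
  }
  n <- nrow(g)
  q <- matrix(1 / k, nrow = n, ncol = k)
  tf <- t(f); tf1 <- 1 - tf # M x K
  g2 <- 2 - g
  ll_of <- function(q) {
    p <- q %*% f # N x M expected allele frequency
    sum(g * log(p) + g2 * log(1 - p))
  }
  ll_old <- ll_of(q)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    p <- q %*% f
    # E-step: expected ancestry-of-origin counts per individual
    a_alt <- (g / p) %*% tf   # weight of f_k in the alt-allele term
    a_ref <- (g2 / (1 - p)) %*% tf1
    q <- q * (a_alt + a_ref) / (2 * ncol(g))
    q <- q / rowSums(q)
    ll <- ll_of(q)
    if ((ll - ll_old) / n < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  structure(list(proportions = q, loglik = ll_old, n_iter = it,
                 converged = converged, flag = flag),
            class = "ancestry_estimate")
}

#' @export
print.ancestry_estimate <- function(x, ...) {
  cat("<ancestry_estimate> ", nrow(x$proportions), " individuals x ",
      ncol(x$proportions), " ancestries; loglik = ", format(x$loglik),
      if (!is.na(x$flag)) paste0(" [", x$flag, "]"), "\n", sep = "")
  invisible(x)
}
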