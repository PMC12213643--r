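#' Linear mixed-model association (EMMAX-style two-step)
#'
#' The binary phenotype is modelled on the observed 0/1 scale as
#' `y = X b + g beta + u + e`, `u ~ N(0, sg2 K)`, `e ~ N(0, se2 I)` with `K`
#' the genetic relationship matrix. Step 1 estimates the variance ratio
#' `delta = se2 / sg2` by REML on the null model (no SNP), using the
#' eigendecomposition of `K` and one-dimensional optimisation of the
#' restricted log-likelihood over `log delta` in `[-10, 10]`. Step 2 performs
#' per-SNP generalised-least-squares Wald tests with the correlation
#' structure held fixed at the null-model `delta` (the residual scale is
#' re-estimated per SNP, so with an identity GRM the test reduces exactly to
#' ordinary least squares).
#'
#' In `mode = "loco"` the GRM excluding each tested SNP's chromosome is used
#' (variance components re-estimated per chromosome).
#'
#' @param cohort A `cohort`.
#' @param grm Optional precomputed [compute_grm()] result (ignored in loco
#'   mode).
#' @param mode `"all"` (GRM over all chromosomes) or `"loco"`.
#' @param covariates Optional covariate matrix.
#' @return An `assoc_result`; attributes `delta` and `h2` record the
#'   null-model variance-ratio estimate(s).
#' @export
lmm_assoc <- function(cohort, grm = NULL, mode = c("all", "loco"),
                      covariates = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  mode <- match.arg(mode)
  y <- as.numeric(cohort$phenotype)
  covar <- check_covariates(covariates, length(y))
  out <- assoc_skeleton(cohort)
  deltas <- list()
  if (mode == "all") {
    if (is.null(grm)) grm <- compute_grm(cohort)
    check_grm(grm, length(y))
    fit <- lmm_chrom_fit(cohort, grm, y, covar, seq_len(ncol(cohort$genotypes)))
    out <- fill_lmm(out, fit)
    deltas$all <- fit$delta
  } else {
    for (ch in unique(cohort$map$chrom)) {
      grm_ch <- compute_grm(cohort, loco_chrom = ch)
      sites <- which(cohort$map$chrom == ch)
      fit <- lmm_chrom_fit(cohort, grm_ch, y, covar, sites)
      out <- fill_lmm(out, fit)
      deltas[[ch]] <- fit$delta
    }
  }
  res <- new_assoc_result(out, if (mode == "all") "lmm" else "lmm_loco")
  attr(res, "delta") <- unlist(deltas)
  attr(res, "h2") <- 1 / (1 + unlist(deltas))
  res
}

check_grm <- function(grm, n) {
  stopifnot(inherits(grm, "grm"))
  k <- grm$matrix
  if (nrow(k) != n) abort("GRM dimension does not match the cohort")
  if (max(abs(k - t(k))) > 1e-10) abort("GRM is not symmetric")
  invisible(grm)
}

# REML restricted log-likelihood for the null model at variance ratio delta,
# on the rotated scale. X: n x p fixed-effect design (rotated), yr: rotated y,
# d: GRM eigenvalues.
reml_ll <- function(log_delta, yr, Xr, d) {
  delta <- exp(log_delta)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xr * w, Xr)
  XtWy <- crossprod(Xr * w, yr)
  bh <- solve(XtWX, XtWy)
  r <- yr - Xr %*% bh
  n <- length(yr); p <- ncol(Xr)
  rss <- sum(w * r^2)
  # restricted likelihood profiled over the scale sg2
  -0.5 * ((n - p) * log(rss) - sum(log(w)) + determinant(XtWX)$modulus)
}

lmm_chrom_fit <- function(cohort, grm, y, covar, sites) {
  e <- eigen(grm$matrix, symmetric = TRUE)
  if (min(e$values) < -1e-6 * max(abs(e$values)) - 1e-8) {
    abort("GRM is not positive semi-definite within tolerance")
  }
  d <- pmax(e$values, 0)
  U <- e$vectors
  X <- cbind(rep(1, length(y)), covar)
  Xr <- crossprod(U, X)
  yr <- as.numeric(crossprod(U, y))
  opt <- optimize(function(ld) reml_ll(ld, yr, Xr, d),
                  interval = c(-10, 10), maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  w <- 1 / (d + delta)
  # residualise rotated y against rotated covariates under the GLS weights
  sw <- sqrt(w)
  Xw <- Xr * sw
  yw <- yr * sw
  qrX <- qr(Xw)
  y_res <- qr.resid(qrX, yw)
  g <- cohort$genotypes[, sites, drop = FALSE]
  gr <- crossprod(U, g) * sw
  g_res <- qr.resid(qrX, gr)
  sxx <- colSums(g_res^2)
  sxy <- as.numeric(crossprod(g_res, y_res))
  df <- length(y) - ncol(Xw) - 1L
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  rss <- pmax(sum(y_res^2) - ifelse(sxx > 0, sxy^2 / sxx, 0), 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / sxx)
  tval <- beta / se
  list(sites = sites, beta = beta, se = se, stat = tval^2,
       p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
       mono = sxx <= 1e-12, delta = delta)
}

fill_lmm <- function(out, fit) {
  s <- fit$sites
  out$beta[s] <- fit$beta
  out$se[s] <- fit$se
  out$stat[s] <- fit$stat
  out$p[s] <- fit$p
  out$qc_flag[s][fit$mono] <- "monomorphic"
  out$beta[s][fit$mono] <- NA_real_
  out$se[s][fit$mono] <- NA_real_
  out$stat[s][fit$mono] <- NA_real_
  out$p[s][fit$mono] <- NA_real_
  out
}
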