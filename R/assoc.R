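# Shared construction of per-SNP association result tables. Every test fills
# the same fixed column set so results diff cleanly and serialise to one
# summary-statistics TSV schema.

P_FLOOR <- 1e-300

assoc_skeleton <- function(cohort) {
  g <- cohort$genotypes
  f <- colMeans(g, na.rm = TRUE) / 2
  tibble::tibble(
    id = cohort$map$id, chrom = cohort$map$chrom, pos = cohort$map$pos_bp,
    a1 = cohort$map$alt, maf = pmin(f, 1 - f),
    beta = NA_real_, se = NA_real_, stat = NA_real_, p = NA_real_,
    log_bf = NA_real_, ppa = NA_real_,
    n = as.integer(colSums(!is.na(g))), qc_flag = NA_character_)
}

new_assoc_result <- function(df, test_name) {
  df$p <- pmax(df$p, P_FLOOR)
  attr(df, "test_name") <- test_name
  class(df) <- c("assoc_result", class(tibble::tibble()))
  df
}

#' @export
print.assoc_result <- function(x, ...) {
  cat("<assoc_result> test = ", attr(x, "test_name"), "; ", nrow(x),
      " SNPs\n", sep = "")
  NextMethod()
}

#' Cochran-Armitage trend test
#'
#' Per-SNP 1-df chi-square trend test of the binary phenotype on additive
#' genotype scores (0, 1, 2); the statistic equals `N` times the squared
#' Pearson correlation of genotype and phenotype. Monomorphic SNPs are
#' flagged, not scored. This is the basic allelic-trend analysis offered by
#' standard GWAS toolkits.
#'
#' @param cohort A `cohort` with binary phenotype.
#' @return An `assoc_result` tibble.
#' @export
trend_assoc <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  y <- cohort$phenotype
  if (!all(y %in% 0:1)) abort("phenotype must be binary 0/1")
  g <- cohort$genotypes
  out <- assoc_skeleton(cohort)
  n <- nrow(g)
  gc_ <- scale(g, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxy <- as.numeric(crossprod(gc_, yc)) / n
  sxx <- colMeans(gc_^2)
  syy <- mean(yc^2)
  mono <- sxx == 0
  r2 <- ifelse(mono, NA_real_, sxy^2 / (sxx * syy))
  out$stat <- n * r2
  out$p <- pchisq(out$stat, df = 1, lower.tail = FALSE)
  out$beta <- ifelse(mono, NA_real_, sxy / sxx)
  out$qc_flag[mono] <- "monomorphic"
  new_assoc_result(out, "trend")
}

# Per-SNP logistic ML fit; returns beta, se, converged for the genotype
# column given a fixed covariate block (intercept included).
logistic_fit_one <- function(y, x, covar) {
  X <- cbind(1, covar, x)
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    return(list(beta = NA_real_, se = NA_real_, ok = FALSE, fit = NULL))
  }
  j <- ncol(X)
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(cov)) return(list(beta = NA_real_, se = NA_real_, ok = FALSE, fit = fit))
  beta <- fit$coefficients[j]
  se <- sqrt(cov[j, j])
  # quasi-separation: absurd coefficient scale means the Wald test is void
  ok <- is.finite(beta) && is.finite(se) && abs(beta) < 15 && se < 100
  list(beta = unname(beta), se = unname(se), ok = ok, fit = fit)
}

#' Logistic association test with covariates
#'
#' Per-SNP maximum-likelihood logistic regression of case status on the
#' additive genotype coding plus covariates (e.g. principal components), with
#' a Wald test on the genotype coefficient. SNPs whose fit does not converge
#' (e.g. separation) are flagged `non_converged` and receive no p-value.
#'
#' @param cohort A `cohort`.
#' @param covariates Optional N x C numeric covariate matrix (an intercept is
#'   always added; the block must be full rank with it).
#' @return An `assoc_result` tibble.
#' @export
logistic_assoc <- function(cohort, covariates = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  y <- cohort$phenotype
  covar <- check_covariates(covariates, length(y))
  g <- cohort$genotypes
  out <- assoc_skeleton(cohort)
  for (j in seq_len(ncol(g))) {
    x <- g[, j]
    if (length(unique(x)) < 2L) {
      out$qc_flag[j] <- "monomorphic"
      next
    }
    r <- logistic_fit_one(y, x, covar)
    if (!r$ok) {
      out$qc_flag[j] <- "non_converged"
      next
    }
    out$beta[j] <- r$beta
    out$se[j] <- r$se
    out$stat[j] <- (r$beta / r$se)^2
    out$p[j] <- pchisq(out$stat[j], 1, lower.tail = FALSE)
  }
  new_assoc_result(out, "logistic")
}

check_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  covar <- as.matrix(covariates)
  if (nrow(covar) != n) abort("covariate rows must match the cohort")
  if (qr(cbind(1, covar))$rank < ncol(covar) + 1L) {
    abort("covariate matrix is rank deficient after adding an intercept")
  }
  covar
}

#' Bayesian association test (Laplace-approximation Bayes factors)
#'
#' Per-SNP Bayes factor of H1 (additive log-odds effect with a
#' Normal(0, prior_sd^2) prior) against H0 (no effect), computed by a Laplace
#' (asymptotic-normal) approximation around the logistic maximum-likelihood
#' estimate:
#' `log BF = 0.5 log(se^2 / (se^2 + sd^2)) + 0.5 z^2 sd^2 / (se^2 + sd^2)`.
#' Reported on the natural-log scale, so Jeffreys' decisive boundary
#' (BF = 100) sits at `log BF = log(100) ~ 4.61`.
#'
#' @param cohort A `cohort`.
#' @param covariates Optional covariate matrix.
#' @param prior_sd Prior standard deviation of the additive log-odds effect
#'   (default 0.2).
#' @return An `assoc_result` with `log_bf` filled (Wald p also reported).
#' @export
bayes_assoc <- function(cohort, covariates = NULL, prior_sd = 0.2) {
  if (prior_sd <= 0) abort("prior_sd must be > 0")
  res <- logistic_assoc(cohort, covariates)
  res$log_bf <- laplace_log_bf(res$beta, res$se, prior_sd)
  attr(res, "test_name") <- "bayes"
  res
}

# Asymptotic (Laplace) log Bayes factor from an estimate and its SE.
laplace_log_bf <- function(beta, se, prior_sd) {
  v <- se^2
  z2 <- (beta / se)^2
  0.5 * log(v / (v + prior_sd^2)) + 0.5 * z2 * prior_sd^2 / (v + prior_sd^2)
}
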