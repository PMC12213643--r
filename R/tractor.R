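#' Local-ancestry-aware joint association test
#'
#' Per SNP, the phased genotype is decomposed by ancestry of origin into
#' ancestry-specific alt-allele dosages `X_a` and local-ancestry haplotype
#' counts `L_a` (`a = 0..K-1`; `sum_a X_a` = genotype, `sum_a L_a = 2`). The
#' model `phenotype ~ sum_(a<K-1) theta_a L_a + sum_a beta_a X_a +
#' covariates` is fitted by logistic regression (the last ancestry's `L` is
#' dropped as the reference to avoid collinearity with the intercept), with a
#' joint likelihood-ratio test of all ancestry-specific allele effects
#' `beta_a` (K degrees of freedom) plus per-ancestry Wald tests. With a
#' single ancestry the decomposition is the genotype itself and the joint
#' test is exactly the standard logistic Wald test. Ancestry strata with fewer than
#' `min_stratum` haplotypes carrying variation are flagged
#' `untestable_in_stratum` (their dosage term is dropped) rather than failing
#' the whole SNP.
#'
#' @param cohort A `cohort` with phased haplotypes and local-ancestry truth.
#' @param covariates Optional covariate matrix.
#' @param min_stratum Minimum haplotype count (and dosage variation) required
#'   to test an ancestry stratum (default 10).
#' @return An `assoc_result`; `stat`/`p` hold the joint LRT. Per-ancestry
#'   effects are attached as attribute `per_ancestry` (tibble: id, ancestry,
#'   beta, se, p).
#' @export
tractor_assoc <- function(cohort, covariates = NULL, min_stratum = 10L) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$haplotypes) || is.null(cohort$la)) {
    abort("local-ancestry-aware test needs phased haplotypes and ancestry labels")
  }
  y <- cohort$phenotype
  covar <- check_covariates(covariates, length(y))
  k <- cohort$la$n_pops
  h <- cohort$haplotypes
  anc <- cohort$la$assignments
  odd <- seq(1L, nrow(h), by = 2L)
  out <- assoc_skeleton(cohort)
  per_anc <- vector("list", ncol(h))
  ref_anc <- k - 1L
  for (j in seq_len(ncol(h))) {
    a1 <- anc[odd, j]; a2 <- anc[odd + 1L, j]
    g1 <- h[odd, j]; g2 <- h[odd + 1L, j]
    L <- matrix(0L, nrow = length(odd), ncol = k)
    X <- matrix(0L, nrow = length(odd), ncol = k)
    for (a in seq_len(k) - 1L) {
      L[, a + 1L] <- (a1 == a) + (a2 == a)
      X[, a + 1L] <- g1 * (a1 == a) + g2 * (a2 == a)
    }
    hap_n <- colSums(L)
    testable <- hap_n >= min_stratum & apply(X, 2, function(x) length(unique(x)) > 1L)
    if (!any(testable)) {
      out$qc_flag[j] <- "untestable_all_strata"
      next
    }
    flags <- if (!all(testable)) {
      paste0("untestable_in_stratum:",
             paste(which(!testable) - 1L, collapse = ","))
    } else NA_character_
    L_terms <- if (k > 1L) {
      Lk <- L[, setdiff(seq_len(k), ref_anc + 1L), drop = FALSE]
      Lk[, apply(Lk, 2, function(x) length(unique(x)) > 1L), drop = FALSE]
    } else NULL
    X_use <- X[, testable, drop = FALSE]
    X0 <- cbind(rep(1, length(y)), covar, L_terms)
    X1 <- cbind(X0, X_use)
    f1 <- tryCatch(suppressWarnings(glm.fit(X1, y, family = binomial())),
                   error = function(e) NULL)
    if (is.null(f1) || !f1$converged) {
      out$qc_flag[j] <- "non_converged"
      next
    }
    w <- f1$weights
    cov <- tryCatch(solve(crossprod(X1 * sqrt(w))), error = function(e) NULL)
    if (is.null(cov)) {
      out$qc_flag[j] <- "non_converged"
      next
    }
    idx <- seq(ncol(X0) + 1L, ncol(X1))
    bet <- f1$coefficients[idx]
    blk <- cov[idx, idx, drop = FALSE]
    if (k == 1L) {
      # degenerate single-ancestry case: the model is plain logistic
      # regression, so the joint test is exactly its Wald test
      stat <- tryCatch(as.numeric(t(bet) %*% solve(blk, bet)),
                       error = function(e) NA_real_)
    } else {
      # joint likelihood-ratio test of the ancestry-specific allele effects
      # (better calibrated than the Wald block in sparse ancestry strata)
      f0 <- tryCatch(suppressWarnings(glm.fit(X0, y, family = binomial())),
                     error = function(e) NULL)
      stat <- if (is.null(f0)) NA_real_ else
        max(0, f0$deviance - f1$deviance)
    }
    out$stat[j] <- stat
    out$p[j] <- pchisq(stat, df = length(idx), lower.tail = FALSE)
    out$qc_flag[j] <- flags
    ses <- suppressWarnings(sqrt(diag(blk))) # non-PD corner: stratum unstable
    ses[!is.finite(ses)] <- NA_real_
    per_anc[[j]] <- tibble::tibble(
      id = out$id[j], ancestry = which(testable) - 1L,
      beta = unname(bet), se = unname(ses),
      p = pmax(2 * pnorm(abs(bet / ses), lower.tail = FALSE), P_FLOOR))
    # headline effect: largest-|z| stratum
    zs <- abs(bet / ses)
    if (any(is.finite(zs))) {
      zi <- which.max(zs)
      out$beta[j] <- unname(bet[zi])
      out$se[j] <- unname(ses[zi])
    }
  }
  res <- new_assoc_result(out, "tractor")
  attr(res, "per_ancestry") <- dplyr::bind_rows(per_anc)
  attr(res, "reference_ancestry") <- ref_anc
  res
}

#' Admixture mapping: local-ancestry association
#'
#' Per locus, logistic regression of the phenotype on the local-ancestry
#' haplotype dosage `L_a` of the target ancestry, with the individual's
#' global proportion of that ancestry (computed from the truth tracts) as a
#' covariate. Reports the Wald p-value and a Laplace-approximation log Bayes
#' factor for use by [joint_ppa()].
#'
#' @param cohort A `cohort` with local-ancestry truth.
#' @param ancestry 0-based target ancestry index.
#' @param covariates Optional extra covariates (global ancestry is always
#'   included).
#' @param prior_sd Prior SD for the ancestry-dosage log-odds effect in the
#'   Bayes factor (default 0.2).
#' @return An `assoc_result` (one row per locus; `beta` is the log-odds per
#'   ancestry-`a` haplotype copy).
#' @export
admixture_mapping <- function(cohort, ancestry = 0L, covariates = NULL,
                              prior_sd = 0.2) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$la)) abort("admixture mapping needs local-ancestry labels")
  y <- cohort$phenotype
  anc <- cohort$la$assignments
  odd <- seq(1L, nrow(anc), by = 2L)
  ga <- global_ancestry_from_tracts(cohort$la)[, ancestry + 1L]
  covar <- cbind(global_ancestry = ga, check_covariates(covariates, length(y)))
  out <- assoc_skeleton(cohort)
  for (j in seq_len(ncol(anc))) {
    La <- (anc[odd, j] == ancestry) + (anc[odd + 1L, j] == ancestry)
    if (length(unique(La)) < 2L) {
      out$qc_flag[j] <- "constant_ancestry_dosage"
      next
    }
    r <- logistic_fit_one(y, La, covar)
    if (!r$ok) {
      out$qc_flag[j] <- "non_converged"
      next
    }
    out$beta[j] <- r$beta
    out$se[j] <- r$se
    out$stat[j] <- (r$beta / r$se)^2
    out$p[j] <- pchisq(out$stat[j], 1, lower.tail = FALSE)
  }
  out$log_bf <- laplace_log_bf(out$beta, out$se, prior_sd)
  new_assoc_result(out, paste0("admixture_mapping_anc", ancestry))
}

#' Posterior probability of association from joint genotype and ancestry
#' evidence
#'
#' Combines a per-SNP genotype log Bayes factor and a local-ancestry log
#' Bayes factor under an independence assumption:
#' `posterior odds = prior_pi / (1 - prior_pi) * exp(log_bf_geno +
#' log_bf_anc)`; `PPA = odds / (1 + odds)`. PPA is monotone in both inputs
#' and equals 0.5 exactly at posterior odds 1. This is an analog of joint
#' SNP/ancestry posterior scoring, not a re-derivation of any specific
#' published combination.
#'
#' @param log_bf_geno,log_bf_anc Numeric vectors of natural-log Bayes
#'   factors (NA ancestry evidence is treated as log BF 0).
#' @param prior_pi Prior probability of association per SNP (default 1e-4).
#' @return Numeric vector of PPA values in (0, 1).
#' @examples
#' joint_ppa(0, 0, prior_pi = 0.5) # equipoise -> 0.5
#' @export
joint_ppa <- function(log_bf_geno, log_bf_anc = 0, prior_pi = 1e-4) {
  if (prior_pi <= 0 || prior_pi >= 1) abort("prior_pi must lie in (0, 1)")
  log_bf_anc <- ifelse(is.na(log_bf_anc), 0, log_bf_anc)
  log_odds <- log(prior_pi / (1 - prior_pi)) + log_bf_geno + log_bf_anc
  stats::plogis(log_odds)
}
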