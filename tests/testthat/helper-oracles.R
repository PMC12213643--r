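# Independent oracle implementations used to cross-check the package's code
# paths. These deliberately use different algorithms / parameterisations.

# r^2 by explicit 2x2 haplotype contingency counting.
oracle_r2 <- function(a, b) {
  n <- length(a)
  p11 <- sum(a == 1 & b == 1) / n
  pa <- mean(a); pb <- mean(b)
  d <- p11 - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# Cochran-Armitage trend statistic by the textbook 2x3 table formula with
# scores (0, 1, 2). Rows: cases (r), controls (s).
oracle_trend_stat <- function(r, s) {
  x <- 0:2
  n <- sum(r) + sum(s)
  R <- sum(r)
  col <- r + s
  num <- n * (n * sum(x * r) - R * sum(x * col))^2
  den <- R * (n - R) * (n * sum(x^2 * col) - sum(x * col)^2)
  num / den
}

# Independent logistic IRLS solver (no glm.fit), fixed iterations.
oracle_irls <- function(X, y, iter = 50) {
  b <- rep(0, ncol(X))
  for (i in seq_len(iter)) {
    eta <- as.numeric(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    b <- solve(crossprod(X, X * w), crossprod(X, w * z))
  }
  se <- unname(sqrt(diag(solve(crossprod(X, X * as.numeric(w))))))
  list(beta = as.numeric(b), se = se)
}

# HWE exact p-value via the closed-form normalised conditional probability
# P(h het | n individuals, na minor alleles) =
#   n! na! (2n - na)! 2^h / (hom_maj! hom_min! h! (2n)!),
# an analytically normalised route (the package renormalises numerically).
oracle_hwe_p <- function(n_het, n_hom_ref, n_hom_alt) {
  n <- n_het + n_hom_ref + n_hom_alt
  na <- n_het + 2 * n_hom_alt
  nmin <- min(na, 2 * n - na)
  hets <- seq(nmin %% 2, nmin, by = 2)
  pr <- vapply(hets, function(h) {
    hom_min <- (nmin - h) / 2
    hom_maj <- n - h - hom_min
    exp(lfactorial(n) + lfactorial(nmin) + lfactorial(2 * n - nmin) +
          h * log(2) - lfactorial(hom_maj) - lfactorial(hom_min) -
          lfactorial(h) - lfactorial(2 * n))
  }, 1)
  sum(pr[pr <= pr[hets == n_het] * (1 + 1e-10)])
}

# Exact log Bayes factor for a Gaussian toy (known sigma) by numerical
# integration of the marginal likelihood over the effect prior.
oracle_gaussian_log_bf <- function(y, x, sigma, prior_sd) {
  lik <- function(b) {
    vapply(b, function(bb) prod(dnorm(y, x * bb, sigma)), 1)
  }
  m1 <- integrate(function(b) lik(b) * dnorm(b, 0, prior_sd),
                  -Inf, Inf, rel.tol = 1e-10)$value
  m0 <- prod(dnorm(y, 0, sigma))
  log(m1 / m0)
}

# m-values for k = 2 by an explicit 4-configuration sum with hand-coded
# Gaussian marginals.
oracle_m_values_k2 <- function(beta, se, prior_p, sd0) {
  stopifnot(length(beta) == 2)
  null_l <- function(i) dnorm(beta[i], 0, se[i])
  one_l <- function(i) dnorm(beta[i], 0, sqrt(se[i]^2 + sd0^2))
  both_l <- function() {
    # integrate the shared effect numerically
    integrate(function(mu) dnorm(beta[1], mu, se[1]) *
                dnorm(beta[2], mu, se[2]) * dnorm(mu, 0, sd0),
              -Inf, Inf, rel.tol = 1e-10)$value
  }
  w <- c(`00` = (1 - prior_p)^2 * null_l(1) * null_l(2),
         `10` = prior_p * (1 - prior_p) * one_l(1) * null_l(2),
         `01` = (1 - prior_p) * prior_p * null_l(1) * one_l(2),
         `11` = prior_p^2 * both_l())
  w <- w / sum(w)
  c(m1 = unname(w["10"] + w["11"]), m2 = unname(w["01"] + w["11"]))
}
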