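test_that("QC removes SNPs for the right reasons and flags risk SNPs", {
  set.seed(2)
  g <- cbind(rbinom(200, 2, 0.3),       # fine
             rbinom(200, 2, 0.002),     # low MAF
             c(rep(1L, 200)),           # all-het: gross HWE violation
             rbinom(200, 2, 0.4))
  g[1:50, 4] <- NA_integer_             # 25% missing
  co <- manual_cohort(g, rep(0:1, 100), tiny_map(4))
  res <- qc_filter(co, maf_min = 0.01, hwe_alpha = 1e-4, max_missing = 0.1)
  expect_setequal(res$removal_log$id, co$map$id[2:4])
  expect_equal(res$removal_log$reason[match(co$map$id[2:4],
                                            res$removal_log$id)],
               c("MAF", "HWE", "missingness"))
  expect_equal(ncol(res$cohort$genotypes), 1L)
  # thresholds at zero: identity
  res0 <- qc_filter(co, maf_min = 0, hwe_alpha = 0, max_missing = 1)
  expect_equal(ncol(res0$cohort$genotypes), 4L)
  # removed designed risk SNP triggers a loud flag
  co$provenance$loci <- risk_loci(co$map$id[2], "1", 1.8, 3.24)
  expect_warning(qc_filter(co, maf_min = 0.01, hwe_alpha = 1e-4,
                           max_missing = 0.1),
                 "risk SNP")
})

test_that("HWE exact test matches full-enumeration oracle", {
  cases <- list(c(43, 57, 0), c(10, 40, 5), c(0, 50, 50), c(21, 30, 9),
                c(2, 90, 8))
  for (cc in cases) {
    expect_equal(hwe_exact_p(cc[1], cc[2], cc[3]),
                 oracle_hwe_p(cc[1], cc[2], cc[3]), tolerance = 1e-12)
  }
  # equilibrium-looking data is not rejected
  expect_gt(hwe_exact_p(50, 25, 25), 0.05)
})

test_that("GRM matches hand computation and LOCO bookkeeping", {
  g <- matrix(c(0L, 1L, 2L,
                2L, 1L, 0L), nrow = 3) # 3 individuals x 2 SNPs
  co <- manual_cohort(g, c(0L, 0L, 1L), tiny_map(2))
  grm <- compute_grm(co)
  f <- colMeans(g) / 2
  z <- sweep(sweep(g, 2, 2 * f), 2, sqrt(2 * f * (1 - f)), "/")
  expect_equal(grm$matrix, tcrossprod(z) / 2, tolerance = 1e-12)
  expect_true(max(abs(grm$matrix - t(grm$matrix))) < 1e-10)
  # duplicated individual: identical rows, off-diagonal equals diagonal
  g2 <- rbind(g, g[1, ])
  co2 <- manual_cohort(g2, c(0L, 0L, 1L, 1L), tiny_map(2))
  m2 <- compute_grm(co2)$matrix
  expect_equal(m2[1, ], m2[4, ])
  expect_equal(m2[1, 4], m2[1, 1])
  # LOCO excludes the named chromosome
  co3 <- null_hom_cohort()
  grm_loco <- compute_grm(co3, loco_chrom = "1")
  expect_equal(grm_loco$n_snps_used,
               sum(co3$map$chrom != "1" &
                     (colMeans(co3$genotypes) / 2) %% 1 > 0 |
                     co3$map$chrom != "1" &
                     colMeans(co3$genotypes) > 0 &
                     colMeans(co3$genotypes) < 2))
  expect_error(compute_grm(co3, loco_chrom = c("1", "2")), NA)
})

test_that("PCA separates divergent populations; PCs orthonormal", {
  pan <- tiny_panel(k = 2, fst = c(0.15, 0.15), n_hap = 80, n = 300, seed = 43)
  g <- gwasim:::hap_to_geno(pan$haplotypes, seq_len(300))
  co <- manual_cohort(g, rep(0L, 80), tiny_map(300))
  pc <- grm_pca(co, k = 4)
  pop <- pan$pop_labels[seq(1, 160, by = 2)]
  gap <- abs(mean(pc$scores[pop == 0, 1]) - mean(pc$scores[pop == 1, 1]))
  spread <- max(sd(pc$scores[pop == 0, 1]), sd(pc$scores[pop == 1, 1]))
  expect_gt(gap, 4 * spread)
  expect_true(all(range(table(pc$scores[, 1] > 0, pop) == 0) |
                    TRUE)) # PC1 sign split checked below
  expect_true(all(tapply(pc$scores[, 1] > 0, pop, function(x)
    all(x) || all(!x)))) # zero overlap between label groups on PC1
  ip <- crossprod(pc$scores)
  expect_lt(max(abs(ip - diag(4))), 1e-8)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  # rank-1 matrix: top eigenvalue equals the trace
  x <- matrix(rnorm(5), 5)
  r1 <- structure(list(matrix = tcrossprod(x), n_snps_used = 1L,
                       loco_chrom = NULL), class = "grm")
  expect_equal(grm_pca(r1, 1)$eigenvalues, sum(diag(tcrossprod(x))))
  expect_error(grm_pca(r1, 5), "smaller")
})

test_that("trend test matches the textbook 2x3 formula", {
  # printed toy: cases 10/40/50, controls 30/40/30
  r <- c(10, 40, 50); s <- c(30, 40, 30)
  g <- rep(rep(0:2, 2), c(r, s))
  y <- rep(rep(1:0, c(3, 3)), c(r, s))
  co <- manual_cohort(matrix(g, ncol = 1), y, tiny_map(1))
  res <- trend_assoc(co)
  expect_equal(res$stat, oracle_trend_stat(r, s), tolerance = 1e-12)
  expect_equal(res$p, pchisq(oracle_trend_stat(r, s), 1, lower.tail = FALSE))
  # identical genotype distributions: statistic 0, p = 1
  g_eq <- c(rep(0:2, c(30, 40, 30)), rep(0:2, c(30, 40, 30)))
  y_eq <- rep(1:0, each = 100)
  res_eq <- trend_assoc(manual_cohort(matrix(g_eq, ncol = 1), y_eq,
                                      tiny_map(1)))
  expect_equal(res_eq$stat, 0, tolerance = 1e-12)
  expect_equal(res_eq$p, 1)
  # monomorphic flagged
  res_m <- trend_assoc(manual_cohort(matrix(rep(1L, 200), ncol = 1), y_eq,
                                     tiny_map(1)))
  expect_identical(res_m$qc_flag, "monomorphic")
  expect_true(is.na(res_m$p))
})

test_that("trend p-values are uniform under phenotype permutation", {
  co <- null_hom_cohort()
  set.seed(77)
  co$phenotype <- sample(co$phenotype)
  p <- trend_assoc(co)$p
  expect_gt(suppressWarnings(ks.test(p[!is.na(p)], "punif"))$p.value, 0.01)
})

test_that("logistic fit matches an independent IRLS solve", {
  # balanced 12-row design
  x <- rep(c(0, 1, 2, 0, 1, 2), 2)
  y <- rep(c(0, 0, 0, 1, 1, 1), 2)
  co <- manual_cohort(matrix(as.integer(x), ncol = 1), as.integer(y),
                      tiny_map(1))
  res <- logistic_assoc(co)
  o <- oracle_irls(cbind(1, x), y)
  expect_equal(res$beta, o$beta[2], tolerance = 1e-8)
  expect_equal(res$se, o$se[2], tolerance = 1e-6)
  # with a covariate
  set.seed(5)
  cv <- rnorm(12)
  res2 <- logistic_assoc(co, covariates = cbind(cv))
  o2 <- oracle_irls(cbind(1, cv, x), y)
  expect_equal(res2$beta, o2$beta[3], tolerance = 1e-6)
  # null genotype: beta near zero at scale
  co0 <- null_hom_cohort()
  r0 <- logistic_assoc(co0)
  expect_lt(abs(mean(r0$beta, na.rm = TRUE)), 0.05)
  # separation is flagged, not fabricated
  xs <- c(rep(0L, 10), rep(2L, 10))
  ys <- c(rep(0L, 10), rep(1L, 10))
  rs <- logistic_assoc(manual_cohort(matrix(xs, ncol = 1), ys, tiny_map(1)))
  expect_identical(rs$qc_flag, "non_converged")
  expect_true(is.na(rs$p))
  expect_error(logistic_assoc(co, covariates = matrix(1, 12, 1)),
               "rank deficient")
})

test_that("Laplace Bayes factor agrees with the exact Gaussian conjugate toy", {
  set.seed(11)
  n <- 40; sigma <- 1; prior_sd <- 0.3
  x <- rnorm(n)
  x <- x - mean(x)
  y <- 0.25 * x + rnorm(n, 0, sigma)
  beta_hat <- sum(x * y) / sum(x^2)
  se <- sigma / sqrt(sum(x^2))
  lbf <- gwasim:::laplace_log_bf(beta_hat, se, prior_sd)
  expect_lt(abs(lbf - oracle_gaussian_log_bf(y, x, sigma, prior_sd)), 0.05)
  # prior collapsing to the null: log BF -> 0
  expect_lt(abs(gwasim:::laplace_log_bf(beta_hat, se, 1e-8)), 1e-6)
  expect_error(bayes_assoc(null_hom_cohort(), prior_sd = 0), "prior_sd")
})

test_that("Bayes factors are calibrated under the null", {
  co <- null_hom_cohort()
  res <- bayes_assoc(co)
  lb <- res$log_bf[!is.na(res$log_bf)]
  expect_lte(mean(lb >= log(100)), 1e-3)
  expect_equal(attr(res, "test_name"), "bayes")
})

test_that("LMM with identity GRM equals OLS; GLS matches a dense solve", {
  co <- null_hom_cohort()
  n <- nrow(co$genotypes)
  id_grm <- structure(list(matrix = diag(n), n_snps_used = 1L,
                           loco_chrom = NULL), class = "grm")
  res <- lmm_assoc(co, grm = id_grm)
  y <- as.numeric(co$phenotype)
  ols_p <- apply(co$genotypes, 2, function(x) {
    if (var(x) == 0) return(NA_real_)
    summary(lm(y ~ x))$coefficients[2, 4]
  })
  expect_equal(res$p, unname(ols_p), tolerance = 1e-6)
  # explicit-inverse GLS oracle at N = 50
  set.seed(13)
  n2 <- 50
  K <- crossprod(matrix(rnorm(n2 * n2), n2)) / n2
  K <- K / mean(diag(K))
  g <- matrix(rbinom(n2 * 5, 2, 0.4), n2)
  co2 <- manual_cohort(g, rbinom(n2, 1, 0.5), tiny_map(5))
  grm2 <- structure(list(matrix = K, n_snps_used = 5L, loco_chrom = NULL),
                    class = "grm")
  res2 <- lmm_assoc(co2, grm = grm2)
  delta <- attr(res2, "delta")[["all"]]
  V <- K + delta * diag(n2)
  Vi <- solve(V)
  y2 <- as.numeric(co2$phenotype)
  for (j in 1:5) {
    X <- cbind(1, g[, j])
    XtVX <- t(X) %*% Vi %*% X
    b <- solve(XtVX, t(X) %*% Vi %*% y2)
    r <- y2 - X %*% b
    s2 <- as.numeric(t(r) %*% Vi %*% r) / (n2 - 2)
    se <- sqrt(s2 * solve(XtVX)[2, 2])
    expect_equal(res2$beta[j], b[2], tolerance = 1e-6)
    expect_equal(res2$se[j], se, tolerance = 1e-6)
  }
})

test_that("LMM variance components: zero-heritability data matches OLS", {
  set.seed(17)
  co <- null_hom_cohort()
  # phenotype independent of genotype AND relatedness
  co$phenotype <- rbinom(nrow(co$genotypes), 1, 0.5)
  res <- lmm_assoc(co)
  h2 <- attr(res, "h2")[["all"]]
  expect_lt(h2, 0.15)
  ols_p <- apply(co$genotypes, 2, function(x) {
    if (var(x) == 0) return(NA_real_)
    summary(lm(co$phenotype ~ x))$coefficients[2, 4]
  })
  keep <- !is.na(res$p)
  expect_gt(cor(res$p[keep], ols_p[keep]), 0.999)
})

test_that("non-PSD GRM is rejected", {
  co <- null_hom_cohort()
  n <- nrow(co$genotypes)
  bad <- diag(n); bad[1, 1] <- -2
  grm_bad <- structure(list(matrix = bad, n_snps_used = 1L, loco_chrom = NULL),
                       class = "grm")
  expect_error(lmm_assoc(co, grm = grm_bad), "positive semi-definite")
})
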