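mk_stats <- function(beta_list, se_list, n_list = NULL) {
  k <- length(beta_list)
  if (is.null(n_list)) n_list <- rep(1000L, k)
  studies <- lapply(seq_len(k), function(i) {
    tibble::tibble(id = paste0("rs", seq_along(beta_list[[i]])),
                   beta = beta_list[[i]], se = se_list[[i]],
                   n = n_list[[i]])
  })
  names(studies) <- paste0("s", seq_len(k))
  study_stats(studies)
}

test_that("fixed effects: single study, symmetry, and a 3-study oracle", {
  st1 <- mk_stats(list(c(0.3)), list(c(0.1)))
  fe1 <- fixed_effects(st1)
  expect_equal(fe1$fe_beta, 0.3)
  expect_equal(fe1$fe_se, 0.1)
  st2 <- mk_stats(list(0.2, 0.4), list(0.1, 0.1))
  fe2 <- fixed_effects(st2)
  expect_equal(fe2$fe_beta, 0.3)
  expect_equal(fe2$fe_se, 0.1 / sqrt(2))
  # 3-study toy vs direct arithmetic
  b <- c(0.1, -0.2, 0.5); s <- c(0.05, 0.2, 0.12)
  fe3 <- fixed_effects(mk_stats(as.list(b), as.list(s)))
  w <- 1 / s^2
  expect_equal(fe3$fe_beta, sum(w * b) / sum(w), tolerance = 1e-12)
  expect_equal(fe3$fe_se, 1 / sqrt(sum(w)), tolerance = 1e-12)
  # pooled SE never exceeds the smallest study SE
  expect_lte(fe3$fe_se, min(s))
})

test_that("random effects: DL tau2, FE recovery, I2 bounds, RE2 gains power
           under heterogeneity", {
  # homogeneous studies: tau2 = 0 and RE = FE exactly
  sth <- mk_stats(list(0.3, 0.3, 0.3), list(0.1, 0.1, 0.1))
  re <- random_effects(sth)
  fe <- fixed_effects(sth)
  expect_equal(re$re_tau2, 0)
  expect_equal(re$re_beta, fe$fe_beta)
  expect_equal(re$re_se, fe$fe_se)
  # two-study toy: hand-computed DL tau2
  st2 <- mk_stats(list(0.5, -0.5), list(0.1, 0.1))
  re2 <- random_effects(st2)
  w <- 100 # 1/0.1^2
  q <- w * 0.5^2 * 2 # sum w (b - 0)^2
  tau2_hand <- (q - 1) / (2 * w - 2 * w^2 / (2 * w))
  expect_equal(re2$re_tau2, tau2_hand, tolerance = 1e-12)
  expect_gt(re2$re_tau2, 0)
  # I2 in [0, 100] for randomised inputs
  set.seed(31)
  for (i in 1:10) {
    st <- mk_stats(as.list(rnorm(3)), as.list(runif(3, 0.05, 0.3)))
    r <- random_effects(st)
    expect_gte(r$i2, 0); expect_lte(r$i2, 100)
  }
  # heterogeneous one-population effect: RE2 more liberal than the DL z-test
  sth2 <- mk_stats(list(0.6, 0.0), list(0.08, 0.08))
  rh <- random_effects(sth2)
  expect_lt(rh$re2_p, rh$re_p)
  expect_error(random_effects(mk_stats(list(0.3), list(0.1))), "2 studies")
})

test_that("m-values: degenerate prior, k = 2 brute force, symmetry, sum rule", {
  st <- mk_stats(list(c(0.5, 0.1), c(0.02, 0.1)),
                 list(c(0.05, 0.1), c(0.05, 0.1)))
  # prior probability 1: every m-value exactly 1
  m1 <- m_values(st, prior_effect_prob = 1)
  expect_true(all(m1$m_value == 1))
  # k = 2: match the independent 4-configuration enumeration
  m <- m_values(st, prior_effect_prob = 0.5, effect_prior_sd = 0.2)
  for (snp in c("rs1", "rs2")) {
    b <- st$beta[st$id == snp]; s <- st$se[st$id == snp]
    o <- oracle_m_values_k2(b, s, 0.5, 0.2)
    got <- m$m_value[m$id == snp]
    expect_equal(got, unname(o), tolerance = 1e-8)
  }
  # strong study clearly separated from the null study at rs1
  expect_gt(m$m_value[m$id == "rs1" & m$study_id == "s1"], 0.9)
  expect_lt(m$m_value[m$id == "rs1" & m$study_id == "s2"], 0.5)
  # exchangeability: symmetric studies get symmetric m-values (rs2)
  ms <- m$m_value[m$id == "rs2"]
  expect_equal(ms[1], ms[2], tolerance = 1e-12)
  # m_i is a posterior probability: complement well-defined
  expect_true(all(m$m_value >= 0 & m$m_value <= 1))
  big <- mk_stats(as.list(rep(0.1, 21)), as.list(rep(0.1, 21)))
  expect_error(m_values(big), "20 studies")
})

test_that("binary effects: Stouffer limit, zero-m invariance, 2-study oracle", {
  st <- mk_stats(list(c(0.3), c(0.15)), list(c(0.1), c(0.1)),
                 n_list = list(1000L, 1000L))
  m_all1 <- tibble::tibble(id = "rs1", study_id = c("s1", "s2"),
                           m_value = c(1, 1))
  be <- binary_effects(st, m_all1)
  z <- c(3, 1.5)
  expect_equal(be$be_z, sum(sqrt(0.5) * z) / sqrt(2 * 0.5), tolerance = 1e-12)
  # study with m = 0 contributes nothing, whatever its z
  m_drop <- tibble::tibble(id = "rs1", study_id = c("s1", "s2"),
                           m_value = c(1, 0))
  be1 <- binary_effects(st, m_drop)
  st_wild <- mk_stats(list(c(0.3), c(9.9)), list(c(0.1), c(0.1)))
  expect_equal(binary_effects(st_wild, m_drop)$be_z, be1$be_z)
  # all m = 0: flagged undefined
  m0 <- tibble::tibble(id = "rs1", study_id = c("s1", "s2"), m_value = c(0, 0))
  expect_true(binary_effects(st, m0)$be_undefined)
  # two-study weighted arithmetic oracle
  stw <- mk_stats(list(c(0.2), c(0.4)), list(c(0.1), c(0.2)),
                  n_list = list(3000L, 1000L))
  mw <- tibble::tibble(id = "rs1", study_id = c("s1", "s2"),
                       m_value = c(0.9, 0.6))
  bew <- binary_effects(stw, mw)
  zz <- c(2, 2); ww <- c(0.75, 0.25)
  expect_equal(bew$be_z,
               sum(c(0.9, 0.6) * sqrt(ww) * zz) /
                 sqrt(sum(c(0.9, 0.6)^2 * ww)), tolerance = 1e-12)
})

test_that("meta_analysis joins all models per SNP", {
  st <- mk_stats(list(c(0.5, 0.0), c(0.45, 0.02)),
                 list(c(0.08, 0.08), c(0.09, 0.09)))
  mr <- meta_analysis(st)
  expect_s3_class(mr, "meta_result")
  expect_equal(nrow(mr), 2L)
  expect_true(all(c("fe_p", "re_p", "re2_p", "be_p", "i2", "q_stat") %in%
                    names(mr)))
  td <- tidy(mr)
  expect_setequal(unique(td$model), c("fe", "re", "re2", "be"))
  expect_equal(nrow(glance(mr)), 1L)
})

test_that("replication classification follows significance and the tag map", {
  mk_res <- function(p, beta, ids = paste0("rs", seq_along(p))) {
    gwasim:::new_assoc_result(tibble::tibble(
      id = ids, chrom = "2", pos = seq_along(p), a1 = "G", maf = 0.3,
      beta = beta, se = 0.1, stat = (beta / 0.1)^2, p = p,
      log_bf = NA_real_, ppa = NA_real_, n = 1000L,
      qc_flag = NA_character_), "toy")
  }
  truth <- tibble::tibble(snp_id = c("rs1", "rs2", "rs3", "rs4"),
                          partner_id = c(NA, "rs5", NA, NA))
  a <- mk_res(c(1e-10, 1e-9, 1e-8, 0.5, 0.9), rep(0.5, 5))
  # identical studies: every significant locus replicates at the same SNP
  rep_same <- replication_report(a, a, truth, alpha_a = 1e-6, alpha_b = 1e-6)
  expect_true(all(rep_same$classification[1:3] == "replicated-same-SNP"))
  expect_equal(rep_same$classification[4], "non-replicated")
  # partner-mediated: rs2 null in study B but its LD partner rs5 fires
  b <- mk_res(c(1e-10, 0.8, 1e-8, 0.6, 1e-9), rep(0.5, 5))
  rep_b <- replication_report(a, b, truth, alpha_a = 1e-6, alpha_b = 1e-6)
  expect_equal(rep_b$classification[2], "replicated-via-LD-partner")
  # direction-discordant significant pair is not same-SNP replication
  c_res <- mk_res(c(1e-10, 0.8, 1e-8, 0.6, 0.9), c(-0.5, 0.5, 0.5, 0.5, 0.5))
  rep_c <- replication_report(a, c_res, truth, alpha_a = 1e-6, alpha_b = 1e-6)
  expect_false(rep_c$classification[1] == "replicated-same-SNP")
  # null studies: nothing replicates
  d <- mk_res(rep(0.5, 5), rep(0, 5))
  rep_d <- replication_report(d, d, truth, alpha_a = 1e-6, alpha_b = 1e-6)
  expect_true(all(rep_d$classification == "non-replicated"))
  expect_error(replication_report(a, b, NULL), "truth")
})
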