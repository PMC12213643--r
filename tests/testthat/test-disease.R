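test_that("penetrance follows the genotype-class logistic model", {
  b0 <- stats::qlogis(0.1)
  loc <- risk_loci("rs1", "1", rr_het = 1.5, rr_hom = 2.25)
  # null model and zero genotypes collapse to the baseline
  null_loc <- risk_loci("rs1", "1", 1, 1)
  expect_equal(penetrance(matrix(0:2, ncol = 1), null_loc, b0),
               rep(stats::plogis(b0), 3))
  expect_equal(penetrance(0, loc, b0), stats::plogis(b0))
  # single-locus heterozygote: independent scalar computation
  expect_equal(penetrance(1, loc, b0), stats::plogis(log(1 / 9) + log(1.5)))
  expect_equal(penetrance(2, loc, b0), stats::plogis(log(1 / 9) + log(2.25)))
  # multi-locus: effects multiply on the odds scale
  two <- risk_loci(c("a", "b"), c("1", "1"), c(1.5, 2), c(2.25, 4))
  expect_equal(penetrance(matrix(c(1, 2), 1), two, b0),
               stats::plogis(log(1 / 9) + log(1.5) + log(4)))
  expect_error(risk_loci("x", "1", -1, 2), "must be > 0")
  expect_error(penetrance(1, loc, Inf), "finite")
})

test_that("baseline calibration hits the target prevalence", {
  set.seed(4)
  g <- cbind(rbinom(500, 2, 0.3), rbinom(500, 2, 0.1))
  loci <- risk_loci(c("a", "b"), c("1", "2"), c(1.8, 1.15), c(3.24, 1.32))
  # all rr = 1: exactly the logit of the target
  null_loci <- risk_loci(c("a", "b"), c("1", "2"), c(1, 1), c(1, 1))
  expect_equal(calibrate_baseline(g, null_loci, 0.2), stats::qlogis(0.2),
               tolerance = 1e-8)
  b0 <- calibrate_baseline(g, loci, 0.1)
  expect_lt(b0, stats::qlogis(0.1)) # risk loci push the baseline down
  expect_lt(abs(mean(penetrance(g, loci, b0)) - 0.1), 1e-6)
  # grid-scan oracle on an enumerable genotype distribution
  g_enum <- as.matrix(expand.grid(0:2, 0:2))
  grid <- seq(-6, 0, by = 1e-4)
  pen_mean <- vapply(grid, function(b) mean(penetrance(g_enum, loci, b)), 1)
  b_grid <- grid[which.min(abs(pen_mean - 0.1))]
  expect_lt(abs(calibrate_baseline(g_enum, loci, 0.1) - b_grid), 1e-4)
  expect_error(calibrate_baseline(g, loci, 1.2), "target_prevalence")
})

test_that("tag-pair selection is deterministic and matches a brute-force scan", {
  set.seed(8)
  h <- matrix(rbinom(6 * 12, 1, 0.5), nrow = 6)
  map <- tiny_map(12)
  # duplicated columns: complete-LD pair found at r2_min = 1
  h[, 7] <- h[, 4]
  pair <- select_tag_pair(h, h, map, "1", r2_min = 1)
  expect_equal(pair$r2_a, 1.0)
  expect_identical(c(pair$snp_x, pair$snp_y), map$id[c(4, 7)])
  # brute force: the returned pair reaches the maximal pairwise r2
  all_r2 <- outer(1:12, 1:12, Vectorize(function(i, j) {
    if (i >= j) return(NA_real_)
    tryCatch(compute_ld_r2(h, i, j), error = function(e) NA_real_)
  }))
  expect_equal(pair$r2_a, max(all_r2, na.rm = TRUE))
  h3 <- cbind(c(1, 1, 1, 0, 0, 0), c(1, 1, 0, 1, 0, 0), c(1, 0, 1, 0, 1, 0))
  expect_error(select_tag_pair(h3, h3, map[1:3, ], "1", r2_min = 1),
               "design infeasible")
})

test_that("manufactured pairs are in complete LD in the design population only", {
  pan <- tiny_panel(k = 2, fst = c(0.1, 0.1), n_hap = 60, n = 40, seed = 19)
  mt <- manufacture_tag_pair(pan, "1", ld_pops = 0L, flip_prob = 0.1, seed = 3)
  i <- match(mt$snp_x, pan$map$id); j <- match(mt$snp_y, pan$map$id)
  eur <- mt$panel$pop_labels == 0L
  expect_equal(compute_ld_r2(mt$panel$haplotypes[eur, ], i, j), 1.0)
  r2_b <- compute_ld_r2(mt$panel$haplotypes[!eur, ], i, j)
  expect_lt(r2_b, 1.0)
  expect_gt(r2_b, 0.3) # still in high LD
  # reported both-population r2 via the selection operation
  pair <- select_tag_pair(mt$panel$haplotypes[eur, ],
                          mt$panel$haplotypes[!eur, ], pan$map, "1",
                          r2_min = 1)
  expect_equal(pair$r2_a, 1.0)
  expect_lt(pair$r2_b, 1.0)
})

test_that("case-control rejection sampling meets quotas exactly", {
  co <- null_hom_cohort()
  expect_equal(sum(co$phenotype == 1L), 150L)
  expect_equal(sum(co$phenotype == 0L), 150L)
  expect_true(all(co$genotypes %in% 0:2))
  # genotypes consistent with retained phased haplotypes
  expect_identical(co$genotypes,
                   gwasim:::hap_to_geno(co$haplotypes,
                                        seq_len(ncol(co$genotypes))))
  expect_error(simulate_case_control(tiny_panel(), risk_loci(
    character(), character(), numeric(), numeric()), 0, 10), "> 0")
})

test_that("null effects give centred case-control frequency differences", {
  co <- null_hom_cohort()
  f_case <- colMeans(co$genotypes[co$phenotype == 1L, ]) / 2
  f_ctrl <- colMeans(co$genotypes[co$phenotype == 0L, ]) / 2
  d <- f_case - f_ctrl
  expect_lt(abs(mean(d)), 0.01)
  # roughly binomial scatter, no systematic shift
  expect_lt(mean(abs(d) > 4 * sqrt(0.25 / 150)), 0.02)
})

test_that("configured genotypic odds ratios are recovered", {
  pan <- tiny_panel(k = 1, fst = 0.1, n_hap = 100, n = 120, seed = 23)
  site <- gwasim:::pick_risk_site(pan, "1")
  loci <- risk_loci(pan$map$id[site], "1", rr_het = 1.5, rr_hom = 2.25)
  co <- simulate_case_control(pan, loci, 2500, 2500, seed = 29)
  tab <- table(factor(co$genotypes[, site], 0:2), co$phenotype)
  or_het <- (tab["1", "1"] * tab["0", "0"]) / (tab["0", "1"] * tab["1", "0"])
  or_hom <- (tab["2", "1"] * tab["0", "0"]) / (tab["0", "1"] * tab["2", "0"])
  expect_lt(abs(or_het / 1.5 - 1), 0.15)
  expect_lt(abs(or_hom / 2.25 - 1), 0.15)
})

test_that("monomorphic risk locus warns and proceeds", {
  pan <- tiny_panel(k = 1, fst = 0.1, n_hap = 20, n = 30, seed = 31)
  pan$haplotypes[, 5] <- 0L # force monomorphic
  loci <- risk_loci(pan$map$id[5], "1", 1.8, 3.24)
  expect_warning(
    co <- simulate_case_control(pan, loci, 30, 30, seed = 33),
    "monomorphic")
  expect_equal(sum(co$phenotype), 30L)
  expect_match(co$provenance$warnings, "monomorphic")
})

test_that("ancestry-risk injection shifts regional ancestry by the deviation", {
  pan <- tiny_panel(k = 2, fst = c(0.15, 0.15), n_hap = 60, n = 120,
                    chroms = c("1", "2"), seed = 37)
  scen <- admixture_scenario(pan, c(0.6, 0.4), generations = 4, n_out = 250)
  region <- ancestry_risk_spec("1", 2e7, 6e7, ancestry = 0L, deviation = 0.15)
  co <- simulate_case_control(scen, risk_loci(character(), character(),
                                              numeric(), numeric()),
                              400, 400, seed = 39, ancestry_risk = region)
  a <- co$la$assignments
  in_reg <- co$map$chrom == "1" & co$map$pos_bp >= 2e7 & co$map$pos_bp < 6e7
  odd <- seq(1, nrow(a), by = 2)
  dos <- (rowMeans(a[odd, in_reg, drop = FALSE] == 0L) +
            rowMeans(a[odd + 1, in_reg, drop = FALSE] == 0L)) / 2
  diff_reg <- mean(dos[co$phenotype == 1L]) - mean(dos[co$phenotype == 0L])
  expect_lt(abs(diff_reg - 0.15), 0.05)
  # locality: ancestry outside the region is unchanged between groups
  out_reg <- co$map$chrom == "2"
  dos_out <- (rowMeans(a[odd, out_reg, drop = FALSE] == 0L) +
                rowMeans(a[odd + 1, out_reg, drop = FALSE] == 0L)) / 2
  d_out <- mean(dos_out[co$phenotype == 1L]) - mean(dos_out[co$phenotype == 0L])
  se_out <- sd(dos_out) * sqrt(2 / 400)
  expect_lt(abs(d_out), 3 * se_out)
  # invalid inputs
  bad_region <- ancestry_risk_spec("9", 1, 10, 0L, 0.1)
  expect_error(simulate_case_control(scen, risk_loci(character(), character(),
                                                     numeric(), numeric()),
                                     10, 10, seed = 1,
                                     ancestry_risk = bad_region),
               "no variants")
  too_much <- ancestry_risk_spec("1", 2e7, 6e7, 0L, deviation = 0.6)
  expect_error(simulate_case_control(scen, risk_loci(character(), character(),
                                                     numeric(), numeric()),
                                     10, 10, seed = 1,
                                     ancestry_risk = too_much),
               "outside")
})

test_that("scenario presets wire the designed loci and sizes", {
  sc <- build_scenario("fiveway", size = "small", seed = 2,
                       n_snps_per_chrom = 40, n_hap_per_pop = 40,
                       n_cases = 60, n_controls = 60)
  expect_equal(nrow(sc$design), 8L)
  expect_setequal(unique(sc$design$chrom), c("2", "6", "11", "15", "20"))
  # chromosome-11 pair is in complete LD in every population of a
  # homogeneous-design panel
  sch <- build_scenario("eur_hom", size = "small", seed = 2,
                        n_snps_per_chrom = 40, n_hap_per_pop = 40,
                        n_cases = 40, n_controls = 40)
  d11 <- sch$design[sch$design$chrom == "11", ]
  i <- match(d11$snp_id[d11$role == "anchor"], sch$map$id)
  j <- match(d11$snp_id[d11$role == "partner"], sch$map$id)
  for (k in 0:1) {
    hk <- sch$panel$haplotypes[sch$panel$pop_labels == k, ]
    expect_equal(compute_ld_r2(hk, i, j), 1.0)
  }
  expect_equal(sum(sc$cohort$phenotype), 60L)
  # same seed, different quota: identical locus design, differing only in n
  sc2 <- build_scenario("fiveway", size = "small", seed = 2,
                        n_snps_per_chrom = 40, n_hap_per_pop = 40,
                        n_cases = 80, n_controls = 80)
  expect_identical(sc$design$snp_id, sc2$design$snp_id)
  expect_equal(sum(sc2$cohort$phenotype), 80L)
  # null override: no active risk loci for downstream FPR work
  sc0 <- build_scenario("eur_hom", size = "small", seed = 2,
                        n_snps_per_chrom = 40, n_hap_per_pop = 40,
                        n_cases = 40, n_controls = 40, force_null = TRUE)
  expect_true(all(scenario_truth(sc0)$signal_class == "null"))
  expect_error(build_scenario("unknown"), "arg")
})
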