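no_mut <- gametogenesis_params(mutation_rate = 0)

test_that("meiosis limits: no recombination / identical parents", {
  map <- tiny_map(30)
  a <- rep(0L, 30); b <- rep(1L, 30)
  g <- meiosis(a, b, map, gametogenesis_params(recomb = FALSE,
                                               mutation_rate = 0), seed = 3)
  expect_true(identical(g$gamete, a) || identical(g$gamete, b))
  expect_equal(nrow(g$breakpoints), 0L)
  # identical parents: gamete equals the parent regardless of breakpoints
  p <- rbinom(30, 1, 0.5)
  g2 <- meiosis(p, p, map, no_mut, seed = 4)
  expect_identical(g2$gamete, as.integer(p))
  expect_error(meiosis(a, b[-1], map, no_mut, seed = 1), "aligned")
})

test_that("crossover count is Poisson with mean total-cM / 100", {
  map <- tiny_map(101) # one chromosome spanning ~100 cM
  total_cm <- max(map$pos_cm) - min(map$pos_cm)
  a <- rep(0L, 101); b <- rep(1L, 101)
  counts <- vapply(1:4000, function(i) {
    nrow(meiosis(a, b, map, no_mut, seed = i)$breakpoints)
  }, 1L)
  expect_lt(abs(mean(counts) - total_cm / 100), 0.05)
  # ancestry labels propagate with the same segments
  g <- meiosis(a, b, map, no_mut, seed = 12,
               anc_a = rep(0L, 101), anc_b = rep(1L, 101))
  expect_identical(as.integer(g$ancestry), g$gamete)
})

test_that("homogeneous growth resamples the panel faithfully", {
  pan <- tiny_panel(k = 1, fst = 0.1, n_hap = 20, n = 120, seed = 2)
  # recombination and mutation disabled: offspring are verbatim panel rows
  off0 <- grow_homogeneous(pan, 30,
                           gametogenesis_params(recomb = FALSE,
                                                mutation_rate = 0), seed = 3)
  key <- function(m) apply(m, 1, paste, collapse = "")
  expect_true(all(key(off0$haplotypes) %in% key(pan$haplotypes)))
  # allele frequencies preserved within binomial error (4 SE at <= 1% of sites)
  map2k <- tiny_map(2000)
  pan2 <- generate_reference_panel(1, 0.1, 100, map2k, seed = 6)
  off <- grow_homogeneous(pan2, 500, no_mut, seed = 7)
  f0 <- colMeans(pan2$haplotypes)
  f1 <- colMeans(off$haplotypes)
  se <- sqrt(f0 * (1 - f0) / 1000)
  expect_lte(mean(abs(f1 - f0) > 4 * se), 0.01)
  expect_error(grow_homogeneous(pan, 0), "n_out")
})

test_that("mutation introduces the configured flip rate", {
  map <- tiny_map(20000, length_mb = 1) # short map: recombination negligible
  pan <- generate_reference_panel(1, 0.1, 20, map, seed = 8)
  off <- grow_homogeneous(pan, 100,
                          gametogenesis_params(recomb = FALSE,
                                               mutation_rate = 1e-3), seed = 9)
  key <- function(m) apply(m, 1, paste, collapse = "")
  # flips per haplotype = Hamming distance to the copied parent row
  flips <- vapply(seq_len(nrow(off$haplotypes)), function(i) {
    min(colSums(abs(t(pan$haplotypes) - off$haplotypes[i, ])))
  }, 1)
  expect_lt(abs(mean(flips) - 20), 1.5)
})

test_that("admixture scenario validation", {
  pan <- tiny_panel(k = 2, fst = c(0.1, 0.1), n_hap = 20, n = 30)
  expect_error(admixture_scenario(pan, c(0.6, 0.5), 10, 50), "sum to 1")
  expect_error(admixture_scenario(pan, c(0.7, 0.3), 0, 50), "generations")
  expect_error(admixture_scenario(pan, c(0.7, 0.3), 10, 1), "founding")
  expect_error(admixture_scenario(pan, c(1), 10, 50), "one entry per")
})

test_that("single-ancestry proportions give single-ancestry tracts", {
  pan <- tiny_panel(k = 3, fst = c(0.1, 0.1, 0.1), n_hap = 20, n = 40)
  scen <- admixture_scenario(pan, c(1, 0, 0), generations = 2, n_out = 20)
  ad <- simulate_admixture(scen, no_mut, seed = 5)
  expect_true(all(ad$ancestry == 0L))
  la <- local_ancestry(ad$ancestry, ad$map)
  expect_true(all(la$tracts$ancestry == 0L))
  expect_equal(nrow(la$tracts), length(la$hap_ids)) # one tract per haplotype
})

test_that("more generations produce more, shorter tracts", {
  pan <- tiny_panel(k = 2, fst = c(0.15, 0.15), n_hap = 40, n = 150)
  n_tracts <- vapply(c(1, 10), function(g) {
    scen <- admixture_scenario(pan, c(0.5, 0.5), generations = g, n_out = 60)
    ad <- simulate_admixture(scen, no_mut, seed = 6)
    nrow(local_ancestry(ad$ancestry, ad$map)$tracts)
  }, 1L)
  expect_gt(n_tracts[2], n_tracts[1])
})

test_that("global ancestry is conserved in expectation", {
  pan <- tiny_panel(k = 3, fst = c(0.1, 0.1, 0.1), n_hap = 60, n = 60,
                    chroms = c("1", "2"))
  props <- c(0.7, 0.2, 0.1)
  scen <- admixture_scenario(pan, props, generations = 5, n_out = 300)
  ad <- simulate_admixture(scen, no_mut, seed = 7)
  ga <- global_ancestry_from_tracts(local_ancestry(ad$ancestry, ad$map))
  expect_equal(rowSums(ga), rep(1, nrow(ga)))
  # cohort mean within 3 SE of the founding proportions (drift-inflated SE:
  # the founding pool is the dominant variance source)
  se <- sqrt(props * (1 - props) / scen$n_out) * sqrt(1 + scen$generations / 2)
  expect_true(all(abs(colMeans(ga) - props) < 3 * se + 0.02))
})

test_that("tract/assignment duality is exact and cM weighting matches
           site counting on a uniform map", {
  co <- null_admixed_cohort()
  la <- co$la
  back <- assignments_from_tracts(la$tracts, la$map, la$hap_ids)
  expect_identical(back, la$assignments)
  ga <- global_ancestry_from_tracts(la)
  # brute force: per-site label counting (uniform map, even spacing)
  n <- nrow(la$assignments) / 2
  odd <- seq(1, 2 * n, by = 2)
  brute <- vapply(0:(la$n_pops - 1), function(a) {
    (rowMeans(la$assignments[odd, ] == a) +
       rowMeans(la$assignments[odd + 1, ] == a)) / 2
  }, numeric(n))
  expect_lt(max(abs(ga - brute)), 1e-12)
})

test_that("admixed haplotypes without recombination are verbatim founders", {
  pan <- tiny_panel(k = 2, fst = c(0.2, 0.2), n_hap = 20, n = 50)
  scen <- admixture_scenario(pan, c(0.5, 0.5), generations = 3, n_out = 25)
  ad <- simulate_admixture(scen, gametogenesis_params(recomb = FALSE,
                                                      mutation_rate = 0),
                           seed = 8)
  key <- function(m) apply(m, 1, paste, collapse = "")
  expect_true(all(key(ad$haplotypes) %in% key(pan$haplotypes)))
})

test_that("admixture raises heterozygosity at divergent sites", {
  pan <- tiny_panel(k = 2, fst = c(0.25, 0.25), n_hap = 60, n = 200, seed = 3)
  f <- pan$allele_freqs
  divergent <- which(abs(f[1, ] - f[2, ]) > 0.3)
  scen <- admixture_scenario(pan, c(0.5, 0.5), generations = 5, n_out = 200)
  ad <- simulate_admixture(scen, no_mut, seed = 9)
  g <- gwasim:::hap_to_geno(ad$haplotypes, divergent)
  het_adm <- mean(g == 1L)
  het_par <- mean(vapply(divergent, function(j) {
    mean(2 * f[, j] * (1 - f[, j]))
  }, 1))
  expect_gt(het_adm, het_par)
})

test_that("noisy local ancestry corrupts roughly epsilon of the labels", {
  co <- null_admixed_cohort()
  la2 <- noisy_local_ancestry(co$la, epsilon = 0.1, seed = 4)
  rate <- mean(la2$assignments != co$la$assignments)
  expect_lt(abs(rate - 0.1), 0.02)
  expect_identical(dim(la2$assignments), dim(co$la$assignments))
})
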