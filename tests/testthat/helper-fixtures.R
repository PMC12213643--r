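# Shared fixtures, built in code. Expensive objects are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_map <- function(n = 60, chroms = "1", length_mb = 100) {
  default_variant_map(n_snps_per_chrom = n, chroms = chroms,
                      chrom_length_mb = length_mb)
}

tiny_panel <- function(k = 1, fst = 0.1, n_hap = 40, n = 60, chroms = "1",
                       seed = 11, length_mb = 100, ...) {
  generate_reference_panel(k, fst, n_hap, tiny_map(n, chroms, length_mb),
                           seed = seed, ...)
}

# A small two-ancestry admixed cohort with haplotypes + local ancestry,
# no genotype risk (null phenotype), reused across ancestry-aware tests.
null_admixed_cohort <- function() {
  cached("null_admixed_cohort", {
    pan <- tiny_panel(k = 2, fst = c(0.15, 0.15), n_hap = 60, n = 80,
                      chroms = c("1", "2"), seed = 21)
    scen <- admixture_scenario(pan, c(0.6, 0.4), generations = 5, n_out = 150)
    simulate_case_control(scen, risk_loci(character(), character(),
                                          numeric(), numeric()),
                          n_cases = 100, n_controls = 100, seed = 31,
                          params = gametogenesis_params(mutation_rate = 0))
  })
}

# Null homogeneous cohort for calibration-style checks.
null_hom_cohort <- function(n_cases = 150, n_controls = 150, seed = 41) {
  cached(paste0("null_hom_", n_cases, "_", seed), {
    pan <- tiny_panel(k = 1, fst = 0.05, n_hap = 60, n = 150,
                      chroms = c("1", "2"), seed = 51)
    simulate_case_control(pan, risk_loci(character(), character(),
                                         numeric(), numeric()),
                          n_cases = n_cases, n_controls = n_controls,
                          seed = seed)
  })
}

# Build a cohort directly from matrices (for exact-arithmetic tests).
manual_cohort <- function(genotypes, phenotype, map = NULL,
                          haplotypes = NULL, la_assign = NULL) {
  if (is.null(map)) map <- tiny_map(ncol(genotypes))
  co <- gwasim:::new_cohort(genotypes, phenotype, map,
                            haplotypes = haplotypes)
  if (!is.null(la_assign)) co$la <- local_ancestry(la_assign, map)
  co
}
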