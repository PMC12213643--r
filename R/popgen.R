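#' Gametogenesis parameters
#'
#' @param recomb Logical; if `TRUE` crossovers are placed by a Poisson process
#'   on the genetic map (rate 1 crossover per 100 cM, no interference). If
#'   `FALSE` gametes copy a whole parental haplotype.
#' @param mutation_rate Per-site, per-meiosis allele flip probability in
#'   `[0, 0.01]`. Default `1e-8`, a human-scale per-generation rate.
#' @return A `gametogenesis_params` list.
#' @examples
#' gametogenesis_params(mutation_rate = 0)
#' @export
gametogenesis_params <- function(recomb = TRUE, mutation_rate = 1e-8) {
  if (mutation_rate < 0 || mutation_rate > 0.01) {
    abort("mutation_rate must lie in [0, 0.01]")
  }
  structure(list(recomb = isTRUE(recomb), mutation_rate = mutation_rate),
            class = "gametogenesis_params")
}

# Precompute per-chromosome structure used by the fast meiosis path.
chrom_structure <- function(map) {
  idx <- map_chrom_index(map)
  lapply(idx, function(sites) {
    cm <- map$pos_cm[sites]
    list(sites = sites, cm = cm, cm_min = cm[1], cm_max = cm[length(cm)],
         len = cm[length(cm)] - cm[1])
  })
}

# One meiosis: returns list(take_a = logical over all sites, breaks = numeric
# cM positions). Vectorised over sites within each chromosome.
meiosis_take <- function(cs, recomb, want_breaks = FALSE) {
  n_sites <- sum(vapply(cs, function(x) length(x$sites), 1L))
  take <- logical(n_sites)
  breaks <- if (want_breaks) list() else NULL
  for (ch in seq_along(cs)) {
    x <- cs[[ch]]
    coin <- sample.int(2L, 1L) - 1L
    nx <- if (recomb && x$len > 0) rpois(1L, x$len / 100) else 0L
    if (nx == 0L) {
      take[x$sites] <- coin == 0L
    } else {
      u <- sort(runif(nx, x$cm_min, x$cm_max))
      seg <- (coin + findInterval(x$cm, u)) %% 2L
      take[x$sites] <- seg == 0L
      if (want_breaks) {
        breaks[[length(breaks) + 1L]] <-
          data.frame(chrom = names(cs)[ch], cm = u)
      }
    }
  }
  if (want_breaks) {
    breaks <- if (length(breaks)) tibble::as_tibble(dplyr::bind_rows(breaks))
    else tibble::tibble(chrom = character(), cm = numeric())
  }
  list(take_a = take, breaks = breaks)
}

#' Simulate one meiosis
#'
#' Produces a gamete from two aligned parental haplotypes. Crossover counts
#' per chromosome are Poisson with mean `total cM / 100`; breakpoints are
#' uniform on the genetic (cM) scale; the gamete copies alternating parental
#' segments starting from a fair-coin choice; each emitted allele is then
#' flipped independently with probability `mutation_rate`. If local-ancestry
#' labels are supplied for the parents they are propagated segment-wise
#' (mutation does not alter ancestry).
#'
#' @param parent_hap_a,parent_hap_b Integer 0/1 vectors over the map's sites.
#' @param variant_map A [variant_map()].
#' @param params A [gametogenesis_params()].
#' @param seed Integer seed.
#' @param anc_a,anc_b Optional integer ancestry labels aligned to the parents.
#' @return List with `gamete`, `breakpoints` (tibble of chrom / cM positions),
#'   and `ancestry` (or `NULL`).
#' @examples
#' map <- default_variant_map(n_snps_per_chrom = 20, chroms = "1")
#' a <- rep(0L, 20); b <- rep(1L, 20)
#' meiosis(a, b, map, gametogenesis_params(mutation_rate = 0), seed = 1)$gamete
#' @export
meiosis <- function(parent_hap_a, parent_hap_b, variant_map,
                    params = gametogenesis_params(), seed = 1,
                    anc_a = NULL, anc_b = NULL) {
  if (length(parent_hap_a) != nrow(variant_map) ||
      length(parent_hap_b) != nrow(variant_map)) {
    abort("parent haplotypes must be aligned to the variant map")
  }
  cs <- chrom_structure(variant_map)
  with_child_seed(seed, "meiosis", 0L, {
    mt <- meiosis_take(cs, params$recomb, want_breaks = TRUE)
    g <- ifelse(mt$take_a, parent_hap_a, parent_hap_b)
    anc <- if (!is.null(anc_a)) ifelse(mt$take_a, anc_a, anc_b) else NULL
    g <- apply_mutation(g, params$mutation_rate)
    list(gamete = as.integer(g), breakpoints = mt$breaks, ancestry = anc)
  })
}

apply_mutation <- function(g, mu) {
  if (mu <= 0) return(g)
  n_flip <- rbinom(1L, length(g), mu)
  if (n_flip > 0L) {
    at <- sample.int(length(g), n_flip)
    g[at] <- 1L - g[at]
  }
  g
}

# Internal: draw n_off offspring (diploid) from a parental pool.
# pool_h: 2P x M haplotypes; pool_anc: 2P x M ancestry or NULL.
# Returns list(h = 2*n_off x M, anc = matrix or NULL).
mate_pool <- function(pool_h, pool_anc, cs, params, n_off) {
  n_par <- nrow(pool_h) / 2L
  if (n_par < 2) abort("fewer than 2 individuals available for mating")
  m <- ncol(pool_h)
  out_h <- matrix(0L, nrow = 2L * n_off, ncol = m)
  out_anc <- if (!is.null(pool_anc)) matrix(0L, nrow = 2L * n_off, ncol = m) else NULL
  for (i in seq_len(n_off)) {
    pr <- sample.int(n_par, 2L, replace = FALSE) # selfing excluded
    for (j in 1:2) {
      r1 <- 2L * pr[j] - 1L
      mt <- meiosis_take(cs, params$recomb)
      ha <- pool_h[r1, ]; hb <- pool_h[r1 + 1L, ]
      g <- ha; g[!mt$take_a] <- hb[!mt$take_a]
      g <- apply_mutation(g, params$mutation_rate)
      out_h[2L * i - 2L + j, ] <- g
      if (!is.null(out_anc)) {
        aa <- pool_anc[r1, ]; ab <- pool_anc[r1 + 1L, ]
        av <- aa; av[!mt$take_a] <- ab[!mt$take_a]
        out_anc[2L * i - 2L + j, ] <- av
      }
    }
  }
  list(h = out_h, anc = out_anc)
}

new_haplotype_set <- function(haplotypes, map, ancestry = NULL, hap_ids = NULL,
                              n_pops = NULL) {
  storage.mode(haplotypes) <- "integer"
  if (is.null(hap_ids)) {
    hap_ids <- paste0("ind", rep(seq_len(nrow(haplotypes) / 2L), each = 2L),
                      "_h", rep(1:2, times = nrow(haplotypes) / 2L))
  }
  structure(list(haplotypes = haplotypes, map = map, ancestry = ancestry,
                 hap_ids = hap_ids, n_pops = n_pops),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("<haplotype_set> ", nrow(x$haplotypes), " haplotypes x ",
      ncol(x$haplotypes), " sites",
      if (!is.null(x$ancestry)) " (with local-ancestry labels)", "\n", sep = "")
  invisible(x)
}

#' Grow a homogeneous population by resampling with recombination
#'
#' Each offspring is formed from two distinct parent individuals drawn
#' uniformly with replacement from the reference panel (one gamete per parent
#' via [meiosis()]). The resampling retains the panel's allele frequencies
#' (within binomial error) and its local LD.
#'
#' @param panel A `reference_panel` (optionally restricted to one population
#'   via `pop`).
#' @param n_out Number of diploid offspring.
#' @param params [gametogenesis_params()].
#' @param seed Integer seed.
#' @param pop Optional 0-based population index to grow from.
#' @return A `haplotype_set` with `2 * n_out` haplotypes.
#' @examples
#' map <- default_variant_map(n_snps_per_chrom = 20, chroms = "1")
#' pan <- generate_reference_panel(1, 0.05, 20, map, seed = 1)
#' off <- grow_homogeneous(pan, n_out = 10, seed = 2)
#' @export
grow_homogeneous <- function(panel, n_out, params = gametogenesis_params(),
                             seed = 1, pop = NULL) {
  stopifnot(inherits(panel, "reference_panel"))
  if (n_out <= 0) abort("n_out must be positive")
  h <- panel$haplotypes
  if (!is.null(pop)) h <- h[panel$pop_labels == pop, , drop = FALSE]
  if (nrow(h) < 4) abort("panel too small: need >= 2 diploid individuals")
  cs <- chrom_structure(panel$map)
  with_child_seed(seed, "grow_homogeneous", 0L, {
    off <- mate_pool(h, NULL, cs, params, as.integer(n_out))
    new_haplotype_set(off$h, panel$map)
  })
}

#' Define a single-point admixture scenario
#'
#' Admixture happens once: a founding pool is assembled at generation 0 by
#' sampling whole individuals from the parental populations with the given
#' proportions, and the pool then interbreeds (random mating, selfing
#' excluded, constant size) for `generations` rounds. The cohort is the pool
#' after the final round.
#'
#' @param parental_panels A single `reference_panel` whose populations are the
#'   ancestries, or a list of single-population panels sharing one variant
#'   map.
#' @param proportions Ancestry contribution proportions (sum to 1).
#' @param generations Number of random-mating generations `G >= 1`
#'   (default 10).
#' @param n_out Diploid cohort (and pool) size.
#' @return An `admixture_scenario` list.
#' @export
admixture_scenario <- function(parental_panels, proportions, generations = 10,
                               n_out) {
  panel <- merge_parental_panels(parental_panels)
  k <- length(panel$pop_names)
  proportions <- as.numeric(proportions)
  if (length(proportions) != k) {
    abort("proportions must have one entry per parental population")
  }
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9) {
    abort("proportions must be non-negative and sum to 1")
  }
  if (generations < 1) abort("generations must be >= 1")
  if (n_out < 2) abort("n_out must be >= 2 (fewer than 2 founding individuals)")
  structure(list(panel = panel, proportions = proportions,
                 generations = as.integer(generations),
                 n_out = as.integer(n_out)),
            class = "admixture_scenario")
}

merge_parental_panels <- function(x) {
  if (inherits(x, "reference_panel")) return(x)
  stopifnot(is.list(x), all(vapply(x, inherits, TRUE, "reference_panel")))
  map <- x[[1]]$map
  for (p in x[-1]) {
    if (!identical(p$map$id, map$id)) {
      abort("parental panels must share one variant map (intersect first)")
    }
  }
  hap <- do.call(rbind, lapply(x, `[[`, "haplotypes"))
  labels <- unlist(lapply(seq_along(x), function(i) {
    rep(i - 1L, nrow(x[[i]]$haplotypes))
  }))
  names <- vapply(seq_along(x), function(i) {
    if (length(x[[i]]$pop_names) == 1L) x[[i]]$pop_names else paste0("anc", i - 1L)
  }, "")
  new_reference_panel(hap, map, labels, names)
}

# Build the generation-0 founding pool for a scenario. Returns list(h, anc).
founding_pool <- function(scenario) {
  panel <- scenario$panel
  k <- length(scenario$proportions)
  n <- scenario$n_out
  pop_of_founder <- sample.int(k, n, replace = TRUE, prob = scenario$proportions) - 1L
  h <- matrix(0L, nrow = 2L * n, ncol = ncol(panel$haplotypes))
  anc <- matrix(0L, nrow = 2L * n, ncol = ncol(panel$haplotypes))
  for (kk in unique(pop_of_founder)) {
    rows_k <- which(panel$pop_labels == kk)
    ind_k <- matrix(rows_k, nrow = 2L) # columns = individuals
    take <- which(pop_of_founder == kk)
    picks <- sample.int(ncol(ind_k), length(take), replace = TRUE)
    for (t in seq_along(take)) {
      i <- take[t]
      h[2L * i - 1L, ] <- panel$haplotypes[ind_k[1L, picks[t]], ]
      h[2L * i, ] <- panel$haplotypes[ind_k[2L, picks[t]], ]
      anc[c(2L * i - 1L, 2L * i), ] <- kk
    }
  }
  list(h = h, anc = anc)
}

#' Simulate single-point multi-way admixture with exact ancestry tracking
#'
#' Runs the scenario: founding pool sampled with the scenario proportions,
#' then `generations` rounds of random mating via [meiosis()]. Every site of
#' every final haplotype carries its true ancestral population of origin;
#' expected global ancestry equals the scenario proportions.
#'
#' @param scenario An [admixture_scenario()].
#' @param params [gametogenesis_params()].
#' @param seed Integer seed.
#' @return A `haplotype_set` whose `ancestry` matrix holds truth labels;
#'   use [local_ancestry()] to obtain the tract representation.
#' @export
simulate_admixture <- function(scenario, params = gametogenesis_params(),
                               seed = 1) {
  stopifnot(inherits(scenario, "admixture_scenario"))
  cs <- chrom_structure(scenario$panel$map)
  with_child_seed(seed, "simulate_admixture", 0L, {
    pool <- founding_pool(scenario)
    for (g in seq_len(scenario$generations)) {
      pool <- mate_pool(pool$h, pool$anc, cs, params, scenario$n_out)
    }
    new_haplotype_set(pool$h, scenario$panel$map, ancestry = pool$anc,
                      n_pops = length(scenario$proportions))
  })
}

# A lazily-mated admixed population: pool evolved for G-1 generations; cohort
# candidates are drawn as generation-G offspring on demand. Used by the
# case-control rejection sampler.
admixture_source <- function(scenario, params = gametogenesis_params(),
                             seed = 1) {
  cs <- chrom_structure(scenario$panel$map)
  pool <- with_child_seed(seed, "admixture_source", 0L, {
    p <- founding_pool(scenario)
    for (g in seq_len(scenario$generations - 1L)) {
      p <- mate_pool(p$h, p$anc, cs, params, scenario$n_out)
    }
    p
  })
  counter <- 0L
  list(
    map = scenario$panel$map,
    n_pops = length(scenario$proportions),
    panel = scenario$panel,
    proportions = scenario$proportions,
    draw = function(n) {
      counter <<- counter + 1L
      with_child_seed(seed, "admixture_source_draw", counter, {
        mate_pool(pool$h, pool$anc, cs, params, n)
      })
    }
  )
}

# Homogeneous analogue: candidates are offspring of panel individuals.
homogeneous_source <- function(panel, params = gametogenesis_params(),
                               seed = 1, pop = NULL) {
  h <- panel$haplotypes
  if (!is.null(pop)) h <- h[panel$pop_labels == pop, , drop = FALSE]
  cs <- chrom_structure(panel$map)
  counter <- 0L
  list(
    map = panel$map,
    n_pops = NULL,
    draw = function(n) {
      counter <<- counter + 1L
      with_child_seed(seed, "homogeneous_source_draw", counter, {
        mate_pool(h, NULL, cs, params, n)
      })
    }
  )
}
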