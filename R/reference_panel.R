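#' Generate a synthetic multi-population reference haplotype panel
#'
#' Stands in for a merged real-data reference panel (e.g. several European
#' plus West African populations). Per-population allele frequencies follow
#' the Balding-Nichols model: the ancestral frequency of each site is drawn
#' from Uniform(0.05, 0.95) and the frequency in population `k` from
#' Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k), where `F_k` is that population's
#' divergence (FST) from the ancestral pool.
#'
#' Local linkage disequilibrium is induced by a first-order founder-copying
#' walk: each population carries a pool of `n_founders` founder haplotypes
#' whose per-site allele counts quantise the Balding-Nichols frequencies, and
#' every emitted haplotype copies along the chromosome from one founder at a
#' time, switching to a random founder between adjacent sites with probability
#' `1 - exp(-d_cM / ld_block_len)`. This yields positive r-squared decaying
#' with genetic distance at scale `ld_block_len` plus a long-range floor from
#' the finite pool, without the realised population frequencies drifting away
#' from the Balding-Nichols draws.
#'
#' Sites whose overall minor allele frequency falls below `maf_min` are
#' redrawn (common-SNP panel).
#'
#' @param k_pops Number of populations (>= 1).
#' @param fst Numeric vector of length `k_pops`, divergence per population,
#'   each in (0, 1).
#' @param n_hap_per_pop Haplotypes per population; must be even (diploid
#'   pairs). Scalar or length `k_pops`.
#' @param variant_map A [variant_map()].
#' @param ld_block_len Mean LD block length in cM (default 0.1).
#' @param n_founders Founder pool size per population (default 20).
#' @param maf_min Minor allele frequency floor in the emitted panel.
#' @param pop_names Optional population names.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A `reference_panel` object: list with `haplotypes` (2N x M 0/1
#'   integer matrix), `map`, `pop_labels` (0-based population index per
#'   haplotype), `pop_names`, and cached `allele_freqs` (K x M).
#' @examples
#' map <- default_variant_map(n_snps_per_chrom = 30, chroms = "1")
#' pan <- generate_reference_panel(2, fst = c(0.05, 0.1), n_hap_per_pop = 20,
#'                                 variant_map = map, seed = 1)
#' dim(pan$haplotypes)
#' @export
generate_reference_panel <- function(k_pops, fst, n_hap_per_pop, variant_map,
                                     ld_block_len = 0.1, n_founders = 20,
                                     maf_min = 0.01, pop_names = NULL,
                                     seed = 1) {
  if (!is.numeric(k_pops) || length(k_pops) != 1L || k_pops < 1) {
    abort("k_pops must be a single count >= 1")
  }
  k_pops <- as.integer(k_pops)
  fst <- as.numeric(fst)
  if (length(fst) == 1L) fst <- rep(fst, k_pops)
  if (length(fst) != k_pops) abort("fst must have one entry per population")
  if (any(fst <= 0 | fst >= 1)) abort("fst entries must lie in (0, 1)")
  n_hap_per_pop <- as.integer(rep_len(n_hap_per_pop, k_pops))
  if (any(n_hap_per_pop <= 0) || any(n_hap_per_pop %% 2L != 0L)) {
    abort("n_hap_per_pop must be positive and even (diploid pairs)")
  }
  validate_variant_map(variant_map)
  if (ld_block_len < 0) abort("ld_block_len must be non-negative")
  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(k_pops) - 1L)

  m_sites <- nrow(variant_map)
  n_total <- sum(n_hap_per_pop)
  pop_labels <- rep(seq_len(k_pops) - 1L, times = n_hap_per_pop)
  chrom_idx <- map_chrom_index(variant_map)

  with_child_seed(seed, "generate_reference_panel", 0L, {
    # Balding-Nichols frequencies, with MAF-floor resampling on the overall
    # (weighted mean) frequency.
    w <- n_hap_per_pop / n_total
    draw_freqs <- function(m) {
      p <- runif(m, 0.05, 0.95)
      f <- matrix(0, nrow = k_pops, ncol = m)
      for (k in seq_len(k_pops)) {
        a <- p * (1 - fst[k]) / fst[k]
        b <- (1 - p) * (1 - fst[k]) / fst[k]
        f[k, ] <- rbeta(m, a, b)
      }
      f
    }
    freqs <- draw_freqs(m_sites)
    for (iter in 1:50) {
      overall <- as.numeric(w %*% freqs)
      bad <- which(pmin(overall, 1 - overall) < maf_min)
      if (length(bad) == 0L) break
      freqs[, bad] <- draw_freqs(length(bad))
    }

    # Founder pools: per site, quantise n_founders * f to an allele count with
    # a stochastic remainder, then scatter the alt alleles over founders.
    draw_founders <- function(fr) {
      founders <- matrix(0L, nrow = n_founders, ncol = length(fr))
      target <- n_founders * fr
      cnt <- floor(target) + (runif(length(fr)) < (target - floor(target)))
      for (m in which(cnt > 0)) {
        founders[sample.int(n_founders, cnt[m]), m] <- 1L
      }
      founders
    }
    haplotypes <- matrix(0L, nrow = n_total, ncol = m_sites)
    founder_sets <- vector("list", k_pops)
    fid_sets <- vector("list", k_pops)
    for (k in seq_len(k_pops)) {
      rows <- which(pop_labels == k - 1L)
      founders <- draw_founders(freqs[k, ])
      fid_all <- matrix(0L, nrow = length(rows), ncol = m_sites)
      # Copying walk along each chromosome.
      for (sites in chrom_idx) {
        cm <- variant_map$pos_cm[sites]
        d <- diff(cm)
        p_switch <- if (ld_block_len > 0) 1 - exp(-d / ld_block_len) else rep(1, length(d))
        for (hi in seq_along(rows)) {
          n_s <- length(sites)
          switches <- c(TRUE, runif(n_s - 1L) < p_switch)
          # founder id per site: new uniform draw at each switch, carried
          # forward between switches
          ids <- cumsum(switches)
          draws <- sample.int(n_founders, max(ids), replace = TRUE)
          fid <- draws[ids]
          fid_all[hi, sites] <- fid
          haplotypes[rows[hi], sites] <- founders[cbind(fid, sites)]
        }
      }
      founder_sets[[k]] <- founders
      fid_sets[[k]] <- fid_all
    }
    # Enforce the MAF floor on the emitted panel: sites still below the floor
    # after copying get fresh frequency draws and founder columns, re-read
    # through the stored founder-copying paths (so LD structure is intact).
    for (iter in 1:50) {
      overall <- colMeans(haplotypes)
      bad <- which(pmin(overall, 1 - overall) < maf_min)
      if (length(bad) == 0L) break
      freqs[, bad] <- draw_freqs(length(bad))
      for (k in seq_len(k_pops)) {
        rows <- which(pop_labels == k - 1L)
        fnd <- draw_founders(freqs[k, bad])
        fid <- fid_sets[[k]][, bad, drop = FALSE]
        for (b in seq_along(bad)) {
          haplotypes[rows, bad[b]] <- fnd[fid[, b], b]
        }
      }
    }
    new_reference_panel(haplotypes, variant_map, pop_labels, pop_names)
  })
}

new_reference_panel <- function(haplotypes, map, pop_labels, pop_names) {
  storage.mode(haplotypes) <- "integer"
  structure(
    list(
      haplotypes = haplotypes,
      map = map,
      pop_labels = as.integer(pop_labels),
      pop_names = as.character(pop_names),
      allele_freqs = panel_allele_freqs(haplotypes, pop_labels)
    ),
    class = "reference_panel"
  )
}

# K x M per-population alt-allele frequencies from a haplotype matrix.
panel_allele_freqs <- function(haplotypes, pop_labels) {
  ks <- sort(unique(pop_labels))
  out <- matrix(0, nrow = length(ks), ncol = ncol(haplotypes))
  for (i in seq_along(ks)) {
    out[i, ] <- colMeans(haplotypes[pop_labels == ks[i], , drop = FALSE])
  }
  out
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("<reference_panel> ", nrow(x$haplotypes), " haplotypes x ",
      ncol(x$haplotypes), " sites; ", length(x$pop_names), " population(s): ",
      paste0(x$pop_names, " (", tabulate(x$pop_labels + 1L), ")", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Squared correlation (r-squared) between two sites
#'
#' Classical LD measure: `r2 = D^2 / (pA(1-pA) pB(1-pB))` with `D` the
#' haplotype-frequency covariance, equal to the squared Pearson correlation of
#' the two binary haplotype columns.
#'
#' @param haplotypes A haplotype matrix (rows = haplotypes) restricted to, or
#'   indexed at, two sites.
#' @param i,j Column indices of the two sites (default 1 and 2).
#' @return r-squared in \[0, 1\].
#' @examples
#' h <- cbind(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' compute_ld_r2(h)
#' @export
compute_ld_r2 <- function(haplotypes, i = 1L, j = 2L) {
  a <- as.numeric(haplotypes[, i])
  b <- as.numeric(haplotypes[, j])
  pa <- mean(a); pb <- mean(b)
  if (pa == 0 || pa == 1 || pb == 0 || pb == 1) {
    abort("undefined LD: at least one site is monomorphic in the supplied haplotypes")
  }
  d <- mean(a * b) - pa * pb
  d^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Hudson FST estimator between two panel populations
#'
#' Ratio-of-averages Hudson estimator over all sites polymorphic in the pooled
#' pair, with the usual finite-sample correction of the numerator.
#'
#' @param panel A `reference_panel`.
#' @param pop_a,pop_b Distinct 0-based population indices.
#' @return FST estimate (float; can be slightly negative at zero divergence).
#' @examples
#' map <- default_variant_map(n_snps_per_chrom = 200, chroms = "1")
#' pan <- generate_reference_panel(2, fst = c(0.1, 0.1), n_hap_per_pop = 100,
#'                                 variant_map = map, seed = 7)
#' hudson_fst(pan, 0, 1)
#' @export
hudson_fst <- function(panel, pop_a, pop_b) {
  stopifnot(inherits(panel, "reference_panel"))
  if (pop_a == pop_b) abort("pop_a and pop_b must differ")
  ra <- panel$pop_labels == pop_a
  rb <- panel$pop_labels == pop_b
  n1 <- sum(ra); n2 <- sum(rb)
  if (n1 < 2 || n2 < 2) abort("both populations need >= 2 haplotypes")
  p1 <- colMeans(panel$haplotypes[ra, , drop = FALSE])
  p2 <- colMeans(panel$haplotypes[rb, , drop = FALSE])
  pooled <- (n1 * p1 + n2 * p2) / (n1 + n2)
  poly <- pooled > 0 & pooled < 1
  if (!any(poly)) abort("no polymorphic sites in the pooled pair")
  p1 <- p1[poly]; p2 <- p2[poly]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}
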