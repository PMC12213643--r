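#' Define risk loci
#'
#' A risk-locus table drives the logistic penetrance model. Relative risks are
#' genotype-class odds ratios inside the logistic model (`rr_het` for one alt
#' allele, `rr_hom` for two), honoured independently rather than through an
#' additive coding, so dominance patterns can be expressed. At low prevalence
#' the odds ratio approximates the relative risk.
#'
#' @param snp_id Variant identifiers.
#' @param chrom Chromosome labels.
#' @param rr_het,rr_hom Heterozygote / homozygote odds ratios (> 0;
#'   protective values < 1 allowed).
#' @param partner_id Optional tag-SNP partner in complete LD (same
#'   chromosome), used by replication designs.
#' @param signal_class One of `"strong"`, `"weak"`, `"null"`.
#' @return A tibble of class `risk_loci`.
#' @examples
#' risk_loci("rs1", "2", rr_het = 1.5, rr_hom = 2.25)
#' @export
risk_loci <- function(snp_id, chrom, rr_het, rr_hom,
                      partner_id = NA_character_, signal_class = "strong") {
  out <- tibble::tibble(
    snp_id = as.character(snp_id), chrom = as.character(chrom),
    rr_het = as.numeric(rr_het), rr_hom = as.numeric(rr_hom),
    partner_id = as.character(partner_id),
    signal_class = as.character(signal_class))
  if (any(out$rr_het <= 0) || any(out$rr_hom <= 0)) {
    abort("relative risks rr_het and rr_hom must be > 0")
  }
  if (!all(out$signal_class %in% c("strong", "weak", "null"))) {
    abort("signal_class must be one of strong, weak, null")
  }
  class(out) <- c("risk_loci", class(tibble::tibble()))
  out
}

#' Ancestry-risk specification
#'
#' Describes a region in which cases carry an elevated probability of a target
#' ancestry: during case formation, each case haplotype's segment overlapping
#' the region is re-drawn from ancestry `ancestry` with probability
#' `pi_a + deviation` (where `pi_a` is the cohort-level proportion of that
#' ancestry), while controls are left at `pi_a`. The realised case-minus-
#' control mean local ancestry in the region then equals `deviation` up to
#' sampling error, and ancestry outside the region is untouched in
#' expectation.
#'
#' @param chrom Chromosome label.
#' @param start_bp,end_bp Half-open region bounds (1-based bp).
#' @param ancestry 0-based target ancestry index.
#' @param deviation Target case-control mean difference, in `(-1, 1)`
#'   (conventionally 0.05 weak, 0.15 strong, 0.25 very strong).
#' @param strength_class Label: `"strong"`, `"weak"`, or `"none"`.
#' @return A tibble of class `ancestry_risk_spec`.
#' @export
ancestry_risk_spec <- function(chrom, start_bp, end_bp, ancestry, deviation,
                               strength_class = "strong") {
  if (any(abs(deviation) >= 1)) abort("deviation must lie in (-1, 1)")
  out <- tibble::tibble(
    chrom = as.character(chrom), start_bp = as.numeric(start_bp),
    end_bp = as.numeric(end_bp), ancestry = as.integer(ancestry),
    deviation = as.numeric(deviation),
    strength_class = as.character(strength_class))
  class(out) <- c("ancestry_risk_spec", class(tibble::tibble()))
  out
}

#' Logistic multi-locus penetrance
#'
#' `logit P(case) = baseline_logit + sum over loci of
#' log(rr_het) 1(g = 1) + log(rr_hom) 1(g = 2)` — genotype-class coding, so
#' heterozygote and homozygote odds ratios act independently.
#'
#' @param genotypes Vector (one individual) or N x L matrix of alt-allele
#'   counts at the risk loci, columns in `loci` order.
#' @param loci A [risk_loci()] table.
#' @param baseline_logit Baseline log-odds of disease.
#' @return Case probability (vector of length N).
#' @examples
#' loc <- risk_loci("rs1", "2", 1.5, 2.25)
#' penetrance(matrix(0:2, ncol = 1), loc, stats::qlogis(0.1))
#' @export
penetrance <- function(genotypes, loci, baseline_logit) {
  if (!is.finite(baseline_logit)) abort("baseline_logit must be finite")
  g <- if (is.matrix(genotypes)) genotypes else matrix(genotypes, ncol = nrow(loci))
  if (ncol(g) != nrow(loci)) abort("genotype columns must match the loci table")
  eta <- rep(baseline_logit, nrow(g))
  for (l in seq_len(nrow(loci))) {
    eta <- eta + log(loci$rr_het[l]) * (g[, l] == 1) +
      log(loci$rr_hom[l]) * (g[, l] == 2)
  }
  stats::plogis(eta)
}

#' Calibrate the baseline logit to a target prevalence
#'
#' One-dimensional monotone root-find of `mean(penetrance(sample)) =
#' target_prevalence`.
#'
#' @param genotype_sample N x L matrix of genotypes at the risk loci drawn
#'   from the source population.
#' @param loci [risk_loci()] table.
#' @param target_prevalence Target disease prevalence in (0, 1).
#' @return The calibrated baseline logit (mean penetrance matches the target
#'   within 1e-6).
#' @export
calibrate_baseline <- function(genotype_sample, loci, target_prevalence) {
  if (target_prevalence <= 0 || target_prevalence >= 1) {
    abort("target_prevalence must lie in (0, 1)")
  }
  g <- as.matrix(genotype_sample)
  f <- function(b0) mean(penetrance(g, loci, b0)) - target_prevalence
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0) abort("cannot bracket the baseline (degenerate sample)")
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Select a tag-SNP pair by LD in a design population
#'
#' Scans SNP pairs on a chromosome in position order and returns the first
#' pair whose r-squared in the design population (`hap_a`) reaches `r2_min`,
#' reporting the realised r-squared in both populations (population-specific
#' LD means the second population's value may be lower). The search is
#' deterministic given fixed inputs.
#'
#' @param hap_a,hap_b Haplotype matrices for the design and second population,
#'   aligned to `map`.
#' @param map Shared [variant_map()].
#' @param chrom Chromosome to search.
#' @param r2_min Minimum r-squared in the design population.
#' @param max_span Maximum index separation searched per anchor SNP.
#' @return Tibble row: `snp_x`, `snp_y`, `r2_a`, `r2_b`.
#' @export
select_tag_pair <- function(hap_a, hap_b, map, chrom, r2_min = 1,
                            max_span = 50L) {
  sites <- which(map$chrom == as.character(chrom))
  if (length(sites) < 2) abort("chromosome has fewer than two shared variants")
  poly_a <- colMeans(hap_a[, sites, drop = FALSE])
  ok <- poly_a > 0 & poly_a < 1
  for (ii in seq_len(length(sites) - 1L)) {
    if (!ok[ii]) next
    for (jj in seq(ii + 1L, min(ii + max_span, length(sites)))) {
      if (!ok[jj]) next
      r2a <- compute_ld_r2(hap_a, sites[ii], sites[jj])
      if (r2a >= r2_min - 1e-12) {
        pb <- colMeans(hap_b[, sites[c(ii, jj)], drop = FALSE])
        r2b <- if (all(pb > 0 & pb < 1)) {
          compute_ld_r2(hap_b, sites[ii], sites[jj])
        } else NA_real_
        return(tibble::tibble(snp_x = map$id[sites[ii]],
                              snp_y = map$id[sites[jj]],
                              r2_a = r2a, r2_b = r2b))
      }
    }
  }
  abort("design infeasible: no pair reaches r2_min; try a lower r2_min")
}

#' Manufacture a complete-LD tag pair in a reference panel
#'
#' Natural `r2 = 1` pairs may not exist in a small synthetic panel, so the
#' pair is manufactured: the partner column (the next SNP on the chromosome)
#' is overwritten with a copy of the anchor column in the populations listed
#' in `ld_pops`, and with a mutated copy (independent flips with probability
#' `flip_prob`) in the remaining populations, giving high but imperfect LD
#' there.
#'
#' @param panel A `reference_panel`.
#' @param chrom Chromosome on which to place the pair.
#' @param ld_pops 0-based population indices in which the pair is in complete
#'   LD.
#' @param flip_prob Per-haplotype flip probability in the other populations.
#' @param maf_target Anchor SNPs are chosen as the variant nearest
#'   mid-chromosome with overall MAF at least this value.
#' @param seed Integer seed.
#' @return List: modified `panel`, `snp_x`, `snp_y` (ids).
#' @export
manufacture_tag_pair <- function(panel, chrom, ld_pops = 0L, flip_prob = 0.1,
                                 maf_target = 0.2, seed = 1) {
  stopifnot(inherits(panel, "reference_panel"))
  sites <- which(panel$map$chrom == as.character(chrom))
  if (length(sites) < 2) abort("chromosome has fewer than two variants")
  anchor <- pick_risk_site(panel, chrom, maf_target)
  at <- match(anchor, sites)
  partner <- if (at < length(sites)) sites[at + 1L] else sites[at - 1L]
  h <- panel$haplotypes
  with_child_seed(seed, "manufacture_tag_pair", 0L, {
    for (k in sort(unique(panel$pop_labels))) {
      rows <- panel$pop_labels == k
      col <- h[rows, anchor]
      if (!(k %in% ld_pops)) {
        flip <- runif(length(col)) < flip_prob
        col[flip] <- 1L - col[flip]
      }
      h[rows, partner] <- col
    }
    pan2 <- new_reference_panel(h, panel$map, panel$pop_labels, panel$pop_names)
    list(panel = pan2, snp_x = panel$map$id[anchor],
         snp_y = panel$map$id[partner])
  })
}

# Variant nearest mid-chromosome with overall MAF >= maf_target (falling back
# to the most common variant if none qualifies).
pick_risk_site <- function(panel, chrom, maf_target = 0.2) {
  sites <- which(panel$map$chrom == as.character(chrom))
  p <- colMeans(panel$haplotypes[, sites, drop = FALSE])
  maf <- pmin(p, 1 - p)
  mid <- (panel$map$pos_bp[sites[1]] + panel$map$pos_bp[sites[length(sites)]]) / 2
  cand <- which(maf >= maf_target)
  if (length(cand) == 0L) cand <- which(maf == max(maf))
  sites[cand[which.min(abs(panel$map$pos_bp[sites[cand]] - mid))]]
}

new_cohort <- function(genotypes, phenotype, map, sample_ids = NULL,
                       haplotypes = NULL, la = NULL, provenance = list()) {
  storage.mode(genotypes) <- "integer"
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(nrow(genotypes)))
  structure(list(genotypes = genotypes, phenotype = as.integer(phenotype),
                 sample_ids = sample_ids, map = map, haplotypes = haplotypes,
                 la = la, provenance = provenance),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$genotypes), " individuals x ", ncol(x$genotypes),
      " SNPs; ", sum(x$phenotype == 1L), " cases / ",
      sum(x$phenotype == 0L), " controls",
      if (!is.null(x$la)) "; local ancestry attached", "\n", sep = "")
  invisible(x)
}

#' Simulate a case-control cohort by rejection sampling
#'
#' Individuals are generated from the haplotype source, assigned case status
#' by a Bernoulli draw on their multi-locus logistic penetrance (baseline
#' calibrated so the source-population prevalence equals
#' `target_prevalence`), and accumulated until the case and control quotas
#' are both met exactly; surplus individuals are discarded. If
#' `ancestry_risk` rows are supplied (admixed sources only), accepted cases
#' additionally have their haplotype segments in each risk region re-drawn
#' from the parental panels with the elevated target-ancestry probability.
#'
#' @param source A source created by [homogeneous_source()] or
#'   [admixture_source()], or a `reference_panel` (wrapped as a homogeneous
#'   source), or an [admixture_scenario()].
#' @param loci [risk_loci()] table (may have zero rows for a null cohort).
#' @param n_cases,n_controls Exact quotas.
#' @param target_prevalence Disease prevalence in the source population
#'   (default 0.10).
#' @param seed Integer seed.
#' @param ancestry_risk Optional [ancestry_risk_spec()] table.
#' @param params [gametogenesis_params()] used when `source` needs wrapping.
#' @param keep_haplotypes Retain phased haplotypes (required by the
#'   local-ancestry-aware tests).
#' @param batch Candidate batch size.
#' @return A `cohort` object with exact phenotype counts.
#' @export
simulate_case_control <- function(source, loci, n_cases, n_controls,
                                  target_prevalence = 0.1, seed = 1,
                                  ancestry_risk = NULL,
                                  params = gametogenesis_params(),
                                  keep_haplotypes = TRUE, batch = 500L) {
  if (n_cases <= 0 || n_controls <= 0) abort("requested counts must be > 0")
  if (inherits(source, "reference_panel")) {
    source <- homogeneous_source(source, params, seed = derive_seed(seed, "src"))
  } else if (inherits(source, "admixture_scenario")) {
    source <- admixture_source(source, params, seed = derive_seed(seed, "src"))
  }
  map <- source$map
  loci_idx <- match(loci$snp_id, map$id)
  if (anyNA(loci_idx)) abort("all risk loci must be present in the variant map")
  if (!is.null(ancestry_risk) && nrow(ancestry_risk) > 0) {
    if (is.null(source$n_pops)) {
      abort("ancestry risk requires an admixed source with ancestry truth")
    }
    for (r in seq_len(nrow(ancestry_risk))) {
      in_reg <- map$chrom == ancestry_risk$chrom[r] &
        map$pos_bp >= ancestry_risk$start_bp[r] &
        map$pos_bp < ancestry_risk$end_bp[r]
      if (!any(in_reg)) abort("ancestry-risk region contains no variants")
      pi_a <- source$proportions[ancestry_risk$ancestry[r] + 1L]
      if (pi_a + ancestry_risk$deviation[r] < 0 ||
          pi_a + ancestry_risk$deviation[r] > 1) {
        abort("pi_a + deviation falls outside [0, 1]")
      }
    }
  }

  prov <- list(seed = seed, n_cases = n_cases, n_controls = n_controls,
               prevalence = target_prevalence, loci = loci,
               ancestry_risk = ancestry_risk, warnings = character())

  # Calibrate the baseline on a source sample.
  calib <- source$draw(max(200L, 2L * nrow(loci) * 50L))
  g_cal <- hap_to_geno(calib$h, loci_idx)
  mono <- which(apply(g_cal, 2, function(x) length(unique(x))) == 1L)
  if (length(mono)) {
    msg <- paste0("risk locus monomorphic in source sample: ",
                  paste(loci$snp_id[mono], collapse = ", "))
    warn(msg)
    prov$warnings <- c(prov$warnings, msg)
  }
  b0 <- if (nrow(loci)) calibrate_baseline(g_cal, loci, target_prevalence) else
    stats::qlogis(target_prevalence)
  prov$baseline_logit <- b0

  track_anc <- keep_haplotypes # ancestry kept alongside haplotypes if present
  n_total <- n_cases + n_controls
  m <- nrow(map)
  acc_h <- matrix(0L, nrow = 2L * n_total, ncol = m)
  acc_anc <- if (!is.null(source$n_pops)) matrix(0L, nrow = 2L * n_total, ncol = m) else NULL
  acc_ph <- integer(n_total)
  got_case <- 0L; got_ctrl <- 0L; got <- 0L
  attempts <- 0L
  cap <- 1000 * n_total
  rng_state <- derive_seed(seed, "case_control_assign")
  set.seed(rng_state)
  while ((got_case < n_cases || got_ctrl < n_controls) && attempts < cap) {
    b <- source$draw(as.integer(batch))
    attempts <- attempts + batch
    g_b <- hap_to_geno(b$h, loci_idx)
    p <- if (nrow(loci)) penetrance(g_b, loci, b0) else
      rep(stats::plogis(b0), nrow(g_b))
    is_case <- runif(length(p)) < p
    for (i in seq_along(is_case)) {
      if (is_case[i] && got_case < n_cases) {
        got <- got + 1L; got_case <- got_case + 1L
        acc_ph[got] <- 1L
      } else if (!is_case[i] && got_ctrl < n_controls) {
        got <- got + 1L; got_ctrl <- got_ctrl + 1L
        acc_ph[got] <- 0L
      } else next
      acc_h[c(2L * got - 1L, 2L * got), ] <- b$h[c(2L * i - 1L, 2L * i), ]
      if (!is.null(acc_anc)) {
        acc_anc[c(2L * got - 1L, 2L * got), ] <- b$anc[c(2L * i - 1L, 2L * i), ]
      }
      if (got_case >= n_cases && got_ctrl >= n_controls) break
    }
  }
  if (got_case < n_cases || got_ctrl < n_controls) {
    abort("rejection sampling attempt cap reached before quotas were met")
  }

  # Ancestry-risk injection on accepted cases.
  if (!is.null(ancestry_risk) && nrow(ancestry_risk) > 0) {
    inj <- inject_ancestry_risk(acc_h, acc_anc, acc_ph, map, ancestry_risk,
                                source, seed)
    acc_h <- inj$h; acc_anc <- inj$anc
  }

  geno <- hap_to_geno(acc_h, seq_len(m))
  la <- if (!is.null(acc_anc) && track_anc) {
    hap_ids <- paste0("ind", rep(seq_len(n_total), each = 2L), "_h",
                      rep(1:2, n_total))
    local_ancestry(acc_anc, map, hap_ids, source$n_pops)
  } else NULL
  new_cohort(geno, acc_ph, map,
             haplotypes = if (keep_haplotypes) acc_h else NULL,
             la = la, provenance = prov)
}

# genotype matrix (individuals x sites) from stacked haplotype rows
hap_to_geno <- function(h, cols) {
  odd <- seq(1L, nrow(h), by = 2L)
  h[odd, cols, drop = FALSE] + h[odd + 1L, cols, drop = FALSE]
}

# Re-draw case haplotype segments in ancestry-risk regions from the parental
# panels, with elevated target-ancestry probability for cases.
inject_ancestry_risk <- function(h, anc, phenotype, map, ancestry_risk,
                                 source, seed) {
  set.seed(derive_seed(seed, "inject_ancestry_risk"))
  panel <- source$panel
  k <- source$n_pops
  case_idx <- which(phenotype == 1L)
  ctrl_rows <- sort(c(2L * which(phenotype == 0L) - 1L,
                      2L * which(phenotype == 0L)))
  for (r in seq_len(nrow(ancestry_risk))) {
    region_sites <- which(map$chrom == ancestry_risk$chrom[r] &
                            map$pos_bp >= ancestry_risk$start_bp[r] &
                            map$pos_bp < ancestry_risk$end_bp[r])
    a <- ancestry_risk$ancestry[r]
    # baseline pi_a: realised regional target-ancestry fraction among the
    # (untouched) controls, so the case-minus-control difference equals the
    # requested deviation regardless of founding drift
    pi_a <- mean(anc[ctrl_rows, region_sites] == a)
    p_target <- pi_a + ancestry_risk$deviation[r]
    if (p_target < 0 || p_target > 1) {
      abort("pi_a + deviation falls outside [0, 1] for the realised cohort")
    }
    other <- setdiff(seq_len(k) - 1L, a)
    p_other <- source$proportions[other + 1L]
    p_other <- if (sum(p_other) > 0) p_other / sum(p_other) else
      rep(1 / length(other), length(other))
    for (i in case_idx) {
      for (row in c(2L * i - 1L, 2L * i)) {
        anc_draw <- if (runif(1) < p_target) a else
          other[sample.int(length(other), 1L, prob = p_other)]
        donor_rows <- which(panel$pop_labels == anc_draw)
        donor <- donor_rows[sample.int(length(donor_rows), 1L)]
        h[row, region_sites] <- panel$haplotypes[donor, region_sites]
        if (!is.null(anc)) anc[row, region_sites] <- anc_draw
      }
    }
  }
  list(h = h, anc = anc)
}
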