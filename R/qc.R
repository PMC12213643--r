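#' Exact Hardy-Weinberg equilibrium test p-value
#'
#' Conditional exact test: enumerates the full distribution of heterozygote
#' counts given the observed allele counts and sums the probabilities of
#' configurations no more probable than the observed one (two-sided,
#' Wigginton-style).
#'
#' @param n_het,n_hom_ref,n_hom_alt Genotype counts.
#' @return Exact p-value in (0, 1].
#' @examples
#' hwe_exact_p(43, 57, 0)
#' @export
hwe_exact_p <- function(n_het, n_hom_ref, n_hom_alt) {
  n <- n_het + n_hom_ref + n_hom_alt
  n_alt <- n_het + 2L * n_hom_alt
  n_minor <- min(n_alt, 2L * n - n_alt)
  # heterozygote counts compatible with the allele counts share parity
  hets <- seq(n_minor %% 2L, n_minor, by = 2L)
  # log P(het = h | allele counts) up to a constant
  lp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    h * log(2) - lfactorial(h) - lfactorial(hom_min) - lfactorial(hom_maj)
  }, 1)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- which(hets == n_het)
  if (length(obs) == 0L) abort("observed heterozygote count incompatible with allele counts")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-10)]))
}

#' Quality-control filter for a cohort
#'
#' Removes SNPs with minor allele frequency below `maf_min`, an exact
#' Hardy-Weinberg test p-value (computed in controls) below `hwe_alpha`, or
#' missingness above `max_missing`. The removal log names every removed SNP
#' and the triggering rule; designed risk SNPs recorded in the cohort's
#' provenance that get removed are additionally flagged with a warning (a
#' quality-control step can silently delete a true signal).
#'
#' @param cohort A `cohort`.
#' @param maf_min MAF floor (default 0.01).
#' @param hwe_alpha HWE exact-test alpha (default 1e-6).
#' @param max_missing Maximum per-SNP missingness fraction (default 0.05).
#' @return List with `cohort` (filtered; haplotype/ancestry columns filtered
#'   in step) and `removal_log` (tibble: id, reason).
#' @export
qc_filter <- function(cohort, maf_min = 0.01, hwe_alpha = 1e-6,
                      max_missing = 0.05) {
  stopifnot(inherits(cohort, "cohort"))
  if (maf_min < 0 || maf_min > 0.5) abort("maf_min must lie in [0, 0.5]")
  if (hwe_alpha < 0 || hwe_alpha > 1) abort("hwe_alpha must lie in [0, 1]")
  g <- cohort$genotypes
  miss <- colMeans(is.na(g))
  f <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  ctrl <- cohort$phenotype == 0L
  hwe_p <- rep(1, ncol(g))
  candidates <- which(maf >= maf_min & miss <= max_missing)
  if (hwe_alpha > 0) {
    for (j in candidates) {
      gj <- g[ctrl, j]
      gj <- gj[!is.na(gj)]
      hwe_p[j] <- hwe_exact_p(sum(gj == 1L), sum(gj == 0L), sum(gj == 2L))
    }
  }
  reason <- rep(NA_character_, ncol(g))
  reason[miss > max_missing] <- "missingness"
  reason[is.na(reason) & maf < maf_min] <- "MAF"
  reason[is.na(reason) & hwe_p < hwe_alpha] <- "HWE"
  drop <- which(!is.na(reason))
  removal_log <- tibble::tibble(id = cohort$map$id[drop], reason = reason[drop])
  risk_ids <- cohort$provenance$loci$snp_id
  lost <- intersect(risk_ids, removal_log$id)
  if (length(lost)) {
    warn(paste0("QC removed designed risk SNP(s): ", paste(lost, collapse = ", ")))
  }
  keep <- setdiff(seq_len(ncol(g)), drop)
  map2 <- cohort$map[keep, ]
  class(map2) <- class(cohort$map)
  out <- new_cohort(
    g[, keep, drop = FALSE], cohort$phenotype, map2, cohort$sample_ids,
    haplotypes = if (!is.null(cohort$haplotypes))
      cohort$haplotypes[, keep, drop = FALSE] else NULL,
    la = if (!is.null(cohort$la))
      local_ancestry(cohort$la$assignments[, keep, drop = FALSE], map2,
                     cohort$la$hap_ids, cohort$la$n_pops) else NULL,
    provenance = c(cohort$provenance,
                   list(qc = list(maf_min = maf_min, hwe_alpha = hwe_alpha,
                                  max_missing = max_missing,
                                  removed = removal_log,
                                  removed_risk = lost))))
  list(cohort = out, removal_log = removal_log)
}
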