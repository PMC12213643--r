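#' Signal-class default relative risks and ancestry deviations
#'
#' Strong genotype signals default to heterozygote/homozygote odds ratios
#' 1.8 / 3.24, weak to 1.15 / 1.32, null to 1 / 1; ancestry deviations default
#' to 0.15 (strong), 0.25 (very strong) and 0.05 (weak). These are chosen so
#' that strong loci are detectable at a total n of about 1,000 and weak loci
#' are marginal.
#'
#' @param class One of `"strong"`, `"weak"`, `"null"`.
#' @return Named list with `rr_het` and `rr_hom`.
#' @export
signal_class_rr <- function(class) {
  switch(class,
         strong = list(rr_het = 1.8, rr_hom = 3.24),
         weak = list(rr_het = 1.15, rr_hom = 1.32),
         null = list(rr_het = 1, rr_hom = 1),
         abort(paste0("unknown signal class: ", class)))
}

ancestry_class_dev <- function(class) {
  switch(class, strong = 0.15, very_strong = 0.25, weak = 0.05, none = 0,
         abort(paste0("unknown ancestry class: ", class)))
}

# Risk design tables per preset. Each row is one designed SNP; `role` marks
# manufactured tag-pair anchors/partners; per-cohort signal classes follow.
# `carrier` marks SNPs that carry their own penetrance term. The chromosome-11
# partner is in complete LD with its anchor in every population, so it shows
# the anchor's association through the shared genotype column; giving it an
# own term as well would square the effective odds ratio.
hom_design <- function() {
  tibble::tribble(
    ~chrom, ~role,      ~ld_pops,  ~class_eur, ~class_afr, ~carrier,
    "2",    "anchor",   list(0L),   "strong",   "null",     TRUE,
    "2",    "partner",  list(0L),   "null",     "strong",   TRUE,
    "20",   "anchor",   list(0L),   "strong",   "null",     TRUE,
    "20",   "partner",  list(0L),   "null",     "strong",   TRUE,
    "11",   "anchor",   list(0:1),  "strong",   "weak",     TRUE,
    "11",   "partner",  list(0:1),  "strong",   "weak",     FALSE,
    "6",    "single",   list(NULL), "strong",   "strong",   TRUE,
    "15",   "single",   list(NULL), "strong",   "strong",   TRUE)
}

admixed_design <- function(preset) {
  if (preset == "threeway") {
    tibble::tribble(
      ~chrom, ~role,     ~class,   ~anc_class, ~carrier,
      "2",    "anchor",  "strong", "strong",   TRUE,
      "2",    "partner", "null",   NA,         TRUE,
      "20",   "anchor",  "null",   NA,         TRUE,
      "20",   "partner", "null",   NA,         TRUE,
      "11",   "anchor",  "strong", "strong",   TRUE,
      "11",   "partner", "strong", NA,         FALSE,
      "6",    "single",  "weak",   "very_strong", TRUE,
      "15",   "single",  "weak",   "weak",     TRUE)
  } else {
    tibble::tribble(
      ~chrom, ~role,     ~class,   ~anc_class, ~carrier,
      "2",    "anchor",  "strong", "strong",   TRUE,
      "2",    "partner", "null",   NA,         TRUE,
      "20",   "anchor",  "strong", "none",     TRUE,
      "20",   "partner", "null",   NA,         TRUE,
      "11",   "anchor",  "weak",   "weak",     TRUE,
      "11",   "partner", "null",   NA,         TRUE,
      "6",    "single",  "strong", "none",     TRUE,
      "15",   "single",  "weak",   "weak",     TRUE)
  }
}

#' Build a preset simulation scenario
#'
#' Wires a complete benchmark scenario: synthetic reference panel,
#' manufactured cross-population tag-SNP pairs, eight designed risk SNPs on
#' chromosomes 2, 6, 11, 15 and 20 (all other chromosomes null), logistic
#' case-control sampling, and — for the admixed presets — single-point
#' admixture with ten generations of random mating plus regional ancestry
#' risk.
#'
#' Presets:
#' * `"eur_hom"` / `"afr_hom"`: homogeneous cohorts grown from a two-
#'   population (European-like / African-like) panel. The chromosome 2 and 20
#'   pairs are in complete LD in the European-like population only, with the
#'   anchor causal in the European-like cohort and the partner causal in the
#'   African-like cohort (the replication/misreplication design); the
#'   chromosome 11 pair is in complete LD in both, strong in the European-like
#'   and weak in the African-like cohort; chromosomes 6 and 15 carry one
#'   shared strong SNP each.
#' * `"threeway"`: three-way admixture (majority contribution 70%), strong
#'   genotype+ancestry risk on chromosomes 2 and 11, very strong ancestry with
#'   weak genotype risk on chromosome 6, weak/weak on chromosome 15.
#' * `"fiveway"`: five-way admixture; strong genotype+ancestry risk on
#'   chromosome 2, strong genotype without ancestry risk on chromosomes 6 and
#'   20, weak/weak on chromosomes 11 and 15.
#'
#' @param preset One of `"eur_hom"`, `"afr_hom"`, `"threeway"`, `"fiveway"`.
#' @param size `"large"` (2,500 cases + 2,500 controls) or `"small"`
#'   (500 + 500); overridable via `n_cases` / `n_controls`.
#' @param seed Integer master seed.
#' @param n_snps_per_chrom SNPs per chromosome (default 4,000; smaller values
#'   keep the same 100 cM genetic length per chromosome).
#' @param n_hap_per_pop Reference haplotypes per population (default 200).
#' @param n_cases,n_controls Optional explicit quotas overriding `size`.
#' @param paired For the homogeneous presets, also build the partner
#'   population's cohort from the same panel and design (for replication
#'   studies).
#' @param force_null Override every signal class to null (no genotype or
#'   ancestry risk) — a pure null calibration scenario.
#' @param target_prevalence Disease prevalence (default 0.10).
#' @param generations Admixture generations (default 10).
#' @param region_half_bp Half-width of ancestry-risk regions around their
#'   risk SNP (default 2 Mb).
#' @param params [gametogenesis_params()].
#' @param keep_haplotypes Retain phased haplotypes in the cohorts.
#' @return A `gwas_scenario` list: `cohort`, optional `paired_cohort`,
#'   `panel`, `design` (the eight designed SNPs with ids, partners, and
#'   per-cohort signal classes), `ancestry_risk`, `config`.
#' @export
build_scenario <- function(preset = c("eur_hom", "afr_hom", "threeway", "fiveway"),
                           size = c("large", "small"), seed = 1,
                           n_snps_per_chrom = 4000, n_hap_per_pop = 200,
                           n_cases = NULL, n_controls = NULL, paired = FALSE,
                           force_null = FALSE, target_prevalence = 0.1,
                           generations = 10, region_half_bp = 2e6,
                           params = gametogenesis_params(),
                           keep_haplotypes = TRUE) {
  preset <- match.arg(preset)
  size <- match.arg(size)
  n_quota <- if (size == "large") 2500L else 500L
  if (is.null(n_cases)) n_cases <- n_quota
  if (is.null(n_controls)) n_controls <- n_quota
  map <- default_variant_map(n_snps_per_chrom)

  admixed <- preset %in% c("threeway", "fiveway")
  k <- if (!admixed) 2L else if (preset == "threeway") 3L else 5L
  fst <- switch(preset,
                eur_hom = , afr_hom = c(0.05, 0.10),
                threeway = c(0.12, 0.10, 0.08),
                fiveway = c(0.15, 0.12, 0.10, 0.08, 0.06))
  pop_names <- if (!admixed) c("EURlike", "AFRlike") else
    paste0("anc", seq_len(k) - 1L)
  proportions <- switch(preset,
                        threeway = c(0.70, 0.15, 0.15),
                        fiveway = c(0.30, 0.25, 0.20, 0.15, 0.10),
                        NULL)

  panel <- generate_reference_panel(
    k_pops = k, fst = fst, n_hap_per_pop = n_hap_per_pop, variant_map = map,
    ld_block_len = 0.1, pop_names = pop_names,
    seed = derive_seed(seed, paste0("panel_", preset)))

  # Manufacture tag pairs and resolve designed SNP ids.
  dsg <- if (!admixed) hom_design() else admixed_design(preset)
  dsg$snp_id <- NA_character_
  dsg$partner_id <- NA_character_
  for (ch in unique(dsg$chrom[dsg$role == "anchor"])) {
    ld_pops <- if (!admixed) {
      v <- dsg$ld_pops[dsg$chrom == ch & dsg$role == "anchor"][[1]]
      if (is.list(v)) v[[1]] else v # tribble list-cell carries one extra level
    } else seq_len(k) - 1L
    mt <- manufacture_tag_pair(panel, ch, ld_pops = ld_pops,
                               seed = derive_seed(seed, paste0("tag", ch)))
    panel <- mt$panel
    dsg$snp_id[dsg$chrom == ch & dsg$role == "anchor"] <- mt$snp_x
    dsg$snp_id[dsg$chrom == ch & dsg$role == "partner"] <- mt$snp_y
    dsg$partner_id[dsg$chrom == ch & dsg$role == "anchor"] <- mt$snp_y
    dsg$partner_id[dsg$chrom == ch & dsg$role == "partner"] <- mt$snp_x
  }
  for (i in which(dsg$role == "single")) {
    dsg$snp_id[i] <- map$id[pick_risk_site(panel, dsg$chrom[i])]
  }
  if (force_null) {
    for (col in intersect(c("class", "class_eur", "class_afr"), names(dsg))) {
      dsg[[col]] <- "null"
    }
    if ("anc_class" %in% names(dsg)) dsg$anc_class <- NA_character_
  }

  loci_from_classes <- function(classes) {
    keep <- classes != "null" & dsg$carrier
    rr <- lapply(classes[keep], signal_class_rr)
    risk_loci(dsg$snp_id[keep], dsg$chrom[keep],
              rr_het = vapply(rr, `[[`, 1, "rr_het"),
              rr_hom = vapply(rr, `[[`, 1, "rr_hom"),
              partner_id = dsg$partner_id[keep],
              signal_class = classes[keep])
  }

  config <- list(preset = preset, size = size, seed = seed,
                 n_snps_per_chrom = n_snps_per_chrom,
                 n_hap_per_pop = n_hap_per_pop, n_cases = n_cases,
                 n_controls = n_controls, fst = fst,
                 proportions = proportions, generations = generations,
                 prevalence = target_prevalence, force_null = force_null)

  if (!admixed) {
    this_pop <- if (preset == "eur_hom") 0L else 1L
    class_col <- if (preset == "eur_hom") dsg$class_eur else dsg$class_afr
    loci <- loci_from_classes(class_col)
    src <- homogeneous_source(panel, params, seed = derive_seed(seed, "srcA"),
                              pop = this_pop)
    cohort <- simulate_case_control(src, loci, n_cases, n_controls,
                                    target_prevalence,
                                    seed = derive_seed(seed, "ccA"),
                                    params = params,
                                    keep_haplotypes = keep_haplotypes)
    paired_cohort <- NULL
    if (paired) {
      other_pop <- 1L - this_pop
      class_col2 <- if (other_pop == 0L) dsg$class_eur else dsg$class_afr
      loci2 <- loci_from_classes(class_col2)
      src2 <- homogeneous_source(panel, params,
                                 seed = derive_seed(seed, "srcB"),
                                 pop = other_pop)
      paired_cohort <- simulate_case_control(src2, loci2, n_cases, n_controls,
                                             target_prevalence,
                                             seed = derive_seed(seed, "ccB"),
                                             params = params,
                                             keep_haplotypes = keep_haplotypes)
    }
    anc_risk <- NULL
  } else {
    loci <- loci_from_classes(dsg$class)
    anc_rows <- which(!is.na(dsg$anc_class) & dsg$anc_class != "none")
    anc_risk <- if (length(anc_rows) && !force_null) {
      pos <- map$pos_bp[match(dsg$snp_id[anc_rows], map$id)]
      ancestry_risk_spec(
        chrom = dsg$chrom[anc_rows],
        start_bp = pmax(1, pos - region_half_bp),
        end_bp = pos + region_half_bp,
        ancestry = 0L, # deviation toward the first (majority) ancestry
        deviation = vapply(dsg$anc_class[anc_rows], ancestry_class_dev, 1),
        strength_class = dsg$anc_class[anc_rows])
    } else NULL
    scen <- admixture_scenario(panel, proportions, generations,
                               n_out = max(500L, n_cases))
    src <- admixture_source(scen, params, seed = derive_seed(seed, "srcA"))
    cohort <- simulate_case_control(src, loci, n_cases, n_controls,
                                    target_prevalence,
                                    seed = derive_seed(seed, "ccA"),
                                    ancestry_risk = anc_risk, params = params,
                                    keep_haplotypes = keep_haplotypes)
    paired_cohort <- NULL
  }

  dsg$ld_pops <- NULL
  structure(list(preset = preset, cohort = cohort,
                 paired_cohort = paired_cohort, panel = panel, map = map,
                 design = dsg, ancestry_risk = anc_risk, config = config),
            class = "gwas_scenario")
}

#' @export
print.gwas_scenario <- function(x, ...) {
  cat("<gwas_scenario> preset=", x$preset, " (", x$config$n_cases, " cases / ",
      x$config$n_controls, " controls; ", nrow(x$map), " SNPs)\n", sep = "")
  invisible(x)
}

#' Designed risk SNPs (truth) for a scenario cohort
#'
#' Returns the designed loci with a non-null signal class for the requested
#' cohort, i.e. the truth set against which power is computed.
#'
#' @param scenario A `gwas_scenario`.
#' @param which_cohort `"cohort"` or `"paired_cohort"`.
#' @return Tibble with `snp_id`, `chrom`, `partner_id`, `signal_class`.
#' @export
scenario_truth <- function(scenario, which_cohort = "cohort") {
  d <- scenario$design
  cls <- if ("class" %in% names(d)) d$class
  else if (which_cohort == "cohort" && scenario$preset == "eur_hom") d$class_eur
  else if (which_cohort == "cohort" && scenario$preset == "afr_hom") d$class_afr
  else if (scenario$preset == "eur_hom") d$class_afr
  else d$class_eur
  tibble::tibble(snp_id = d$snp_id, chrom = d$chrom,
                 partner_id = d$partner_id, signal_class = cls)
}
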