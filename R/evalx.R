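#' Bonferroni per-test significance threshold
#'
#' @param alpha Family-wise error target in (0, 1).
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 1e6) # 5e-8, the usual genome-wide threshold
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("alpha must lie in (0, 1)")
  }
  if (n_tests < 1) abort("n_tests must be >= 1")
  alpha / n_tests
}

#' Apply a decision rule to an association result
#'
#' * `frequentist-p`: significant when `p <= threshold`;
#' * `log-bf`: significant when `log_bf >= threshold` (default `log(100) ~
#'   4.61`, Jeffreys' decisive boundary — the comparison is a strict `>=`, so
#'   4.605 does not pass 4.61);
#' * `ppa`: significant when `ppa >= threshold` (default 0.5).
#'
#' @param result An `assoc_result`.
#' @param rule One of `"frequentist-p"`, `"log-bf"`, `"ppa"`.
#' @param threshold Decision threshold (defaults: required for
#'   `frequentist-p`; `log(100)` for `log-bf`; 0.5 for `ppa`).
#' @return Character vector of significant SNP ids.
#' @export
decision_rule <- function(result, rule = c("frequentist-p", "log-bf", "ppa"),
                          threshold = NULL) {
  rule <- match.arg(rule)
  col <- switch(rule, `frequentist-p` = "p", `log-bf` = "log_bf", ppa = "ppa")
  v <- result[[col]]
  if (is.null(v) || (nrow(result) > 0L && all(is.na(v)))) {
    abort(paste0("decision rule '", rule, "' needs statistic '", col,
                 "', which this result does not carry"))
  }
  if (is.null(threshold)) {
    threshold <- switch(rule, `frequentist-p` =
                          abort("a p-value threshold must be supplied"),
                        `log-bf` = 4.61, ppa = 0.5)
  }
  sig <- if (rule == "frequentist-p") !is.na(v) & v <= threshold else
    !is.na(v) & v >= threshold
  result$id[sig]
}

#' Power and false-positive rate against the designed truth
#'
#' Power is the fraction of designed risk loci detected (a locus counts as
#' detected when the locus itself is significant; the optional LD-proxy mode
#' also credits its complete-LD partner, and is off by default to keep the
#' literal definition). The false-positive rate is computed over all
#' non-risk SNPs as `FPR = FP / (FP + TN)`.
#'
#' @param result An `assoc_result`.
#' @param truth Tibble with `snp_id` (designed risk loci; optionally
#'   `partner_id` and `signal_class`). Loci with `signal_class == "null"` are
#'   dropped from the truth set but excluded from the FPR denominator too.
#' @param rule,threshold Passed to [decision_rule()].
#' @param ld_proxy Credit a locus when its `partner_id` is significant.
#' @return One-row tibble: `power`, `fpr`, `n_risk`, `n_detected`, `n_fp`,
#'   `n_nonrisk`, `n_tests`.
#' @export
power_fpr <- function(result, truth, rule = "frequentist-p", threshold = NULL,
                      ld_proxy = FALSE) {
  if (is.null(truth) || nrow(truth) == 0L) {
    abort("empty truth: power is undefined")
  }
  sig <- decision_rule(result, rule, threshold)
  designed <- truth$snp_id
  active <- if ("signal_class" %in% names(truth)) {
    truth[truth$signal_class != "null", , drop = FALSE]
  } else truth
  detected <- active$snp_id %in% sig
  if (ld_proxy && "partner_id" %in% names(active)) {
    detected <- detected | (!is.na(active$partner_id) & active$partner_id %in% sig)
  }
  tested <- result$id[!is.na(result$p) | !is.na(result$log_bf) | !is.na(result$ppa)]
  nonrisk <- setdiff(tested, designed)
  fp <- sum(sig %in% nonrisk)
  tibble::tibble(
    power = if (nrow(active)) mean(detected) else NA_real_,
    fpr = if (length(nonrisk)) fp / length(nonrisk) else NA_real_,
    n_risk = nrow(active), n_detected = sum(detected),
    n_fp = fp, n_nonrisk = length(nonrisk), n_tests = length(tested))
}

#' Genomic inflation factor
#'
#' `lambda_GC = median(qchisq(1 - p, 1)) / 0.4549` (the median of a central
#' 1-df chi-square). Values near 1 indicate a calibrated test; inflation
#' above 1 indicates residual confounding.
#'
#' @param result An `assoc_result`, or a numeric vector of p-values.
#' @param min_tests Minimum number of p-values required (default 100).
#' @return Numeric scalar.
#' @export
lambda_gc <- function(result, min_tests = 100L) {
  p <- if (is.numeric(result)) result else result$p
  p <- p[!is.na(p)]
  if (length(p) < min_tests) abort("too few tests for a stable inflation estimate")
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, 1, lower.tail = FALSE)
}

#' Run a battery of association tests on one cohort
#'
#' @param cohort A `cohort` (post-QC).
#' @param tests Character vector from `"trend"`, `"logistic"`,
#'   `"logistic_pcs"`, `"lmm"`, `"lmm_loco"`, `"bayes"`, `"tractor"`,
#'   `"admixture_mapping"`, `"jointppa"`.
#' @param n_pcs Number of principal components used by `"logistic_pcs"` /
#'   `"bayes"` covariate adjustment (default 10 for cohorts with local
#'   ancestry, 5 otherwise).
#' @param prior_sd Bayes-factor prior SD.
#' @param prior_pi Prior for [joint_ppa()].
#' @return Named list of `assoc_result` objects.
#' @export
run_tests <- function(cohort, tests = c("trend", "logistic_pcs", "lmm"),
                      n_pcs = NULL, prior_sd = 0.2, prior_pi = 1e-4) {
  admixed <- !is.null(cohort$la)
  if (is.null(n_pcs)) n_pcs <- if (admixed) 10L else 5L
  n_pcs <- min(n_pcs, nrow(cohort$genotypes) - 2L)
  needs_pcs <- any(tests %in% c("logistic_pcs", "bayes"))
  pcs <- if (needs_pcs) grm_pca(cohort, k = n_pcs)$scores else NULL
  out <- list()
  for (t in tests) {
    out[[t]] <- switch(
      t,
      trend = trend_assoc(cohort),
      logistic = logistic_assoc(cohort),
      logistic_pcs = logistic_assoc(cohort, covariates = pcs),
      lmm = lmm_assoc(cohort, mode = "all"),
      lmm_loco = lmm_assoc(cohort, mode = "loco"),
      bayes = bayes_assoc(cohort, covariates = pcs, prior_sd = prior_sd),
      tractor = tractor_assoc(cohort),
      admixture_mapping = admixture_mapping(cohort, ancestry = 0L,
                                            prior_sd = prior_sd),
      jointppa = {
        bf_g <- bayes_assoc(cohort, covariates = pcs, prior_sd = prior_sd)
        bf_a <- admixture_mapping(cohort, ancestry = 0L, prior_sd = prior_sd)
        r <- bf_g
        r$ppa <- joint_ppa(r$log_bf, bf_a$log_bf[match(r$id, bf_a$id)],
                           prior_pi = prior_pi)
        attr(r, "test_name") <- "jointppa"
        r
      },
      abort(paste0("unknown test: ", t)))
  }
  out
}

#' Benchmark scenarios x tests x seeds
#'
#' Runs the full cross of scenario presets, association tests and seeds,
#' evaluating power and FPR for each cell against the scenario's designed
#' truth. Stage failures are recorded per cell, not fatal to the grid.
#'
#' @param presets Character vector of [build_scenario()] presets.
#' @param tests Character vector of test names (see [run_tests()]).
#' @param seeds Integer vector of master seeds.
#' @param size `"small"` or `"large"`.
#' @param alpha Family-wise alpha for the Bonferroni threshold.
#' @param n_snps_per_chrom,n_hap_per_pop Scale knobs forwarded to
#'   [build_scenario()].
#' @param qc Apply [qc_filter()] before testing.
#' @param ... Further arguments to [build_scenario()].
#' @return An `eval_report` tibble: one row per (scenario, test, seed) with
#'   power, fpr, lambda_gc, threshold, n_tests, error.
#' @export
benchmark <- function(presets, tests, seeds, size = "small", alpha = 0.05,
                      n_snps_per_chrom = 200, n_hap_per_pop = 100,
                      qc = TRUE, ...) {
  rows <- list()
  for (preset in presets) {
    for (seed in seeds) {
      scen <- tryCatch(
        build_scenario(preset, size = size, seed = seed,
                       n_snps_per_chrom = n_snps_per_chrom,
                       n_hap_per_pop = n_hap_per_pop, ...),
        error = function(e) e)
      if (inherits(scen, "error")) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          scenario = preset, test = NA_character_, seed = seed,
          power = NA_real_, fpr = NA_real_, lambda_gc = NA_real_,
          threshold = NA_real_, n_tests = NA_integer_,
          removed_risk = NA_character_, error = conditionMessage(scen))
        next
      }
      cohort <- scen$cohort
      removed_risk <- NA_character_
      if (qc) {
        qcres <- withCallingHandlers(
          qc_filter(cohort), warning = function(w) invokeRestart("muffleWarning"))
        removed <- intersect(scen$design$snp_id, qcres$removal_log$id)
        if (length(removed)) removed_risk <- paste(removed, collapse = ",")
        cohort <- qcres$cohort
      }
      truth <- scenario_truth(scen)
      for (t in tests) {
        cell <- tryCatch({
          res <- run_tests(cohort, tests = t)[[t]]
          thr <- bonferroni_threshold(alpha, sum(!is.na(res$p)))
          rule <- if (t == "jointppa") "ppa" else "frequentist-p"
          pf <- power_fpr(res, truth, rule = rule,
                          threshold = if (rule == "ppa") 0.5 else thr)
          lam <- tryCatch(lambda_gc(res), error = function(e) NA_real_)
          tibble::tibble(scenario = preset, test = t, seed = seed,
                         power = pf$power, fpr = pf$fpr, lambda_gc = lam,
                         threshold = thr, n_tests = pf$n_tests,
                         removed_risk = removed_risk, error = NA_character_)
        }, error = function(e) tibble::tibble(
          scenario = preset, test = t, seed = seed, power = NA_real_,
          fpr = NA_real_, lambda_gc = NA_real_, threshold = NA_real_,
          n_tests = NA_integer_, removed_risk = removed_risk,
          error = conditionMessage(e)))
        rows[[length(rows) + 1L]] <- cell
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("eval_report", class(tibble::tibble()))
  out
}

#' Plot-ready Manhattan and QQ tables
#'
#' @param result An `assoc_result`.
#' @return List of two tibbles: `manhattan` (id, chrom, pos, p, neglog10p)
#'   and `qq` (expected vs observed -log10 p).
#' @export
plot_tables <- function(result) {
  ok <- !is.na(result$p)
  man <- tibble::tibble(id = result$id[ok], chrom = result$chrom[ok],
                        pos = result$pos[ok], p = result$p[ok],
                        neglog10p = -log10(result$p[ok]))
  p <- sort(result$p[ok], decreasing = TRUE)
  qq <- tibble::tibble(
    expected = -log10((length(p):1 - 0.5) / length(p)),
    observed = -log10(p))
  list(manhattan = man, qq = qq)
}
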