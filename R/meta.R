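#' Assemble per-study summary statistics for meta-analysis
#'
#' Harmonises a list of association results (or plain tibbles with `id`,
#' `beta`, `se`) on their shared SNP ids. Alleles are matched by id plus
#' allele pair when present; strand flips are out of scope for
#' strand-consistent synthetic data.
#'
#' @param studies Named list of `assoc_result` tibbles (or any tibble with
#'   columns `id`, `beta`, `se`; `n` optional).
#' @return A long tibble of class `study_stats`: `study_id`, `id`, `beta`,
#'   `se`, `n`, keeping only SNPs present with finite `beta`/`se` in every
#'   study.
#' @export
study_stats <- function(studies) {
  if (is.null(names(studies))) names(studies) <- paste0("study", seq_along(studies))
  long <- purrr::imap(studies, function(s, nm) {
    tibble::tibble(study_id = nm, id = s$id, beta = s$beta, se = s$se,
                   n = if ("n" %in% names(s)) s$n else NA_integer_)
  })
  long <- dplyr::bind_rows(long)
  ok <- long |>
    dplyr::filter(is.finite(.data$beta), is.finite(.data$se), .data$se > 0) |>
    dplyr::count(.data$id) |>
    dplyr::filter(.data$n == length(studies))
  out <- dplyr::semi_join(long, ok, by = "id")
  class(out) <- c("study_stats", class(tibble::tibble()))
  out
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Per SNP: weights `w_i = 1/se_i^2`, pooled `beta = sum(w b) / sum(w)`,
#' `SE = 1/sqrt(sum w)`, two-sided z p-value. The pooled SE never exceeds the
#' smallest study SE.
#'
#' @param stats A [study_stats()] tibble.
#' @return Tibble: `id`, `fe_beta`, `fe_se`, `fe_z`, `fe_p`, `k`.
#' @export
fixed_effects <- function(stats) {
  if (any(stats$se <= 0)) abort("study standard errors must be > 0")
  stats |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      fe_beta = sum(.data$beta / .data$se^2) / sum(1 / .data$se^2),
      fe_se = 1 / sqrt(sum(1 / .data$se^2)),
      k = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(fe_z = .data$fe_beta / .data$fe_se,
                  fe_p = pmax(2 * pnorm(abs(.data$fe_z), lower.tail = FALSE),
                              P_FLOOR))
}

#' Random-effects meta-analysis (DerSimonian-Laird), with a
#' heterogeneity-likelihood-ratio variant
#'
#' Per SNP: Cochran's `Q`; `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 /
#' sum w))`; re-weighted pooling with `w* = 1 / (se^2 + tau2)`;
#' `I2 = max(0, (Q - (k-1)) / Q) * 100`. `re_p` is the DerSimonian-Laird
#' normal test. `re2_p` is a likelihood-ratio random-effects test of the
#' joint null `beta = 0, tau2 = 0` against the free alternative (the
#' METASOFT-style random-effects model, which gains power under
#' heterogeneity), using the Self-Liang 50:50 chi-square(1)/chi-square(2)
#' mixture reference.
#'
#' @param stats A [study_stats()] tibble; every SNP needs >= 2 studies.
#' @return Tibble: `id`, `re_tau2`, `re_beta`, `re_se`, `re_p`, `re2_stat`,
#'   `re2_p`, `q_stat`, `q_df`, `i2`.
#' @export
random_effects <- function(stats) {
  ks <- table(stats$id)
  if (any(ks < 2)) {
    abort("random-effects pooling needs >= 2 studies per SNP; use fixed_effects()")
  }
  one <- function(beta, se) {
    w <- 1 / se^2
    k <- length(beta)
    bf <- sum(w * beta) / sum(w)
    q <- sum(w * (beta - bf)^2)
    tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    ws <- 1 / (se^2 + tau2)
    rb <- sum(ws * beta) / sum(ws)
    rse <- 1 / sqrt(sum(ws))
    i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
    ll <- function(mu, t2) sum(stats::dnorm(beta, mu, sqrt(se^2 + t2), log = TRUE))
    # alternative: profile over mu on a tau2 grid refined by optimize
    obj <- function(t2) {
      wts <- 1 / (se^2 + t2)
      ll(sum(wts * beta) / sum(wts), t2)
    }
    upper <- max(1e-8, 10 * (stats::var(beta) + max(se^2)))
    op <- optimize(obj, c(0, upper), maximum = TRUE, tol = 1e-10)
    ll1 <- max(op$objective, obj(0))
    lrt <- max(0, 2 * (ll1 - ll(0, 0)))
    re2_p <- 0.5 * pchisq(lrt, 1, lower.tail = FALSE) +
      0.5 * pchisq(lrt, 2, lower.tail = FALSE)
    tibble::tibble(re_tau2 = tau2, re_beta = rb, re_se = rse,
                   re_p = pmax(2 * pnorm(abs(rb / rse), lower.tail = FALSE),
                               P_FLOOR),
                   re2_stat = lrt, re2_p = pmax(re2_p, P_FLOOR),
                   q_stat = q, q_df = k - 1, i2 = i2)
  }
  stats |>
    dplyr::group_by(.data$id) |>
    dplyr::reframe(one(.data$beta, .data$se)) |>
    tibble::as_tibble()
}

#' Per-study posterior probabilities of effect (m-values)
#'
#' Exact Bayesian model averaging over all `2^k` effect-existence
#' configurations of the `k` studies. Within a configuration, the studies
#' with an effect share a common effect with a Normal(0, effect_prior_sd^2)
#' prior, integrated analytically against the Gaussian likelihood of the
#' effect estimates; studies without an effect contribute
#' `N(beta_i; 0, se_i^2)`. `m_i` is the posterior mass of configurations in
#' which study `i` carries the effect; `m_i + P(no effect in i | data) = 1`.
#'
#' @param stats A [study_stats()] tibble (k <= 20 studies: exact enumeration).
#' @param prior_effect_prob Prior probability that a study has an effect
#'   (default 0.5).
#' @param effect_prior_sd Prior SD of the shared effect (default 0.2).
#' @return Tibble: `id`, `study_id`, `m_value`.
#' @export
m_values <- function(stats, prior_effect_prob = 0.5, effect_prior_sd = 0.2) {
  k <- length(unique(stats$study_id))
  if (k > 20) abort("exact enumeration supports at most 20 studies; a sampling approximation is not implemented")
  if (prior_effect_prob < 0 || prior_effect_prob > 1) {
    abort("prior_effect_prob must lie in [0, 1]")
  }
  studies <- unique(stats$study_id)
  configs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  one <- function(beta, se) {
    logpost <- vapply(seq_len(nrow(configs)), function(ci) {
      on <- configs[ci, ]
      lp <- sum(stats::dbinom(as.integer(on), 1, prior_effect_prob, log = TRUE))
      if (any(!on)) {
        lp <- lp + sum(stats::dnorm(beta[!on], 0, se[!on], log = TRUE))
      }
      if (any(on)) {
        lp <- lp + shared_effect_logml(beta[on], se[on], effect_prior_sd)
      }
      lp
    }, 1)
    post <- exp(logpost - max(logpost))
    post <- post / sum(post)
    vapply(seq_len(k), function(i) sum(post[configs[, i]]), 1)
  }
  stats |>
    dplyr::group_by(.data$id) |>
    dplyr::reframe(study_id = studies,
                   m_value = one(.data$beta[match(studies, .data$study_id)],
                                 .data$se[match(studies, .data$study_id)])) |>
    tibble::as_tibble()
}

# log marginal likelihood of estimates sharing one effect mu ~ N(0, sd0^2):
# integral of prod N(b_i; mu, se_i^2) dN(mu; 0, sd0^2)
shared_effect_logml <- function(beta, se, sd0) {
  w <- 1 / se^2
  sw <- sum(w)
  bbar <- sum(w * beta) / sw
  # conditional on mu, then Gaussian-Gaussian marginal for bbar
  lml_cond <- sum(stats::dnorm(beta, bbar, se, log = TRUE)) -
    stats::dnorm(0, 0, sqrt(1 / sw), log = TRUE) +
    stats::dnorm(bbar, 0, sqrt(1 / sw + sd0^2), log = TRUE)
  lml_cond
}

#' Binary-effects combined statistic
#'
#' An m-value-weighted z-score combination: studies judged likely to carry
#' the effect dominate the pooled statistic,
#' `z_BE = sum(m_i sqrt(w_i) z_i) / sqrt(sum(m_i^2 w_i))` with sample-size
#' weights `w_i` proportional to `n_i`, two-sided normal p. This is an
#' explicit analog of the binary-effects model (the exact published
#' likelihood ratio is not reproduced here).
#'
#' @param stats A [study_stats()] tibble with per-study `n` filled.
#' @param m A [m_values()] tibble aligned by `id` and `study_id`.
#' @return Tibble: `id`, `be_z`, `be_p`; SNPs with all `m_i = 0` are flagged
#'   with `be_undefined = TRUE`.
#' @export
binary_effects <- function(stats, m) {
  x <- dplyr::left_join(stats, m, by = c("id", "study_id"))
  if (anyNA(x$m_value)) abort("m_values must cover every study/SNP pair")
  x |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      be_z = {
        z <- .data$beta / .data$se
        w <- if (all(is.finite(.data$n))) .data$n / sum(.data$n) else
          rep(1 / dplyr::n(), dplyr::n())
        den <- sqrt(sum(.data$m_value^2 * w))
        if (den == 0) NA_real_ else sum(.data$m_value * sqrt(w) * z) / den
      },
      .groups = "drop") |>
    dplyr::mutate(
      be_p = pmax(2 * pnorm(abs(.data$be_z), lower.tail = FALSE), P_FLOOR),
      be_undefined = !is.finite(.data$be_z))
}

#' Full meta-analysis of aligned studies
#'
#' Convenience wrapper running [fixed_effects()], [random_effects()],
#' [m_values()] and [binary_effects()] and joining the results per SNP.
#'
#' @param stats A [study_stats()] tibble.
#' @param prior_effect_prob,effect_prior_sd Priors passed to [m_values()].
#' @return A `meta_result` tibble (one row per SNP) with an `m_values`
#'   attribute holding the per-study posteriors.
#' @export
meta_analysis <- function(stats, prior_effect_prob = 0.5,
                          effect_prior_sd = 0.2) {
  fe <- fixed_effects(stats)
  re <- random_effects(stats)
  mv <- m_values(stats, prior_effect_prob, effect_prior_sd)
  be <- binary_effects(stats, mv)
  out <- fe |>
    dplyr::left_join(re, by = "id") |>
    dplyr::left_join(be, by = "id")
  attr(out, "m_values") <- mv
  class(out) <- c("meta_result", class(tibble::tibble()))
  out
}

#' Classify replication of designed loci between two studies
#'
#' Each designed locus is classified from the two studies' significance
#' calls, effect-direction concordance, and the design's tag-pair map:
#' * `replicated-same-SNP`: the locus is significant, direction-concordant,
#'   in both studies;
#' * `replicated-via-LD-partner`: the locus is significant in study A while
#'   its complete-LD partner (the population-specific causal SNP) is
#'   significant in study B — replication with a misassigned causal variant;
#' * `population-specific`: significant in exactly one study;
#' * `non-replicated`: significant in neither.
#'
#' @param study_a,study_b `assoc_result` tibbles with harmonised SNP sets.
#' @param truth Design truth tibble with `snp_id` and optional `partner_id`
#'   (e.g. [scenario_truth()]).
#' @param alpha_a,alpha_b Per-study significance thresholds (defaults:
#'   Bonferroni at 0.05 over each study's test count).
#' @return Tibble: `snp_id`, `p_a`, `p_b`, `classification`.
#' @export
replication_report <- function(study_a, study_b, truth,
                               alpha_a = NULL, alpha_b = NULL) {
  if (is.null(truth) || nrow(truth) == 0L) abort("design truth is missing")
  if (is.null(alpha_a)) alpha_a <- bonferroni_threshold(0.05, sum(!is.na(study_a$p)))
  if (is.null(alpha_b)) alpha_b <- bonferroni_threshold(0.05, sum(!is.na(study_b$p)))
  get_p <- function(study, ids) study$p[match(ids, study$id)]
  get_b <- function(study, ids) study$beta[match(ids, study$id)]
  p_a <- get_p(study_a, truth$snp_id)
  p_b <- get_p(study_b, truth$snp_id)
  b_a <- get_b(study_a, truth$snp_id)
  b_b <- get_b(study_b, truth$snp_id)
  partner <- if ("partner_id" %in% names(truth)) truth$partner_id else
    rep(NA_character_, nrow(truth))
  p_b_partner <- get_p(study_b, partner)
  cls <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    sig_a <- isTRUE(p_a[i] <= alpha_a)
    sig_b <- isTRUE(p_b[i] <= alpha_b)
    concord <- isTRUE(b_a[i] * b_b[i] > 0)
    sig_b_partner <- isTRUE(p_b_partner[i] <= alpha_b)
    cls[i] <- if (sig_a && sig_b && concord) "replicated-same-SNP"
    else if (sig_a && sig_b_partner) "replicated-via-LD-partner"
    else if (xor(sig_a, sig_b)) "population-specific"
    else "non-replicated"
  }
  tibble::tibble(snp_id = truth$snp_id, p_a = p_a, p_b = p_b,
                 classification = cls)
}
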