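#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an association result
#'
#' @param x An `assoc_result`.
#' @param ... Unused.
#' @return A plain tibble (one row per SNP) with a `test` column.
#' @method tidy assoc_result
#' @export
tidy.assoc_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$test <- attr(x, "test_name")
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of an association result
#'
#' @param x An `assoc_result`.
#' @param ... Unused.
#' @return Tibble: test, n_snps, n_tested, min_p, lambda_gc (NA when fewer
#'   than 100 p-values), n_flagged.
#' @method glance assoc_result
#' @export
glance.assoc_result <- function(x, ...) {
  tibble::tibble(
    test = attr(x, "test_name"),
    n_snps = nrow(x),
    n_tested = sum(!is.na(x$p) | !is.na(x$log_bf) | !is.na(x$ppa)),
    min_p = if (any(!is.na(x$p))) min(x$p, na.rm = TRUE) else NA_real_,
    lambda_gc = tryCatch(lambda_gc(x), error = function(e) NA_real_),
    n_flagged = sum(!is.na(x$qc_flag)))
}

#' Tidy a meta-analysis result
#'
#' @param x A `meta_result`.
#' @param ... Unused.
#' @return Long tibble: id, model (fe/re/re2/be), estimate, std_error,
#'   statistic, p_value.
#' @method tidy meta_result
#' @export
tidy.meta_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(id = x$id, model = "fe", estimate = x$fe_beta,
                   std_error = x$fe_se, statistic = x$fe_z, p_value = x$fe_p),
    tibble::tibble(id = x$id, model = "re", estimate = x$re_beta,
                   std_error = x$re_se, statistic = x$re_beta / x$re_se,
                   p_value = x$re_p),
    tibble::tibble(id = x$id, model = "re2", estimate = x$re_beta,
                   std_error = NA_real_, statistic = x$re2_stat,
                   p_value = x$re2_p),
    tibble::tibble(id = x$id, model = "be", estimate = NA_real_,
                   std_error = NA_real_, statistic = x$be_z,
                   p_value = x$be_p))
}

#' One-row summary of a meta-analysis result
#'
#' @param x A `meta_result`.
#' @param ... Unused.
#' @return Tibble: n_snps, k (studies), mean_i2, n_heterogeneous (I2 > 50).
#' @method glance meta_result
#' @export
glance.meta_result <- function(x, ...) {
  tibble::tibble(n_snps = nrow(x), k = x$k[1], mean_i2 = mean(x$i2),
                 n_heterogeneous = sum(x$i2 > 50))
}

#' Tidy a supervised ancestry estimate
#'
#' @param x An `ancestry_estimate`.
#' @param ... Unused.
#' @return Long tibble: individual, ancestry, proportion, flag.
#' @method tidy ancestry_estimate
#' @export
tidy.ancestry_estimate <- function(x, ...) {
  q <- x$proportions
  tibble::tibble(
    individual = rep(seq_len(nrow(q)), times = ncol(q)),
    ancestry = rep(seq_len(ncol(q)) - 1L, each = nrow(q)),
    proportion = as.numeric(q),
    flag = x$flag)
}
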