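#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_abline geom_col
#'   geom_hline labs facet_wrap theme_minimal position_stack
#' @export
ggplot2::autoplot

#' Manhattan / QQ plot of an association result
#'
#' @param object An `assoc_result`.
#' @param type `"manhattan"` or `"qq"`.
#' @param threshold Optional p-value threshold drawn as a horizontal line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot assoc_result
#' @export
autoplot.assoc_result <- function(object, type = c("manhattan", "qq"),
                                  threshold = NULL, ...) {
  type <- match.arg(type)
  tabs <- plot_tables(object)
  if (type == "manhattan") {
    p <- ggplot(tabs$manhattan,
                aes(x = .data$pos, y = .data$neglog10p, colour = .data$chrom)) +
      geom_point(size = 0.6, show.legend = FALSE) +
      facet_wrap(~chrom, nrow = 1, scales = "free_x") +
      labs(x = "position (bp)", y = expression(-log[10](p)),
           title = attr(object, "test_name")) +
      theme_minimal()
    if (!is.null(threshold)) {
      p <- p + geom_hline(yintercept = -log10(threshold), linetype = 2)
    }
    p
  } else {
    ggplot(tabs$qq, aes(x = .data$expected, y = .data$observed)) +
      geom_point(size = 0.6) +
      geom_abline(slope = 1, intercept = 0, linetype = 2) +
      labs(x = expression(expected - log[10](p)),
           y = expression(observed - log[10](p)),
           title = attr(object, "test_name")) +
      theme_minimal()
  }
}

#' Power / FPR bars for a benchmark report
#'
#' @param object An `eval_report` from [benchmark()].
#' @param metric `"power"` or `"fpr"`.
#' @param ... Unused.
#' @return A ggplot object (mean over seeds, faceted by scenario).
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, metric = c("power", "fpr"), ...) {
  metric <- match.arg(metric)
  dat <- object |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$scenario, .data$test) |>
    dplyr::summarise(value = mean(.data[[metric]], na.rm = TRUE),
                     .groups = "drop")
  ggplot(dat, aes(x = .data$test, y = .data$value)) +
    geom_col() +
    facet_wrap(~scenario) +
    labs(x = NULL, y = metric) +
    theme_minimal()
}

#' Stacked global-ancestry bar plot
#'
#' @param object An `ancestry_estimate`.
#' @param ... Unused.
#' @return A ggplot object (individuals ordered by first-ancestry
#'   proportion).
#' @method autoplot ancestry_estimate
#' @export
autoplot.ancestry_estimate <- function(object, ...) {
  d <- tidy.ancestry_estimate(object)
  ord <- order(object$proportions[, 1])
  d$individual <- factor(d$individual, levels = ord)
  ggplot(d, aes(x = .data$individual, y = .data$proportion,
                fill = factor(.data$ancestry))) +
    geom_col(width = 1, position = position_stack()) +
    labs(x = "individual", y = "ancestry proportion", fill = "ancestry") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' PCA scatter for a cohort or GRM
#'
#' @param x A `cohort` or `grm`.
#' @param groups Optional grouping vector (e.g. phenotype or population).
#' @param k Number of PCs to compute.
#' @return A ggplot of PC1 vs PC2.
#' @export
plot_pca <- function(x, groups = NULL, k = 2) {
  pc <- grm_pca(x, k = max(2, k))
  d <- tibble::tibble(PC1 = pc$scores[, 1], PC2 = pc$scores[, 2],
                      group = if (is.null(groups)) "all" else as.factor(groups))
  ggplot(d, aes(x = .data$PC1, y = .data$PC2, colour = .data$group)) +
    geom_point(size = 0.8) +
    theme_minimal()
}
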