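#' Stacked promoter-type composition plot
#'
#' @param freq_table Tibble from [frequency_table()].
#' @return A ggplot.
#' @export
plot_type_frequencies <- function(freq_table) {
  df <- freq_table[freq_table$population != "ALL", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$population,
                                   y = .data$frequency,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "frequency", fill = "promoter type") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ppa_result <- function(object, ...) {
  long <- tidyr::unnest(
    tibble::as_tibble(object)[, c("population", "activities")],
    "activities")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$population,
                                     y = .data$activities)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.2, size = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red",
                          size = 2) +
    ggplot2::labs(x = NULL, y = "individual promoter activity",
                  title = "Population promoter activity (red = PPA)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fold_comparison <- function(object, ...) {
  folds <- attr(object, "folds")
  ggplot2::ggplot(folds, ggplot2::aes(x = .data$fold)) +
    ggplot2::geom_histogram(bins = 15, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(object$ci_lower, object$ci_upper),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$focal_fold, colour = "red") +
    ggplot2::labs(x = "frequency fold (panel SNPs)", y = "count",
                  title = sprintf("focal fold %.2f is %s the %d%% interval",
                                  object$focal_fold, object$focal_flag,
                                  99)) +
    ggplot2::theme_minimal()
}

#' Tract-scan plot: shared-tract length per partner
#'
#' @param ranked Tibble from [rank_tract_partners()].
#' @param top Show the `top` longest partners.
#' @return A ggplot.
#' @export
plot_tract_ranking <- function(ranked, top = 20) {
  df <- utils::head(ranked, top)
  df$partner <- factor(df$partner, levels = rev(df$partner))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$length_bp,
                                        y = .data$partner))
  if ("promoter_type" %in% names(df)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$promoter_type))
  } else {
    p <- p + ggplot2::geom_col()
  }
  p + ggplot2::labs(x = "identical tract length (bp)", y = NULL) +
    ggplot2::theme_minimal()
}
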