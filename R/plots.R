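# ggplot2 views of the result tables.

#' Volcano plot of a differential result
#'
#' log2 fold change against -log10 P, with the volcano rule's selected
#' species coloured by direction.
#'
#' @param results Output of [select_differential()].
#' @return A ggplot.
#' @export
plot_volcano <- function(results) {
  df <- results |>
    dplyr::mutate(
      log2fc = log2(.data$fc),
      neglogp = -log10(.data$p),
      status = dplyr::case_when(
        .data$volcano & .data$direction == "up" ~ "up",
        .data$volcano & .data$direction == "down" ~ "down",
        TRUE ~ "ns")
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$neglogp,
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(up = "red", down = "blue",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 P") +
    ggplot2::theme_minimal()
}

#' S-plot of a PLS-DA model
#'
#' @param fit A `plsda_fit`.
#' @param vip_min Species with VIP above this are highlighted.
#' @return A ggplot.
#' @export
plot_splot <- function(fit, vip_min = 1) {
  df <- splot_coords(fit) |>
    dplyr::left_join(fit$vip, by = "component")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cov_t1, y = .data$corr_t1,
                                   colour = .data$vip > vip_min)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "cov(t1, x)", y = "corr(t1, x)", colour = "VIP > 1") +
    ggplot2::theme_minimal()
}

#' SUS-plot of two PLS-DA models
#'
#' @param fit1,fit2 `plsda_fit` objects for the two comparisons.
#' @return A ggplot.
#' @export
plot_sus <- function(fit1, fit2) {
  df <- sus_coords(fit1, fit2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$corr1, y = .data$corr2)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "corr(t1, x), comparison 1",
                  y = "corr(t1, x), comparison 2") +
    ggplot2::theme_minimal()
}

#' Cumulative QC distributions
#'
#' Empirical cumulative curves of per-species QC CV%, peak FWHM and
#' |predicted - observed| RT from a [robustness_summary()].
#'
#' @param report A `qc_report`.
#' @return A ggplot.
#' @export
plot_qc_report <- function(report) {
  pieces <- list()
  if (!is.null(report$cv_by_subclass)) {
    pieces$`CV %` <- tibble(value = report$cv_by_subclass$cv_pct)
  }
  if (!is.null(report$fwhm) && nrow(report$fwhm) > 0) {
    pieces$`FWHM (min)` <- tibble(value = report$fwhm$fwhm)
  }
  if (!is.null(report$rt_dev)) {
    pieces$`|dRT| (min)` <- tibble(value = report$rt_dev$abs_dev)
  }
  df <- dplyr::bind_rows(pieces, .id = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::stat_ecdf() +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "cumulative fraction") +
    ggplot2::theme_minimal()
}
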