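# Diagnostic figures for the main result types.

#' Isotope bi-plot of consumers and sources
#'
#' d13C against d15N with group means +/- SE, the standard mixing-polygon
#' view of consumers relative to their potential sources.
#'
#' @param samples Isotope sample tibble.
#' @return A ggplot object.
#' @export
plot_isotope_biplot <- function(samples) {
  summ <- isotope_group_summary(samples)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$d13C_mean, y = .data$d15N_mean,
                                     colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$d15N_mean - .data$d15N_se,
                                        ymax = .data$d15N_mean + .data$d15N_se),
                           width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$d13C_mean - .data$d13C_se,
                                         xmax = .data$d13C_mean + .data$d13C_se),
                            height = 0) +
    ggplot2::labs(x = expression(delta^13 * C ~ "(\u2030)"),
                  y = expression(delta^15 * N ~ "(\u2030)"),
                  colour = NULL, title = "Stable isotope bi-plot") +
    ggplot2::theme_minimal()
}

#' Selectivity heat map
#'
#' Month-by-taxon tile plot of Pearre's C, annotated with the significance
#' flags (+/-) of the chi-square test; untestable cells are blank.
#'
#' @param sel Output of [monthly_selectivity()].
#' @return A ggplot object.
#' @export
plot_selectivity <- function(sel) {
  sel$flag <- ifelse(is.na(sel$direction) | sel$direction == "0", "", sel$direction)
  ggplot2::ggplot(sel, ggplot2::aes(x = .data$month, y = .data$taxon,
                                    fill = .data$C)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$flag)) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearre C",
                  title = "Prey selectivity by month") +
    ggplot2::theme_minimal()
}

#' Fatty-acid biomarker ratios by group
#'
#' Mean +/- SE of the n-3/n-6, PUFA/SFA and EPA/DHA ratios across months,
#' faceted by ratio with sex/tissue colour coding when present.
#'
#' @param stats Output of [fa_group_stats()].
#' @return A ggplot object.
#' @export
plot_fa_ratios <- function(stats) {
  ratio_cols <- c("n3_n6", "pufa_sfa", "epa_dha")
  long <- stats |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(c(paste0(ratio_cols, "_mean"), paste0(ratio_cols, "_se"))),
      names_to = c("ratio", ".value"),
      names_pattern = "(n3_n6|pufa_sfa|epa_dha)_(mean|se)"
    )
  aes_col <- if (all(c("sex", "tissue") %in% names(stats))) {
    ggplot2::aes(x = .data$month, y = .data$mean,
                 colour = interaction(.data$sex, .data$tissue), group = interaction(.data$sex, .data$tissue))
  } else {
    ggplot2::aes(x = .data$month, y = .data$mean, group = 1)
  }
  ggplot2::ggplot(long, aes_col) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se),
                             size = 0.3) +
    ggplot2::facet_wrap(~ratio, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Ratio", colour = NULL,
                  title = "Fatty-acid biomarker ratios") +
    ggplot2::theme_minimal()
}
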