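# Stable isotope arithmetic: delta notation and trophic level from d15N
# enrichment over a calanoid-copepod baseline.

#' Isotope ratio to delta notation
#'
#' \eqn{\delta = (R_{sample}/R_{standard} - 1) \times 10^3} in per-mil,
#' relative to the international standard (VPDB for carbon, atmospheric N2
#' for nitrogen).
#'
#' @param R_sample Isotope ratio(s) of the sample (e.g. 13C/12C); >= 0.
#' @param R_standard Isotope ratio of the standard; > 0.
#' @return Delta value(s) in per-mil.
#' @export
#' @examples
#' delta_value(1.0032, 1) # 3.2 permil
delta_value <- function(R_sample, R_standard) {
  if (any(R_standard <= 0)) abort("R_standard must be > 0")
  if (any(R_sample < 0)) abort("R_sample must be >= 0")
  (R_sample / R_standard - 1) * 1e3
}

#' Invert delta notation back to a ratio
#'
#' @param delta Delta value(s) in per-mil.
#' @param R_standard Isotope ratio of the standard; > 0.
#' @return Sample isotope ratio(s).
#' @export
ratio_from_delta <- function(delta, R_standard) {
  if (any(R_standard <= 0)) abort("R_standard must be > 0")
  (delta / 1e3 + 1) * R_standard
}

#' Trophic level from d15N enrichment over a baseline
#'
#' \deqn{TL = (\delta^{15}N_f - \delta^{15}N_{ref}) / \Delta + TL_{ref}}
#' where \eqn{\Delta} is the per-level nitrogen enrichment (default 3.2
#' per-mil) and the baseline organism (default mesozooplanktonic calanoid
#' copepods) sits at `tl_ref = 2`.
#'
#' @param d15N_f Consumer d15N in per-mil (vectorized).
#' @param d15N_ref Baseline d15N in per-mil (scalar or vector).
#' @param tl_ref Trophic level of the baseline organism (default 2).
#' @param enrichment Per-level d15N enrichment in per-mil (default 3.2; > 0).
#' @param group Optional group labels carried into the output.
#' @return Tibble with `group`, `d15N_f`, `d15N_ref`, `tl_ref`, `enrichment`,
#'   and the estimated `tl`.
#' @export
#' @examples
#' trophic_level(5.0, d15N_ref = 2.44) # TL 2.8
trophic_level <- function(d15N_f, d15N_ref, tl_ref = 2, enrichment = 3.2,
                          group = NULL) {
  if (any(enrichment <= 0)) abort("enrichment must be > 0 permil per level")
  out <- tibble(
    d15N_f = as.numeric(d15N_f),
    d15N_ref = as.numeric(d15N_ref),
    tl_ref = tl_ref,
    enrichment = enrichment
  )
  out$tl <- (out$d15N_f - out$d15N_ref) / out$enrichment + out$tl_ref
  if (!is.null(group)) out <- bind_cols(tibble(group = group), out)
  out
}

#' Per-group isotope summaries
#'
#' Arithmetic mean and standard error of d13C and d15N per group (month or
#' size class). Groups listed in `order` come back in that order; empty
#' groups are skipped with a warning.
#'
#' @param samples Isotope sample tibble ([read_isotope_samples()] layout).
#' @param by Grouping column (default `"group"`).
#' @param order Optional label order (e.g. [paper_months()]).
#' @return Tibble with per-group `n`, `d13C_mean`, `d13C_se`, `d15N_mean`,
#'   `d15N_se` and `se_defined`.
#' @export
isotope_group_summary <- function(samples, by = "group", order = NULL) {
  if (!by %in% names(samples)) abort(sprintf("No '%s' column", by))
  if (!is.null(order)) {
    missing_groups <- setdiff(order, unique(as.character(samples[[by]])))
    if (length(missing_groups)) {
      warn(sprintf("Skipping empty group(s): %s", paste(missing_groups, collapse = ", ")))
    }
  }
  out <- samples |>
    group_by(group = .data[[by]]) |>
    summarise(
      n = dplyr::n(),
      d13C_mean = mean(.data$d13C),
      d13C_se = ifelse(dplyr::n() > 1, sd(.data$d13C) / sqrt(dplyr::n()), 0),
      d15N_mean = mean(.data$d15N),
      d15N_se = ifelse(dplyr::n() > 1, sd(.data$d15N) / sqrt(dplyr::n()), 0),
      se_defined = dplyr::n() > 1,
      .groups = "drop"
    )
  if (!is.null(order)) {
    out <- out[order(match(out$group, order)), , drop = FALSE]
  }
  out
}
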