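# Fatty-acid shorthand classification and biomarker ratios.
#
# Shorthand "C<carbons>:<double bonds>n-<omega>" (omega suffix optional,
# parentheses tolerated). Saturation classes: SFA (0 double bonds), MUFA (1),
# PUFA (>= 2). Biomarker ratios follow standard trophic usage: n-3/n-6,
# PUFA/SFA, and EPA/DHA.

fa_pattern <- "^C(\\d+):(\\d+)(?:n-(\\d+))?$"

# Canonical aliases. The common-name labels occasionally get crossed in
# print; canonically EPA = C20:5n-3, DHA = C22:6n-3, AA = C20:4n-6.
fa_aliases <- c(
  EPA = "C20:5n-3",
  DHA = "C22:6n-3",
  AA = "C20:4n-6",
  palmitic = "C16:0"
)

is_fa_name <- function(x) {
  grepl(fa_pattern, normalize_fa_name(x))
}

resolve_fa_name <- function(x, allow_alias = TRUE) {
  y <- normalize_fa_name(x)
  if (allow_alias) {
    hit <- match(y, names(fa_aliases))
    y[!is.na(hit)] <- fa_aliases[hit[!is.na(hit)]]
  }
  y
}

#' Classify fatty acids from shorthand nomenclature
#'
#' Parses names like `"C16:0"`, `"C18:1n-9"` or `"C18:1(n-9)"` (and the
#' aliases EPA, DHA, AA, palmitic) into carbons, double bonds, omega family
#' and saturation class.
#'
#' @param name Character vector of FA shorthand names.
#' @param allow_alias Resolve common-name aliases (default TRUE); a strict
#'   caller can disable this to accept shorthand only.
#' @return Tibble with `name` (canonical shorthand), `carbons`,
#'   `double_bonds`, `omega` (NA when unlabelled), `saturation_class`.
#' @export
#' @examples
#' classify_fa(c("C16:0", "C18:1(n-9)", "EPA"))
classify_fa <- function(name, allow_alias = TRUE) {
  canon <- resolve_fa_name(name, allow_alias)
  bad <- canon[!grepl(fa_pattern, canon)]
  if (length(bad)) {
    abort(sprintf("Malformed FA shorthand: %s", paste(unique(bad), collapse = ", ")))
  }
  m <- regmatches(canon, regexec(fa_pattern, canon))
  carbons <- vapply(m, function(g) as.integer(g[2]), integer(1))
  db <- vapply(m, function(g) as.integer(g[3]), integer(1))
  omega <- vapply(m, function(g) if (g[4] == "") NA_integer_ else as.integer(g[4]),
                  integer(1))
  tibble(
    name = canon, carbons = carbons, double_bonds = db, omega = omega,
    saturation_class = dplyr::case_when(
      db == 0 ~ "SFA",
      db == 1 ~ "MUFA",
      TRUE ~ "PUFA"
    )
  )
}

#' Per-sample fatty-acid totals, class totals and biomarker ratios
#'
#' For each profile row: total FA concentration, per-class totals and
#' percentages (SFA/MUFA/PUFA), and the ratios n-3/n-6, PUFA/SFA and
#' EPA/DHA. Zero denominators yield `NA` (undefined), never infinity. FAs
#' without an omega label contribute to saturation classes but not to the
#' n-3/n-6 ratio; columns that are not parseable FA shorthand are ignored
#' with the same rule as [read_fa_profiles()].
#'
#' @param profiles Fatty-acid tibble ([read_fa_profiles()] layout).
#' @return Tibble keyed like `profiles` with `total`, `sfa`, `mufa`, `pufa`,
#'   `sfa_pct`, `mufa_pct`, `pufa_pct`, `n3_n6`, `pufa_sfa`, `epa_dha`.
#' @export
fa_summary <- function(profiles) {
  meta <- intersect(meta_cols_fa, names(profiles))
  fa_cols <- setdiff(names(profiles), meta_cols_fa)
  fa_cols <- fa_cols[is_fa_name(fa_cols)]
  if (length(fa_cols) == 0L) abort("No parseable FA columns")
  cls <- classify_fa(fa_cols)
  conc <- as.matrix(profiles[, fa_cols, drop = FALSE])
  if (any(conc < 0)) abort("Negative FA concentrations")
  if (any(rowSums(conc) == 0)) abort("All-zero FA profile(s)")

  total <- rowSums(conc)
  class_sum <- function(keep) {
    if (!any(keep)) return(rep(0, nrow(conc)))
    rowSums(conc[, keep, drop = FALSE])
  }
  sfa <- class_sum(cls$saturation_class == "SFA")
  mufa <- class_sum(cls$saturation_class == "MUFA")
  pufa <- class_sum(cls$saturation_class == "PUFA")
  n3 <- class_sum(!is.na(cls$omega) & cls$omega == 3)
  n6 <- class_sum(!is.na(cls$omega) & cls$omega == 6)
  epa <- class_sum(cls$name == fa_aliases[["EPA"]])
  dha <- class_sum(cls$name == fa_aliases[["DHA"]])

  safe_ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  bind_cols(
    profiles[, meta, drop = FALSE],
    tibble(
      total = total, sfa = sfa, mufa = mufa, pufa = pufa,
      sfa_pct = sfa / total * 100, mufa_pct = mufa / total * 100,
      pufa_pct = pufa / total * 100,
      n3_n6 = safe_ratio(n3, n6),
      pufa_sfa = safe_ratio(pufa, sfa),
      epa_dha = safe_ratio(epa, dha)
    )
  )
}

#' Group statistics of fatty-acid summaries
#'
#' Mean and standard error of total concentration, class percentages and
#' biomarker ratios per group (any subset of month, sex, tissue). Undefined
#' ratios are dropped from their group mean; empty groups are skipped.
#'
#' @param profiles Fatty-acid tibble.
#' @param by Grouping columns, default `c("month", "sex", "tissue")`.
#' @return Tibble of per-group `<stat>_mean` / `<stat>_se` columns plus `n`.
#' @export
fa_group_stats <- function(profiles, by = c("month", "sex", "tissue")) {
  miss <- setdiff(by, names(profiles))
  if (length(miss)) abort(sprintf("Missing grouping column(s): %s", paste(miss, collapse = ", ")))
  summ <- fa_summary(profiles)
  stats_cols <- c("total", "sfa_pct", "mufa_pct", "pufa_pct",
                  "n3_n6", "pufa_sfa", "epa_dha")
  summ |>
    group_by(across(dplyr::all_of(by))) |>
    summarise(
      n = dplyr::n(),
      across(dplyr::all_of(stats_cols),
             list(mean = ~ mean(.x, na.rm = TRUE),
                  se = ~ {
                    x <- .x[!is.na(.x)]
                    if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
                  })),
      .groups = "drop"
    ) |>
    arrange(across(dplyr::all_of(by)))
}

#' Gonad-to-soma contrast of total fatty-acid concentration
#'
#' Ratio of mean total FA concentration in gonad versus somatic tissue,
#' overall and per month when available.
#'
#' @param profiles Fatty-acid tibble containing both tissues.
#' @return Tibble with `scope`, `gonad_mean`, `soma_mean`, `ratio`.
#' @export
fa_tissue_contrast <- function(profiles) {
  summ <- fa_summary(profiles)
  if (!all(c("gonad", "soma") %in% summ$tissue)) {
    abort("Need both gonad and soma tissue rows")
  }
  overall <- summ |>
    group_by(.data$tissue) |>
    summarise(mean_total = mean(.data$total), .groups = "drop")
  g <- overall$mean_total[overall$tissue == "gonad"]
  s <- overall$mean_total[overall$tissue == "soma"]
  out <- tibble(scope = "overall", gonad_mean = g, soma_mean = s, ratio = g / s)
  if ("month" %in% names(summ)) {
    per_month <- summ |>
      filter(.data$tissue %in% c("gonad", "soma")) |>
      group_by(.data$month, .data$tissue) |>
      summarise(mean_total = mean(.data$total), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "tissue", values_from = "mean_total") |>
      filter(!is.na(.data$gonad) & !is.na(.data$soma)) |>
      mutate(scope = as.character(.data$month), gonad_mean = .data$gonad,
             soma_mean = .data$soma, ratio = .data$gonad / .data$soma) |>
      select("scope", "gonad_mean", "soma_mean", "ratio")
    out <- bind_rows(out, per_month)
  }
  out
}
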