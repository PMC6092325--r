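# Prey electivity: Pearre's index on diet-vs-environment 2x2 tables with an
# ordinary (uncorrected) chi-square test, plus the stomach-content summary
# statistics (monthly totals and per-taxon means) that frame it.

taxon_cols <- function(tbl, meta) setdiff(names(tbl), meta)

#' Build a diet-versus-environment 2x2 contingency table
#'
#' For a focal taxon in a given month: the diet margin pools integer prey
#' counts over all predators sampled that month; the environment margin
#' converts densities (individuals per cubic metre) to integer pseudo-counts
#' under the chosen policy, rounding half away from zero.
#'
#' Pseudo-count policies (`env_pseudo_n`):
#' \describe{
#'   \item{`"raw"`}{densities rounded as-is (use when densities already are
#'     counts, e.g. individuals in the sampled volume).}
#'   \item{`"volume"`}{densities times `volume_sampled` where available,
#'     falling back to `"match"` otherwise (default).}
#'   \item{`"match"`}{density proportions times the pooled diet total of that
#'     month, equalizing the two margins' n.}
#'   \item{a number}{density proportions times that fixed pseudo-n.}
#' }
#'
#' @param diet Prey count table ([read_prey_counts()] layout).
#' @param env Environment availability table ([read_env_availability()]).
#' @param taxon Focal taxon name.
#' @param month Month label present in both tables.
#' @param env_pseudo_n Environment pseudo-count policy (above).
#' @return One-row tibble with `a_d`, `b_d` (diet focal/other), `a_e`, `b_e`
#'   (environment focal/other) and grand total `n`.
#' @export
build_contingency <- function(diet, env, taxon, month,
                              env_pseudo_n = "volume") {
  diet_taxa <- taxon_cols(diet, meta_cols_prey)
  env_taxa <- taxon_cols(env, meta_cols_env)
  if (!taxon %in% union(diet_taxa, env_taxa)) {
    abort(sprintf("Taxon '%s' present in neither diet nor environment", taxon))
  }
  dm <- diet[as.character(diet$month) == month, , drop = FALSE]
  em <- env[as.character(env$month) == month, , drop = FALSE]
  if (nrow(dm) == 0L) abort(sprintf("Month '%s' absent from diet table", month))
  if (nrow(em) == 0L) abort(sprintf("Month '%s' absent from environment table", month))

  d_counts <- vapply(diet_taxa, function(tx) sum(dm[[tx]]), numeric(1))
  e_dens <- vapply(env_taxa, function(tx) sum(em[[tx]]), numeric(1))
  if (sum(d_counts) + sum(e_dens) == 0) {
    abort(sprintf("All-zero diet and environment margins in month '%s'", month))
  }

  a_d <- if (taxon %in% diet_taxa) d_counts[[taxon]] else 0
  b_d <- sum(d_counts) - a_d

  e_counts <- env_pseudo_counts(e_dens, em, env_pseudo_n,
                                diet_total = sum(d_counts))
  a_e <- if (taxon %in% env_taxa) e_counts[[taxon]] else 0
  b_e <- sum(e_counts) - a_e

  if (a_d + a_e == 0) {
    abort(sprintf("Taxon '%s' absent from both margins in month '%s': not testable",
                  taxon, month))
  }
  tibble(taxon = taxon, month = month,
         a_d = a_d, b_d = b_d, a_e = a_e, b_e = b_e,
         n = a_d + b_d + a_e + b_e)
}

env_pseudo_counts <- function(dens, env_month, policy, diet_total) {
  tot <- sum(dens)
  if (tot == 0) return(round_half_up(dens))
  if (identical(policy, "raw")) return(round_half_up(dens))
  if (identical(policy, "volume")) {
    if ("volume_sampled" %in% names(env_month) &&
        all(is.finite(env_month$volume_sampled))) {
      vol <- sum(env_month$volume_sampled)
      return(round_half_up(dens / nrow(env_month) * vol))
    }
    policy <- "match"
  }
  pseudo_n <- if (identical(policy, "match")) diet_total else {
    if (!is.numeric(policy) || policy <= 0) {
      abort("env_pseudo_n must be 'raw', 'volume', 'match' or a positive number")
    }
    policy
  }
  round_half_up(dens / tot * pseudo_n)
}

#' Pearre's electivity index with chi-square significance
#'
#' For a 2x2 table of focal-vs-other counts in diet and environment,
#' \deqn{C = (a_d b_e - b_d a_e) / \sqrt{(a_d+a_e)(b_d+b_e)(a_d+b_d)(a_e+b_e)}}
#' with \eqn{\chi^2 = n C^2} (the standard uncorrected 2x2 chi-square) on
#' 1 df. Direction is `"+"` for significant positive selection, `"-"` for
#' significant negative selection, `"0"` otherwise.
#'
#' @param tab One-row tibble from [build_contingency()] (or anything with
#'   `a_d`, `b_d`, `a_e`, `b_e`).
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble with `C`, `chi2`, `p`, `direction`.
#' @export
#' @examples
#' pearre_index(tibble::tibble(a_d = 30, b_d = 70, a_e = 10, b_e = 90))
pearre_index <- function(tab, alpha = 0.05) {
  a_d <- tab$a_d; b_d <- tab$b_d; a_e <- tab$a_e; b_e <- tab$b_e
  n <- a_d + b_d + a_e + b_e
  if (n <= 0) abort("Empty contingency table")
  margins <- c(a_d + a_e, b_d + b_e, a_d + b_d, a_e + b_e)
  if (any(margins == 0)) {
    abort("Pearre's index undefined: a margin of the 2x2 table is zero")
  }
  C <- (a_d * b_e - b_d * a_e) / sqrt(prod(margins))
  chi2 <- n * C^2
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  direction <- if (p <= alpha && C > 0) "+" else if (p <= alpha && C < 0) "-" else "0"
  tibble(C = C, chi2 = chi2, p = p, direction = direction)
}

#' Monthly prey-selectivity table
#'
#' Runs [build_contingency()] + [pearre_index()] for every taxon-by-month
#' cell over the shared taxon vocabulary. Cells where the focal taxon is
#' absent from both margins (or a margin is degenerate) are marked not
#' testable rather than scored.
#'
#' @inheritParams build_contingency
#' @param alpha Significance level for the chi-square test.
#' @return Tibble with one row per month-by-taxon cell: `C`, `chi2`, `p`,
#'   `direction` and logical `testable`.
#' @export
monthly_selectivity <- function(diet, env, alpha = 0.05,
                                env_pseudo_n = "volume") {
  taxa <- union(taxon_cols(diet, meta_cols_prey), taxon_cols(env, meta_cols_env))
  cal <- if (is.factor(diet$month)) levels(diet$month) else paper_months()
  months <- intersect(cal, unique(as.character(diet$month)))
  months <- months[months %in% as.character(env$month)]
  grid <- tidyr::expand_grid(month = months, taxon = taxa)
  rows <- purrr::pmap(grid, function(month, taxon) {
    res <- tryCatch({
      ct <- build_contingency(diet, env, taxon, month, env_pseudo_n)
      sc <- pearre_index(ct, alpha)
      bind_cols(tibble(month = month, taxon = taxon, testable = TRUE), sc)
    }, error = function(e) {
      tibble(month = month, taxon = taxon, testable = FALSE,
             C = NA_real_, chi2 = NA_real_, p = NA_real_,
             direction = NA_character_)
    })
    res
  })
  out <- bind_rows(rows)
  out$month <- as_month(out$month, cal)
  arrange(out, .data$month, .data$taxon)
}

#' Monthly total prey per medusa
#'
#' Mean and standard error over predators of their summed stomach counts,
#' per month (the "N +/- SE prey per medusa" statistic).
#'
#' @param diet Prey count table.
#' @return Tibble with `month`, `n` predators, `mean`, `se`, `se_defined`.
#' @export
diet_totals <- function(diet) {
  taxa <- taxon_cols(diet, meta_cols_prey)
  if (nrow(diet) == 0L) abort("Empty diet table")
  totals <- tibble(month = diet$month,
                   total = rowSums(as.matrix(diet[, taxa, drop = FALSE])))
  totals |>
    group_by(.data$month) |>
    summarise(mean_se(.data$total), .groups = "drop") |>
    arrange(.data$month)
}

#' Per-taxon monthly mean prey counts
#'
#' The per-taxon statistic of the monthly diet-composition table: for each
#' month and taxon, the mean and standard error across that month's
#' predators of the per-stomach count.
#'
#' @param diet Prey count table.
#' @return Tibble with `month`, `taxon`, `mean`, `se`, `n`, `se_defined`.
#' @export
diet_taxon_means <- function(diet) {
  taxa <- taxon_cols(diet, meta_cols_prey)
  long <- tidyr::pivot_longer(diet, dplyr::all_of(taxa),
                              names_to = "taxon", values_to = "count")
  long |>
    group_by(.data$month, .data$taxon) |>
    summarise(mean_se(.data$count), .groups = "drop") |>
    arrange(.data$month, .data$taxon)
}

#' Reconstruct per-predator counts from a monthly mean-composition table
#'
#' Published diet tables report, per month, the number of predators examined
#' and the per-taxon mean count per stomach. This builds a per-predator
#' integer count table consistent with those statistics: for each month and
#' taxon, `round(mean * n_predators)` individuals are spread as evenly as
#' possible over the month's predators, so the per-taxon monthly means of
#' the result reproduce the printed means to within rounding.
#'
#' @param means Long tibble with columns `month`, `n_predators`, `taxon`,
#'   `mean` (e.g. read from a published composition table).
#' @param months Month calendar.
#' @return Prey count tibble ([read_prey_counts()] layout).
#' @export
prey_counts_from_means <- function(means, months = paper_months()) {
  need <- c("month", "n_predators", "taxon", "mean")
  if (!all(need %in% names(means))) {
    abort(sprintf("means must have columns: %s", paste(need, collapse = ", ")))
  }
  taxa <- unique(means$taxon)
  rows <- purrr::map(unique(as.character(means$month)), function(m) {
    sub <- means[as.character(means$month) == m, ]
    np <- unique(sub$n_predators)
    if (length(np) != 1L || np < 1) abort(sprintf("Bad n_predators for month %s", m))
    out <- tibble(predator_id = sprintf("%s_%d", m, seq_len(np)), month = m)
    for (tx in taxa) {
      tot <- round(sub$mean[sub$taxon == tx] * np)
      if (length(tot) == 0L) tot <- 0
      base <- tot %/% np
      extra <- tot %% np
      out[[tx]] <- as.integer(base + (seq_len(np) <= extra))
    }
    out
  })
  out <- bind_rows(rows)
  out$month <- as_month(out$month, months)
  out
}
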