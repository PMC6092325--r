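# Seeded synthetic-data generators emulating the statistical structure the
# pipeline assumes: seasonal multinomial prey availability with selective
# predation, consumer isotopes as TEF-shifted source mixtures, and
# fatty-acid profiles with month/sex/tissue structure (gonad concentrations
# up to ~10x somatic). Every generator records its ground truth so recovery
# tests can compare estimates against it.

#' Default taxon list and seasonal availability profiles
#'
#' Mean environmental densities (individuals per cubic metre) per month and
#' taxon for a coastal Mediterranean zooplankton community: copepods peak in
#' spring, pteropods in early winter, fish eggs in spring, euphausiid
#' furcilia and ostracods stay rare (they undergo diel vertical migration
#' away from the surface by day).
#'
#' @return Tibble with `month` plus one density column per taxon.
#' @export
default_env_profiles <- function() {
  months <- paper_months()
  base <- list(
    copepods = c(800, 600, 400, 1500, 1200, 900, 700, 500),
    pteropods = c(60, 150, 20, 25, 40, 30, 10, 8),
    fish_eggs = c(30, 25, 10, 90, 70, 50, 15, 5),
    chaetognaths = c(40, 45, 15, 30, 50, 35, 20, 15),
    ostracods = c(25, 30, 10, 20, 25, 15, 10, 8),
    furcilia = c(15, 10, 5, 30, 25, 15, 8, 5),
    fish_larvae = c(8, 6, 3, 15, 12, 10, 5, 3),
    appendicularians = c(50, 40, 15, 60, 55, 45, 25, 20),
    siphonophores = c(10, 8, 4, 12, 10, 8, 6, 5)
  )
  bind_cols(tibble(month = months), as_tibble(base))
}

#' Generate an environmental availability table
#'
#' Draws per-sample densities log-normally around the configured seasonal
#' mean profiles with coefficient of variation `cv`.
#'
#' @param profiles Month-by-taxon mean density tibble
#'   ([default_env_profiles()] layout).
#' @param n_samples Net tows per month (default 1).
#' @param cv Lognormal coefficient of variation of densities (default 0.2).
#' @param volume_sampled Filtered volume per tow in cubic metres.
#' @param seed Integer seed.
#' @return Environment availability tibble ([read_env_availability()]
#'   layout) with a `truth` attribute holding the generating profiles.
#' @export
gen_environment <- function(profiles = default_env_profiles(), n_samples = 1,
                            cv = 0.2, volume_sampled = 10, seed = 1) {
  taxa <- setdiff(names(profiles), "month")
  if (length(taxa) == 0L) abort("Empty taxon list")
  if (nrow(profiles) == 0L) abort("Empty month list")
  sdlog <- sqrt(log(1 + cv^2))
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(nrow(profiles)), function(i) {
      purrr::map(seq_len(n_samples), function(s) {
        dens <- vapply(taxa, function(tx) {
          m <- profiles[[tx]][i]
          if (m <= 0) 0 else rlnorm(1, log(m) - sdlog^2 / 2, sdlog)
        }, numeric(1))
        bind_cols(tibble(sample_id = sprintf("env_%s_%d", profiles$month[i], s),
                         month = profiles$month[i],
                         volume_sampled = volume_sampled),
                  as_tibble(as.list(dens)))
      }) |> bind_rows()
    }) |> bind_rows()
    rows$month <- as_month(rows$month, profiles$month)
    attr(rows, "truth") <- list(profiles = profiles, cv = cv, seed = seed)
    rows
  })
}

#' Generate stomach-content prey counts under selective predation
#'
#' Each predator's total prey count is Poisson(`mean_total`); prey taxa are
#' multinomial with probabilities proportional to selectivity weight times
#' month-specific availability. Weight 1 for every taxon is neutral
#' (proportional) feeding.
#'
#' @param env Environment availability table.
#' @param weights Named positive selectivity weights per taxon; missing
#'   taxa default to 1.
#' @param n_predators Predators per month: scalar or vector named by month.
#' @param mean_total Expected prey per stomach: scalar or named by month.
#' @param seed Integer seed.
#' @return Prey count tibble ([read_prey_counts()] layout) with a `truth`
#'   attribute (weights, availability used).
#' @export
gen_stomachs <- function(env, weights = NULL, n_predators = 15,
                         mean_total = 25, seed = 1) {
  taxa <- setdiff(names(env), meta_cols_env)
  w <- setNames(rep(1, length(taxa)), taxa)
  if (!is.null(weights)) {
    if (any(weights <= 0)) abort("Selectivity weights must be > 0")
    w[names(weights)] <- weights
  }
  months <- levels(as_month(env$month, levels(env$month)))
  months <- months[months %in% as.character(env$month)]
  get_per_month <- function(x, m) {
    if (length(x) == 1L && is.null(names(x))) x else {
      if (!m %in% names(x)) abort(sprintf("No value for month '%s'", m))
      x[[m]]
    }
  }
  withr::with_seed(seed, {
    rows <- purrr::map(months, function(m) {
      dens <- vapply(taxa, function(tx) sum(env[[tx]][as.character(env$month) == m]),
                     numeric(1))
      if (sum(dens) == 0) abort(sprintf("Zero availability for all taxa in month '%s'", m))
      prob <- w * dens
      prob <- prob / sum(prob)
      np <- get_per_month(n_predators, m)
      mt <- get_per_month(mean_total, m)
      totals <- rpois(np, mt)
      counts <- vapply(totals, function(tt) {
        if (tt == 0) rep(0L, length(taxa)) else as.integer(rmultinom(1, tt, prob))
      }, integer(length(taxa)))
      counts <- matrix(as.integer(counts), nrow = length(taxa))
      out <- as_tibble(as.data.frame(t(counts)), .name_repair = "minimal")
      names(out) <- taxa
      bind_cols(tibble(predator_id = sprintf("med_%s_%d", m, seq_len(np)),
                       month = m), out)
    }) |> bind_rows()
    rows$month <- as_month(rows$month, levels(as_month(env$month, levels(env$month))))
    attr(rows, "truth") <- list(weights = w, seed = seed)
    rows
  })
}

#' Default plankton size-class source specification
#'
#' Three well-separated size-class sources — microplankton (<200 um),
#' mesozooplankton (200-1000 um), macrozooplankton (>1000 um) — forming a
#' non-degenerate mixing triangle in (d13C, d15N) space (per-mil): d15N
#' rises with size class while d13C separates the mid size class, so the two
#' isotopes jointly identify all three proportions.
#'
#' @return Source spec tibble for [mixture_moments()] / [sample_posterior()].
#' @export
default_sources <- function() {
  tibble(
    source = c("<200 um", "200-1000 um", ">1000 um"),
    d13C_mean = c(-23.0, -16.5, -20.5), d13C_sd = c(0.3, 0.3, 0.3),
    d15N_mean = c(1.5, 4.5, 8.0), d15N_sd = c(0.3, 0.3, 0.3)
  )
}

#' Default trophic enrichment factors
#'
#' Diet-to-consumer fractionation: 2 +/- 0.3 per-mil for d13C and
#' 3.2 +/- 0.1 per-mil for d15N.
#'
#' @return TEF tibble with `isotope`, `mean`, `sd`.
#' @export
default_tef <- function() {
  tibble(isotope = c("d13C", "d15N"), mean = c(2, 3.2), sd = c(0.3, 0.1))
}

#' Generate consumer and source isotope samples from known mixing truth
#'
#' Consumers are drawn per isotope from Normal(mixture mean, sqrt(mixture
#' variance + resid_sd^2)) where the mixture moments come from
#' [mixture_moments()] at the true proportions. Source observation samples
#' are drawn around each source's own mean/sd (no TEF).
#'
#' @param true_p True source-proportion simplex.
#' @param sources Source spec tibble (default [default_sources()]).
#' @param tef TEF tibble (default [default_tef()]).
#' @param n_consumers Number of consumer records (default 50).
#' @param resid_sd Residual sd per isotope (recycled; default 0.3).
#' @param n_source_obs Observation samples per source (default 20).
#' @param seed Integer seed.
#' @return Isotope sample tibble with `group` = `"consumer"` or the source
#'   name; `truth` attribute records all generating parameters.
#' @export
gen_isotopes <- function(true_p = c(0.45, 0.40, 0.15),
                         sources = default_sources(), tef = default_tef(),
                         n_consumers = 50, resid_sd = 0.3,
                         n_source_obs = 20, seed = 1) {
  if (any(resid_sd < 0)) abort("resid_sd must be >= 0")
  if (abs(sum(true_p) - 1) > 1e-8 || any(true_p < 0)) {
    abort("true_p must lie on the simplex")
  }
  mom <- mixture_moments(true_p, sources, tef)
  resid <- rep_len(resid_sd, nrow(mom))
  withr::with_seed(seed, {
    cons <- tibble(sample_id = sprintf("cons_%d", seq_len(n_consumers)),
                   group = "consumer")
    for (j in seq_len(nrow(mom))) {
      cons[[mom$isotope[j]]] <- rnorm(n_consumers, mom$mean[j],
                                      sqrt(mom$sd[j]^2 + resid[j]^2))
    }
    srcs <- purrr::map(seq_len(nrow(sources)), function(k) {
      out <- tibble(sample_id = sprintf("src%d_%d", k, seq_len(n_source_obs)),
                    group = sources$source[k])
      for (iso in mom$isotope) {
        out[[iso]] <- rnorm(n_source_obs, sources[[paste0(iso, "_mean")]][k],
                            sources[[paste0(iso, "_sd")]][k])
      }
      out
    }) |> bind_rows()
    out <- bind_rows(cons, srcs)
    attr(out, "truth") <- list(p = true_p, sources = sources, tef = tef,
                               resid_sd = resid, seed = seed)
    out
  })
}

#' Default fatty-acid panel with baseline somatic concentrations
#'
#' Baseline log-scale mean concentrations (ug per mg dry tissue) for a
#' compact panel spanning SFA, MUFA and PUFA, dominated by palmitic acid,
#' EPA and DHA as in gelatinous tissue.
#'
#' @return Named numeric vector of baseline concentrations.
#' @export
default_fa_panel <- function() {
  c("C14:0" = 0.8, "C16:0" = 6.0, "C17:0" = 0.5, "C18:0" = 2.5,
    "C16:1n-7" = 1.2, "C18:1n-9" = 1.8, "C20:1n-9" = 0.4, "C22:1n-11" = 0.3,
    "C18:2n-6" = 0.6, "C20:4n-6" = 1.0,
    "C18:3n-3" = 0.4, "C20:5n-3" = 2.2, "C22:6n-3" = 3.0)
}

#' Generate fatty-acid profiles with month, sex and tissue structure
#'
#' Balanced month x sex x tissue layout. Per-FA concentrations are
#' log-normal around the panel baseline with an additive log-scale month
#' effect (seasonal sinusoid scaled by `month_amplitude`), a multiplicative
#' gonad factor (default 10), and an extra female-gonad boost in configured
#' peak months (reproductive FA accumulation).
#'
#' @param panel Named baseline concentrations (default [default_fa_panel()]).
#' @param months Month calendar.
#' @param n_per_cell Samples per month x sex x tissue cell (default 3).
#' @param gonad_multiplier Gonad:soma concentration factor (default 10).
#' @param month_amplitude Log-scale amplitude of the seasonal effect
#'   (default 0.5).
#' @param female_peak_months Months with an extra female-gonad boost.
#' @param sdlog Residual log-scale sd (default 0.3).
#' @param seed Integer seed.
#' @return Fatty-acid tibble ([read_fa_profiles()] layout), balanced, with a
#'   `truth` attribute.
#' @export
gen_fa_profiles <- function(panel = default_fa_panel(), months = paper_months(),
                            n_per_cell = 3, gonad_multiplier = 10,
                            month_amplitude = 0.5,
                            female_peak_months = c("Apr", "May", "Jun"),
                            sdlog = 0.3, seed = 1) {
  if (!all(is_fa_name(names(panel)))) abort("Invalid FA name(s) in panel")
  if (n_per_cell < 1) abort("n_per_cell must be >= 1 (balanced layout)")
  grid <- tidyr::expand_grid(month = months, sex = c("female", "male"),
                             tissue = c("gonad", "soma"),
                             rep = seq_len(n_per_cell))
  phase <- (match(grid$month, months) - 1) / length(months)
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(nrow(grid)), function(i) {
      lmu <- log(panel) +
        month_amplitude * sin(2 * pi * phase[i]) +
        (if (grid$tissue[i] == "gonad") log(gonad_multiplier) else 0) +
        (if (grid$sex[i] == "female" && grid$tissue[i] == "gonad" &&
             grid$month[i] %in% female_peak_months) log(1.5) else 0)
      conc <- rlnorm(length(panel), lmu - sdlog^2 / 2, sdlog)
      bind_cols(tibble(sample_id = sprintf("fa_%04d", i), month = grid$month[i],
                       sex = grid$sex[i], tissue = grid$tissue[i]),
                as_tibble(as.list(setNames(conc, names(panel)))))
    }) |> bind_rows()
    rows$month <- as_month(rows$month, months)
    attr(rows, "truth") <- list(panel = panel, gonad_multiplier = gonad_multiplier,
                                month_amplitude = month_amplitude,
                                female_peak_months = female_peak_months,
                                sdlog = sdlog, seed = seed)
    rows
  })
}

#' Write a complete study-like synthetic dataset
#'
#' Generates and writes the full input bundle for [run_pipeline()]:
#' `env.csv`, `diet.csv`, `iso.csv`, `sources.csv`, `tef.csv`, `fa.csv` and
#' a `truth.json` ground-truth record. Defaults follow the study layout:
#' eight sampling months with the published per-month medusa counts, ~25
#' prey per stomach, positive selection for fish eggs and avoidance of
#' ostracods and furcilia with the dominant copepods taken neutrally
#' (electivity is compositional: selection weights on the dominant taxon
#' would induce apparent electivity in every other taxon), diet proportions
#' (0.45, 0.40, 0.15) over three plankton size classes, and a 10x gonad FA
#' multiplier.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; per-dataset seeds are derived from it.
#' @param weights Selectivity weights (named; 1 = neutral).
#' @param true_p True diet proportions over the size-class sources.
#' @param n_predators Medusae per month (named vector).
#' @param gonad_multiplier Gonad:soma FA factor.
#' @return Invisibly, a list of file paths plus the truth record.
#' @export
synth_paper_like <- function(out_dir, seed = 42,
                             weights = c(fish_eggs = 2, ostracods = 0.3,
                                         furcilia = 0.3),
                             true_p = c(0.45, 0.40, 0.15),
                             n_predators = c(Nov = 23, Dec = 17, Feb = 3,
                                             Apr = 12, May = 20, Jun = 27,
                                             Jul = 13, Sep = 13),
                             gonad_multiplier = 10) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  env <- gen_environment(seed = child_seed(seed, 1))
  diet <- gen_stomachs(env, weights = weights, n_predators = n_predators,
                       mean_total = 25, seed = child_seed(seed, 2))
  iso <- gen_isotopes(true_p = true_p, seed = child_seed(seed, 3))
  fa <- gen_fa_profiles(gonad_multiplier = gonad_multiplier,
                        seed = child_seed(seed, 4))

  paths <- list(
    env = file.path(out_dir, "env.csv"),
    diet = file.path(out_dir, "diet.csv"),
    isotopes = file.path(out_dir, "iso.csv"),
    sources = file.path(out_dir, "sources.csv"),
    tef = file.path(out_dir, "tef.csv"),
    fa = file.path(out_dir, "fa.csv")
  )
  write_table_csv(env, paths$env)
  write_table_csv(diet, paths$diet)
  write_table_csv(iso, paths$isotopes)
  write_table_csv(default_sources(), paths$sources)
  write_table_csv(default_tef(), paths$tef)
  write_table_csv(fa, paths$fa)

  truth <- list(
    seed = seed,
    selectivity_weights = as.list(attr(diet, "truth")$weights),
    true_p = as.list(setNames(true_p, default_sources()$source)),
    sources = default_sources(),
    tef = default_tef(),
    fa = attr(fa, "truth")[c("gonad_multiplier", "month_amplitude",
                             "female_peak_months", "sdlog")],
    files = paths
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, list(truth = truth)))
}
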