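# CSV readers/writers and validation for the four pipeline inputs.
#
# All interchange is UTF-8 CSV with "." as decimal separator. Typeset tables
# often carry the Unicode minus (U+2212); every numeric parse normalizes it
# to the ASCII hyphen. Validation reports *all* offending rows, not just the
# first.

meta_cols_prey <- c("predator_id", "month")
meta_cols_env  <- c("sample_id", "month", "volume_sampled")
meta_cols_fa   <- c("sample_id", "month", "sex", "tissue", "size_class")

read_csv_quiet <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  out <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(out) == 0L) abort(sprintf("Empty file: %s", path))
  out
}

fail_validation <- function(issues, what) {
  if (nrow(issues) == 0L) return(invisible(NULL))
  msg <- paste0(
    what, " validation failed (", nrow(issues), " issue(s)):\n",
    paste(sprintf("  row %s [%s]: %s", issues$row, issues$id, issues$problem),
          collapse = "\n")
  )
  abort(msg, class = "jellytroph_validation_error")
}

#' Read a stomach-content prey count table
#'
#' Wide CSV: one row per predator (medusa), columns `predator_id`, `month`,
#' then one column per prey taxon holding non-negative integer counts of prey
#' individuals found in that stomach. Taxa absent from a file are structural
#' zeros and can simply be omitted; [monthly_selectivity()] zero-fills
#' against the environment's taxon vocabulary.
#'
#' @param path CSV file path.
#' @param months Ordered month calendar (default [paper_months()]).
#' @return A tibble with `predator_id`, ordered-factor `month`, and integer
#'   taxon columns.
#' @export
read_prey_counts <- function(path, months = paper_months()) {
  raw <- read_csv_quiet(path)
  if (!"month" %in% names(raw)) abort("Schema error: no 'month' column")
  if (!"predator_id" %in% names(raw)) abort("Schema error: no 'predator_id' column")
  taxa <- setdiff(names(raw), meta_cols_prey)
  if (length(taxa) == 0L) abort("Schema error: no taxon count columns")

  issues <- list()
  for (tx in taxa) {
    v <- parse_numeric(raw[[tx]])
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      issues[[tx]] <- tibble(row = bad, id = raw$predator_id[bad],
                             problem = sprintf("count '%s' for %s is not a non-negative integer",
                                               as.character(raw[[tx]][bad]), tx))
    }
  }
  badm <- which(!as.character(raw$month) %in% months)
  if (length(badm)) {
    issues[["month"]] <- tibble(row = badm, id = raw$predator_id[badm],
                                problem = sprintf("month '%s' not in calendar", raw$month[badm]))
  }
  fail_validation(bind_rows(issues), "Prey count table")

  out <- tibble(predator_id = raw$predator_id,
                month = as_month(raw$month, months))
  for (tx in taxa) out[[tx]] <- as.integer(parse_numeric(raw[[tx]]))
  out
}

#' Read an environmental zooplankton availability table
#'
#' Wide CSV with `sample_id`, `month`, optional `volume_sampled` (m^3), and
#' one column per taxon holding densities in individuals per cubic metre.
#'
#' @inheritParams read_prey_counts
#' @return A tibble with metadata columns plus non-negative numeric taxon
#'   densities.
#' @export
read_env_availability <- function(path, months = paper_months()) {
  raw <- read_csv_quiet(path)
  for (col in c("sample_id", "month")) {
    if (!col %in% names(raw)) abort(sprintf("Schema error: no '%s' column", col))
  }
  taxa <- setdiff(names(raw), meta_cols_env)
  if (length(taxa) == 0L) abort("Schema error: no taxon density columns")

  issues <- list()
  for (tx in taxa) {
    v <- parse_numeric(raw[[tx]])
    bad <- which(is.na(v) | v < 0)
    if (length(bad)) {
      issues[[tx]] <- tibble(row = bad, id = raw$sample_id[bad],
                             problem = sprintf("density '%s' for %s is not a non-negative number",
                                               as.character(raw[[tx]][bad]), tx))
    }
  }
  badm <- which(!as.character(raw$month) %in% months)
  if (length(badm)) {
    issues[["month"]] <- tibble(row = badm, id = raw$sample_id[badm],
                                problem = sprintf("month '%s' not in calendar", raw$month[badm]))
  }
  fail_validation(bind_rows(issues), "Environment availability table")

  out <- tibble(sample_id = raw$sample_id, month = as_month(raw$month, months))
  if ("volume_sampled" %in% names(raw)) {
    out$volume_sampled <- parse_numeric(raw$volume_sampled)
  }
  for (tx in taxa) out[[tx]] <- parse_numeric(raw[[tx]])
  out
}

#' Read stable isotope samples
#'
#' Long CSV with `sample_id`, `group` (a month label, a plankton size class
#' such as `"<200 um"`, or `"consumer"`), `d13C` and `d15N` in per-mil.
#' Unicode minus signs are normalized on parse. Missing or non-numeric delta
#' values are errors (never imputed); d13C outside [-40, 0] only warns.
#'
#' @param path CSV file path.
#' @return Tibble with columns `sample_id`, `group`, `d13C`, `d15N`.
#' @export
read_isotope_samples <- function(path) {
  raw <- read_csv_quiet(path)
  for (col in c("group", "d13C", "d15N")) {
    if (!col %in% names(raw)) abort(sprintf("Schema error: no '%s' column", col))
  }
  if (!"sample_id" %in% names(raw)) raw$sample_id <- as.character(seq_len(nrow(raw)))

  issues <- list()
  for (col in c("d13C", "d15N")) {
    v <- parse_numeric(raw[[col]])
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad)) {
      issues[[col]] <- tibble(row = bad, id = raw$sample_id[bad],
                              problem = sprintf("%s value '%s' is missing or non-numeric",
                                                col, as.character(raw[[col]][bad])))
    }
  }
  fail_validation(bind_rows(issues), "Isotope sample set")

  out <- tibble(sample_id = raw$sample_id,
                group = as.character(raw$group),
                d13C = parse_numeric(raw$d13C),
                d15N = parse_numeric(raw$d15N))
  n_out <- sum(out$d13C < -40 | out$d13C > 0)
  if (n_out > 0) {
    warn(sprintf("%d d13C value(s) outside the typical [-40, 0] permil range", n_out))
  }
  out
}

# --- fatty-acid shorthand normalization ------------------------------------

# "C18:1(n-9)" -> "C18:1n-9"; also tolerates spaces and the n-x omega suffix
# with or without parentheses. Unparseable names are returned unchanged.
normalize_fa_name <- function(x) {
  y <- gsub("\\s", "", as.character(x))
  y <- gsub("\\((n-\\d+)\\)", "\\1", y)
  y
}

#' Read fatty-acid concentration profiles
#'
#' Wide CSV with `sample_id`, `month`, `sex` (`male`/`female`/`none`),
#' `tissue` (`gonad`/`soma`/`plankton`), optional `size_class`, and one
#' column per fatty acid named in "C<carbons>:<double bonds>n-<omega>"
#' shorthand (parentheses around the omega suffix tolerated, e.g.
#' `C18:1(n-9)`). Concentrations are micrograms per milligram dry tissue.
#'
#' Columns whose names do not parse as FA shorthand are kept and flagged in
#' the `unknown_fa` attribute (and dropped from saturation-class totals); in
#' strict mode they are an error.
#'
#' @inheritParams read_prey_counts
#' @param strict Error on unparseable FA column names instead of flagging.
#' @return Tibble of profiles; attribute `unknown_fa` lists unparsed columns.
#' @export
read_fa_profiles <- function(path, months = paper_months(), strict = FALSE) {
  raw <- read_csv_quiet(path)
  for (col in c("sample_id", "month", "sex", "tissue")) {
    if (!col %in% names(raw)) abort(sprintf("Schema error: no '%s' column", col))
  }
  fa_cols <- setdiff(names(raw), meta_cols_fa)
  if (length(fa_cols) == 0L) abort("Schema error: no fatty-acid columns")
  norm <- normalize_fa_name(fa_cols)
  parsed <- is_fa_name(norm)
  unknown <- norm[!parsed]
  if (length(unknown) && strict) {
    abort(sprintf("Unparseable FA column name(s): %s", paste(unknown, collapse = ", ")))
  }
  if (length(unknown)) {
    warn(sprintf("Keeping %d unparseable FA column(s): %s",
                 length(unknown), paste(unknown, collapse = ", ")))
  }

  issues <- list()
  for (i in seq_along(fa_cols)) {
    v <- parse_numeric(raw[[fa_cols[i]]])
    bad <- which(is.na(v) | v < 0)
    if (length(bad)) {
      issues[[fa_cols[i]]] <- tibble(row = bad, id = raw$sample_id[bad],
                                     problem = sprintf("concentration '%s' for %s is negative or missing",
                                                       as.character(raw[[fa_cols[i]]][bad]), norm[i]))
    }
  }
  badsex <- which(!raw$sex %in% c("male", "female", "none"))
  if (length(badsex)) {
    issues[["sex"]] <- tibble(row = badsex, id = raw$sample_id[badsex],
                              problem = sprintf("sex '%s' not one of male/female/none", raw$sex[badsex]))
  }
  badtis <- which(!raw$tissue %in% c("gonad", "soma", "plankton"))
  if (length(badtis)) {
    issues[["tissue"]] <- tibble(row = badtis, id = raw$sample_id[badtis],
                                 problem = sprintf("tissue '%s' not one of gonad/soma/plankton", raw$tissue[badtis]))
  }
  fail_validation(bind_rows(issues), "Fatty-acid profile table")

  out <- tibble(sample_id = raw$sample_id,
                month = as_month(raw$month, months),
                sex = raw$sex, tissue = raw$tissue)
  if ("size_class" %in% names(raw)) out$size_class <- raw$size_class
  for (i in seq_along(fa_cols)) out[[norm[i]]] <- parse_numeric(raw[[fa_cols[i]]])
  attr(out, "unknown_fa") <- unknown
  out
}

#' Write a pipeline table to CSV
#'
#' Thin wrapper over [readr::write_csv()]; numeric values round-trip
#' bit-exactly through the matching reader.
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(x)
}

#' Validate pipeline input files and return a machine-readable report
#'
#' Runs each configured reader and collects pass/fail status per file.
#'
#' @param files Named list with any of `diet`, `env`, `isotopes`, `fa`
#'   mapping to CSV paths.
#' @param months Month calendar.
#' @return Tibble with columns `input`, `path`, `ok`, `message`.
#' @export
validate_inputs <- function(files, months = paper_months()) {
  readers <- list(
    diet = function(p) read_prey_counts(p, months),
    env = function(p) read_env_availability(p, months),
    isotopes = read_isotope_samples,
    fa = function(p) read_fa_profiles(p, months)
  )
  rows <- purrr::imap(files, function(path, key) {
    if (!key %in% names(readers)) {
      return(tibble(input = key, path = path, ok = FALSE,
                    message = "unknown input kind"))
    }
    res <- tryCatch(
      { readers[[key]](path); tibble(input = key, path = path, ok = TRUE, message = "ok") },
      error = function(e) tibble(input = key, path = path, ok = FALSE,
                                 message = conditionMessage(e))
    )
    res
  })
  bind_rows(rows)
}
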