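# Small in-code fixtures shared across test files.

tiny_diet <- function() {
  tibble::tibble(
    predator_id = c("m1", "m2", "m3", "m4"),
    month = as_month(c("May", "May", "Jun", "Jun")),
    copepods = c(10L, 14L, 5L, 7L),
    fish_eggs = c(2L, 0L, 1L, 1L),
    chaetognaths = c(0L, 1L, 0L, 0L)
  )
}

tiny_env <- function() {
  tibble::tibble(
    sample_id = c("e1", "e2"),
    month = as_month(c("May", "Jun")),
    volume_sampled = c(10, 10),
    copepods = c(100, 80),
    fish_eggs = c(20, 10),
    chaetognaths = c(5, 5)
  )
}

two_sources <- function(mu1 = 0, mu2 = 10, sd = 0.01) {
  tibble::tibble(
    source = c("a", "b"),
    d13C_mean = c(mu1, mu2), d13C_sd = c(sd, sd),
    d15N_mean = c(mu1, mu2), d15N_sd = c(sd, sd)
  )
}

zero_tef <- function() {
  tibble::tibble(isotope = c("d13C", "d15N"), mean = 0, sd = 0)
}

# Published monthly diet-composition summary bundled as extdata.
composition_table <- function() {
  readr::read_csv(
    system.file("extdata", "monthly_prey_composition.csv", package = "jellytroph"),
    show_col_types = FALSE
  )
}
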